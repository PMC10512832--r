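test_that("the network recovers an exact linear modulus law almost perfectly", {
  ds <- linear_fixture_dataset(n = 240, seed = 11)
  m <- train_bpnn(ds, "compressive", hidden = c(16, 16), epochs = 1500,
                  patience = 200, seed = 3, overfit_tol = Inf)
  ev <- evaluate_bpnn(m, ds, "test")
  expect_lt(ev$mape, 1)
  # fit consistency: training samples are reproduced within the train error
  tr <- evaluate_bpnn(m, ds, "train")
  expect_lt(tr$mape, 1)
})

test_that("training is deterministic for a fixed seed", {
  ds <- linear_fixture_dataset(n = 120, seed = 4)
  m1 <- train_bpnn(ds, "shear", hidden = c(8), epochs = 300, patience = 300,
                   seed = 42, overfit_tol = Inf)
  m2 <- train_bpnn(ds, "shear", hidden = c(8), epochs = 300, patience = 300,
                   seed = 42, overfit_tol = Inf)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$b, m2$b)
  m3 <- train_bpnn(ds, "shear", hidden = c(8), epochs = 300, patience = 300,
                   seed = 43, overfit_tol = Inf)
  expect_false(identical(m1$W, m3$W))
})

test_that("prediction is vectorized, pure, and sensitive to axis order", {
  ds <- linear_fixture_dataset(n = 240, seed = 11)
  m <- train_bpnn(ds, "compressive", hidden = c(16, 16), epochs = 1500,
                  patience = 200, seed = 3, overfit_tol = Inf)
  x <- c(c = 2, phi = 0.6, t = 0.1, m = 7, n = 8, l = 3)
  two <- predict(m, rbind(x, x))
  expect_equal(two[1], two[2])
  swapped <- x; swapped[["m"]] <- 8; swapped[["n"]] <- 7
  expect_gt(abs(predict(m, rbind(x)) - predict(m, rbind(swapped))), 1e-6)
  cfg <- tpms_config(2, 0.6, 7, 8, 3, t = 0.1)
  expect_equal(as.numeric(predict(m, cfg)), as.numeric(predict(m, rbind(x))))
  # inputs far outside the training box are flagged
  far <- x; far[["phi"]] <- 3
  expect_equal(attr(predict(m, rbind(far)), "extrapolated"), 1L)
})

test_that("evaluation computes MAPE and MSE as defined", {
  ds <- linear_fixture_dataset(n = 80, seed = 6)
  m <- constant_bpnn(0)
  # hand-built predictions: MAPE of labels [1, 4] against [2, 4] is 50%
  rel <- abs(c(2, 4) - c(1, 4)) / c(1, 4) * 100
  expect_equal(mean(rel), 50)
  # a perfect model scores zero on both metrics
  perfect <- structure(list(
    W = list(matrix(0, 6, 1), matrix(0, 1, 1)), b = list(0, 0),
    sizes = c(6L, 1L, 1L), activation = "tanh",
    norm = list(xm = rep(0, 6), xs = rep(1, 6), ym = 1, ys = 1),
    target = "compressive", label = "C11", meta = list(R = 13L)),
    class = "bpnn")
  ds0 <- ds
  ds0$records$C11 <- 1  # constant labels; constant model ym = 1 is exact
  ev <- evaluate_bpnn(perfect, ds0, "test")
  expect_equal(ev$mape, 0)
  expect_equal(ev$mse, 0)
  expect_error(evaluate_bpnn(perfect, structure(list(records = ds$records,
                                                     train = 1:5, test = integer(0)),
                                                class = "tpms_dataset"), "test"),
               "empty")
})

test_that("zero labels are excluded from MAPE with a count", {
  ds <- linear_fixture_dataset(n = 80, seed = 6)
  ds$records$C11[ds$test[1]] <- 0
  m <- train_bpnn(ds, "compressive", hidden = c(8), epochs = 200,
                  patience = 200, seed = 1, overfit_tol = Inf)
  ev <- evaluate_bpnn(m, ds, "test")
  expect_equal(ev$n_zero_excluded, 1L)
  expect_true(is.finite(ev$mape))
})

test_that("the overfitting gate trips when test error explodes", {
  ds <- linear_fixture_dataset(n = 120, seed = 8)
  ds$records$C11[ds$test] <- ds$records$C11[ds$test] + 50  # corrupt held-out labels
  expect_error(train_bpnn(ds, "compressive", hidden = c(8), epochs = 300,
                          patience = 300, seed = 1), "overfitting gate")
})

test_that("models serialize to JSON and round-trip bit-identically", {
  ds <- linear_fixture_dataset(n = 120, seed = 4)
  m <- train_bpnn(ds, "compressive", hidden = c(8, 8), epochs = 400,
                  patience = 400, seed = 9, overfit_tol = Inf)
  path <- tempfile(fileext = ".json")
  save_bpnn(m, path)
  back <- load_bpnn(path)
  X <- as.matrix(ds$records[1:20, c("c", "phi", "t", "m", "n", "l")])
  expect_identical(predict(m, X), predict(back, X))
  suppressWarnings(expect_error(load_bpnn(tempfile()),
                                "cannot open|No such|not exist"))
})

test_that("architecture search returns the grid argmin with a full table", {
  ds <- linear_fixture_dataset(n = 160, seed = 10)
  single <- architecture_search(ds, grid = data.frame(layers = 1L, width = 8L),
                                seed = 2, epochs = 200, patience = 200)
  expect_equal(single$best$layers, 1L)
  expect_equal(nrow(single$table), 1L)
  res <- architecture_search(ds, grid = expand.grid(layers = 1:2, width = c(4L, 8L)),
                             seed = 2, epochs = 200, patience = 200)
  expect_equal(nrow(res$table), 4L)
  expect_true(all(is.finite(res$table$mape)))
  expect_equal(res$table$mape[res$best_index], min(res$table$mape))
  expect_error(architecture_search(ds, grid = data.frame()), "empty")
})
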