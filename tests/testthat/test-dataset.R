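test_that("design-space sampling is reproducible and respects the ranges", {
  expect_identical(sample_configs(0), list())
  a <- sample_configs(20, seed = 5, R = 13)
  b <- sample_configs(20, seed = 5, R = 13)
  expect_equal(a, b)
  df <- do.call(rbind, lapply(a, function(cf)
    data.frame(c = cf$c, phi = cf$phi, m = cf$m, n = cf$n, l = cf$l)))
  expect_true(all(df$c %in% 1:4))
  expect_true(all(df$phi >= 0.5 & df$phi <= 0.75))
  expect_true(all(unlist(df[, c("m", "n", "l")]) %in% 3:8))
  # calibrated thresholds round-trip their porosity
  for (cf in a[1:3])
    expect_lt(abs(measure_porosity(voxelize(cf, 13)) - cf$phi), 0.0021)
  expect_error(sample_configs(5, ranges = list(c = 1:4, phi = c(0.2, 1.2),
                                               mnl = c(3, 8))), "porosity")
})

test_that("dataset labels are the canonical compression and shear moduli", {
  cfgs <- sample_configs(3, seed = 8, R = 13)
  ds <- build_dataset(cfgs, R = 13)
  expect_s3_class(ds, "tpms_dataset")
  expect_equal(nrow(ds$records), 3L)
  expect_named(ds$records, c("sid", "c", "phi", "t", "m", "n", "l", "C11",
                             "C44", "R", "E", "nu"))
  expect_true(all(ds$records$C11 > 0 & ds$records$C44 > 0))
  # the stored label equals a direct FE run
  C <- homogenize(voxelize(cfgs[[1]], 13), compression = "x", shear = "yz")
  expect_equal(ds$records$C11[1], C[1, 1], tolerance = 1e-12)
  expect_equal(ds$records$C44[1], C[4, 4], tolerance = 1e-12)
  # rebuilding hits the label cache and changes nothing
  t0 <- Sys.time()
  ds2 <- build_dataset(cfgs, R = 13)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 0.5)
  expect_identical(ds$records, ds2$records)
})

test_that("the compressive label matches the swapped-axis modulus", {
  cf <- sample_configs(1, seed = 13, R = 13)[[1]]
  ds <- build_dataset(list(cf), R = 13)
  swapped <- tpms_config(cf$c, cf$phi, cf$n, cf$m, cf$l, t = cf$t)
  C <- homogenize(voxelize(swapped, 13), compression = "y", shear = character(0))
  expect_equal(ds$records$C11[1], C[2, 2], tolerance = 1e-6)
})

test_that("splits are disjoint, exhaustive, and reproducible", {
  ds <- linear_fixture_dataset(n = 8, seed = 2)
  expect_equal(length(ds$train), 7L)
  expect_equal(length(ds$test), 1L)
  ds <- linear_fixture_dataset(n = 240, seed = 2)
  expect_equal(length(ds$train), 210L)
  expect_equal(length(ds$test), 30L)
  expect_length(intersect(ds$train, ds$test), 0)
  expect_setequal(c(ds$train, ds$test), seq_len(240))
  ds2 <- split_dataset(ds, 7 / 8, seed = ds$provenance$split_seed)
  expect_identical(ds$train, ds2$train)
  small <- ds; small$records <- small$records[1:5, ]
  expect_error(split_dataset(small, 0.5), "fewer than 8")
})

test_that("datasets round-trip through CSV with provenance", {
  ds <- linear_fixture_dataset(n = 24, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$records, ds$records, tolerance = 1e-12)
  expect_identical(back$train, ds$train)
  expect_identical(back$test, ds$test)
  expect_equal(back$provenance$R, 13)
})

test_that("augmented records carry the permuted directional labels", {
  cf <- sample_configs(1, seed = 17, R = 13)[[1]]
  ds <- build_dataset(list(cf), R = 13, augment = TRUE)
  C <- homogenize(voxelize(cf, 13))
  expect_lte(nrow(ds$records), 3L)
  r1 <- ds$records[1, ]
  expect_equal(c(r1$m, r1$n, r1$l), c(cf$m, cf$n, cf$l))
  expect_equal(r1$C11, C[1, 1], tolerance = 1e-12)
  expect_equal(r1$C44, C[4, 4], tolerance = 1e-12)
  if (nrow(ds$records) >= 2) {
    r2 <- ds$records[2, ]
    expect_equal(c(r2$m, r2$n, r2$l), c(cf$n, cf$m, cf$l))
    expect_equal(r2$C11, C[2, 2], tolerance = 1e-12)
    expect_equal(r2$C44, C[5, 5], tolerance = 1e-12)
  }
  # splits keep a structure's permutation records together
  cfgs <- sample_configs(10, seed = 23, R = 13)
  dsa <- split_dataset(build_dataset(cfgs, R = 13, augment = TRUE), 0.7, seed = 3)
  sid_tr <- unique(dsa$records$sid[dsa$train])
  sid_te <- unique(dsa$records$sid[dsa$test])
  expect_length(intersect(sid_tr, sid_te), 0)
})

test_that("Latin-hypercube porosity sampling stratifies the porosity range", {
  a <- sample_configs(12, seed = 5, R = 13, feasible_only = FALSE,
                      phi_sampling = "lhs")
  phis <- vapply(a, function(cf) cf$phi, 0)
  bins <- floor((phis - 0.5) / (0.25 / 12))
  expect_setequal(bins, 0:11)
  b <- sample_configs(12, seed = 5, R = 13, feasible_only = FALSE,
                      phi_sampling = "lhs")
  expect_equal(a, b)
})
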