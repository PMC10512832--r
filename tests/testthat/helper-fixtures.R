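# Shared fixtures, all generated in code.

# Fully solid voxel model on an R^3 grid (the analytic-oracle geometry).
full_solid_model <- function(R = 8, L = 10, E = 10, nu = 0.3) {
  structure(list(occupancy = array(TRUE, c(R, R, R)), R = as.integer(R),
                 spacing = L / R,
                 config = tpms_config(2, 0.5, 3, 3, 3, t = 0, L = L, E = E, nu = nu)),
            class = "voxel_model")
}

# Dataset whose labels are an exact linear function of (phi, m): a sanity
# fixture the surrogate must recover almost perfectly.
linear_fixture_dataset <- function(n = 240, seed = 11) {
  rec <- with_seed_local(seed, data.frame(
    c = sample(1:4, n, TRUE),
    phi = stats::runif(n, 0.5, 0.75),
    t = stats::runif(n, -0.5, 0.5),
    m = sample(3:8, n, TRUE),
    n = sample(3:8, n, TRUE),
    l = sample(3:8, n, TRUE)))
  rec$C11 <- 2 + 3 * rec$phi + 0.5 * rec$m
  rec$C44 <- 1 + 1.5 * rec$phi + 0.2 * rec$m
  rec$R <- 13L; rec$E <- 10; rec$nu <- 0.3
  ds <- structure(list(records = rec, train = integer(0), test = integer(0),
                       provenance = list(R = 13L)),
                  class = "tpms_dataset")
  split_dataset(ds, 7 / 8, seed = seed)
}

# Seed-scoped RNG without touching the caller's stream (test-side copy).
with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Constant-output surrogate: zero weights, output bias 0, denormalizer set so
# predict() returns `value` exactly for any input. Used to test GA arithmetic.
constant_bpnn <- function(value, label = "C11", R = 13L) {
  sizes <- c(6L, 4L, 1L)
  structure(list(
    W = list(matrix(0, 6, 4), matrix(0, 4, 1)),
    b = list(numeric(4), numeric(1)),
    sizes = sizes, activation = "tanh",
    norm = list(xm = rep(0, 6), xs = rep(1, 6), ym = value, ys = 1),
    target = if (label == "C11") "compressive" else "shear", label = label,
    meta = list(R = R)),
    class = "bpnn")
}
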