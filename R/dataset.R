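# Design-space sampling, FE labelling, and train/test persistence for the
# forward surrogates.

#' Sample design points from the scaffold design space
#'
#' Draws `n` design points with the family label uniform on `ranges$c`, the
#' cell counts uniform on `ranges$mnl`, and the porosity uniform on
#' `ranges$phi`, then calibrates the level-set threshold for each point.
#' Near-duplicates (identical `c`, `m`, `n`, `l` and porosity within 0.005)
#' are resampled so every record adds information, as are points that are
#' infeasible at the working resolution (see [is_feasible()]) when
#' `feasible_only` is set.
#'
#' @param n number of design points.
#' @param seed RNG seed (sampling is reproducible for a fixed seed).
#' @param ranges design-space ranges, see [design_ranges()].
#' @param R resolution used to calibrate `t` (and later to label the point).
#' @param L,E,nu geometry and material constants passed to [tpms_config()].
#' @param feasible_only resample design points whose voxelization at `R` has
#'   no spanning load path (default `TRUE`).
#' @param phi_sampling `"uniform"` (default) or `"lhs"` for Latin-hypercube
#'   (stratified) porosity sampling, which lowers the variance of porosity
#'   coverage; resampled rejections fall back to uniform draws.
#' @return A list of [tpms_config()] objects with `t` filled in.
#' @export
sample_configs <- function(n, seed = 1, ranges = design_ranges(), R = 32,
                           L = 10, E = 10, nu = 0.3, feasible_only = TRUE,
                           phi_sampling = c("uniform", "lhs")) {
  phi_sampling <- match.arg(phi_sampling)
  if (n < 0) stop_cfg("n must be nonnegative")
  if (n == 0) return(list())
  if (ranges$phi[1] <= 0 || ranges$phi[2] >= 1 || ranges$phi[1] >= ranges$phi[2])
    stop_cfg("invalid porosity range [%g, %g]", ranges$phi[1], ranges$phi[2])
  if (ranges$mnl[1] < 1) stop_cfg("invalid arrangement range")
  with_seed(seed, {
    phi_stream <- if (phi_sampling == "lhs") {
      if (!requireNamespace("lhs", quietly = TRUE))
        stop_cfg("phi_sampling = 'lhs' needs the lhs package")
      ranges$phi[1] + diff(ranges$phi) * as.vector(lhs::randomLHS(n, 1L))
    }
    seen <- new.env(parent = emptyenv())
    out <- vector("list", n)
    i <- 1L
    tries <- 0L
    fresh <- rep(TRUE, n)  # slot i still entitled to its stratified draw
    while (i <= n) {
      tries <- tries + 1L
      if (tries > 50L * n) stop_cfg("design space too small for %d distinct points", n)
      c <- sample(ranges$c, 1L)
      mnl <- sample(seq(ranges$mnl[1], ranges$mnl[2]), 3L, replace = TRUE)
      phi <- if (!is.null(phi_stream) && fresh[i]) {
        fresh[i] <- FALSE
        phi_stream[i]
      } else stats::runif(1, ranges$phi[1], ranges$phi[2])
      # duplicate gate: same discrete genes and porosity within 0.005
      key <- sprintf("%d|%d|%d|%d|%.0f", c, mnl[1], mnl[2], mnl[3], phi / 0.005)
      if (!is.null(cache_get(seen, key))) next
      cache_set(seen, key, TRUE)
      t <- calibrate_t(c, mnl[1], mnl[2], mnl[3], phi, R = R, L = L)
      cand <- tpms_config(c, phi, mnl[1], mnl[2], mnl[3], t = t,
                          L = L, E = E, nu = nu)
      if (feasible_only && !is_feasible(cand, R)) next
      out[[i]] <- cand
      i <- i + 1L
    }
    out
  })
}

# Session cache for FE labels, keyed by design point + resolution + material.
.label_cache <- new.env(parent = emptyenv())

#' Build a labelled dataset by running the FE forward model
#'
#' For each design point the solid phase is voxelized at resolution `R` and
#' homogenized. The canonical labels are compression along x (the `C11` label
#' for the compressive-modulus network) and shear in the yz plane (the `C44`
#' label for the shear-modulus network).
#'
#' With `augment = FALSE` only those two load cases are run and each structure
#' contributes one record. With `augment = TRUE` (the desk-protocol default
#' via [desk_forward_model()]) all six directional load cases are run — they
#' share one factorization, so the extra cases are nearly free — and each
#' structure contributes up to three records: the axis permutations
#' `(m,n,l)`, `(n,m,l)`, `(l,n,m)` carry canonical labels `(C11, C44)`,
#' `(C22, C55)`, `(C33, C66)` of the original structure. This is exactly the
#' permutation identity the inverse search's regeneration step queries, so
#' augmentation trains the networks on the probes they will answer. The
#' `sid` column records which structure a record came from; splitting keeps a
#' structure's records together.
#'
#' Failed geometries are logged and skipped; results are cached by
#' design-point key so repeated builds recompute nothing.
#'
#' @param configs list of [tpms_config()] (see [sample_configs()]).
#' @param R voxel resolution for labelling.
#' @param mat a [material()]; defaults to each config's constants.
#' @param mode FE boundary-condition mode, see [homogenize()].
#' @param augment emit the three axis-permutation records per structure.
#' @param verbose print progress every 50 structures.
#' @return A `tpms_dataset`: data frame `records` with columns
#'   `sid, c, phi, t, m, n, l, C11, C44, R, E, nu` plus provenance, and empty
#'   splits.
#' @export
build_dataset <- function(configs, R = 32, mat = NULL, mode = "uniaxial",
                          augment = FALSE, verbose = FALSE) {
  n <- length(configs)
  rows <- vector("list", n)
  failed <- 0L
  for (i in seq_len(n)) {
    cf <- configs[[i]]
    m_i <- mat %||% material(cf$E, cf$nu)
    key <- paste0(config_key(cf$c, cf$phi, cf$m, cf$n, cf$l, R),
                  sprintf("|E%.6g|nu%.6g|%s|aug%d", m_i$E, m_i$nu, mode, augment))
    hit <- cache_get(.label_cache, key)
    if (is.null(hit)) {
      hit <- tryCatch({
        v <- voxelize(cf, R)
        if (augment) {
          C <- homogenize(v, m_i, mode = mode)
          cbind(m = c(cf$m, cf$n, cf$l), n = c(cf$n, cf$m, cf$n),
                l = c(cf$l, cf$l, cf$m),
                C11 = c(C[1, 1], C[2, 2], C[3, 3]),
                C44 = c(C[4, 4], C[5, 5], C[6, 6]))
        } else {
          C <- homogenize(v, m_i, compression = "x", shear = "yz", mode = mode)
          cbind(m = cf$m, n = cf$n, l = cf$l, C11 = C[1, 1], C44 = C[4, 4])
        }
      }, error = function(e) {
        warning(sprintf("skipping design point %d (%s): %s", i,
                        tpms_family_name(cf$c), conditionMessage(e)),
                call. = FALSE)
        NULL
      })
      if (!is.null(hit)) cache_set(.label_cache, key, hit)
    }
    if (is.null(hit)) { failed <- failed + 1L; next }
    df <- data.frame(sid = i, c = cf$c, phi = cf$phi, t = cf$t,
                     m = hit[, "m"], n = hit[, "n"], l = hit[, "l"],
                     C11 = hit[, "C11"], C44 = hit[, "C44"],
                     R = R, E = m_i$E, nu = m_i$nu)
    rows[[i]] <- df[!duplicated(df[, c("m", "n", "l")]), , drop = FALSE]
    if (verbose && i %% 50L == 0L) message(sprintf("  labelled %d / %d", i, n))
  }
  if (n > 0 && failed > 0.05 * n)
    stop_cfg("aborting: %d of %d geometries failed (> 5%%)", failed, n)
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(records) <- NULL
  structure(list(records = records, train = integer(0), test = integer(0),
                 provenance = list(R = R, n_requested = n, n_failed = failed,
                                   augment = augment)),
            class = "tpms_dataset")
}

#' Split a dataset into training and test sets
#'
#' Random, seed-reproducible split; no record lands in both sets. The standard
#' protocol holds out 1/8 (7/8 train). Augmented datasets are split by
#' structure (`sid`), keeping a structure's permutation records together so
#' the test set never contains relabelled copies of training structures.
#'
#' @param ds a `tpms_dataset`.
#' @param fraction training fraction in (0, 1); default 7/8.
#' @param seed RNG seed.
#' @return The dataset with `train` and `test` index vectors filled.
#' @export
split_dataset <- function(ds, fraction = 7 / 8, seed = 1) {
  stopifnot(inherits(ds, "tpms_dataset"))
  if (fraction <= 0 || fraction >= 1) stop_cfg("fraction must be in (0, 1)")
  nr <- nrow(ds$records)
  if (nr < 8L) stop_cfg("refusing to split fewer than 8 records (%d)", nr)
  units <- if ("sid" %in% names(ds$records)) unique(ds$records$sid)
           else seq_len(nr)
  nu_ <- length(units)
  if (nu_ < 8L) stop_cfg("refusing to split fewer than 8 structures (%d)", nu_)
  ntrain <- round(fraction * nu_)
  with_seed(seed, {
    perm <- sample(units)
    tr_units <- perm[seq_len(ntrain)]
    if ("sid" %in% names(ds$records)) {
      ds$train <- which(ds$records$sid %in% tr_units)
      ds$test <- which(!ds$records$sid %in% tr_units)
    } else {
      ds$train <- sort(tr_units)
      ds$test <- sort(setdiff(units, tr_units))
    }
  })
  ds$provenance$split_seed <- seed
  ds$provenance$fraction <- fraction
  ds
}

#' @export
print.tpms_dataset <- function(x, ...) {
  cat(sprintf("TPMS dataset: %d records (R = %s), %d train / %d test\n",
              nrow(x$records), x$provenance$R %||% "?",
              length(x$train), length(x$test)))
  invisible(x)
}

#' Write / read a dataset as CSV with a JSON provenance sidecar
#'
#' The CSV holds one record per row with the documented header
#' (`c, phi, t, m, n, l, C11, C44, R, E, nu`); the sidecar
#' (`<path>.json`) stores provenance and the split indices.
#'
#' @param ds a `tpms_dataset`.
#' @param path CSV path.
#' @return `path` (write) or a `tpms_dataset` (read).
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "tpms_dataset"))
  utils::write.csv(ds$records, path, row.names = FALSE)
  jsonlite::write_json(list(provenance = ds$provenance, train = ds$train,
                            test = ds$test),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  records <- utils::read.csv(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list(provenance = list(), train = integer(0), test = integer(0))
  structure(list(records = records,
                 train = as.integer(meta$train), test = as.integer(meta$test),
                 provenance = as.list(meta$provenance)),
            class = "tpms_dataset")
}
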