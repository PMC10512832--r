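# Implicit TPMS geometry: level-set evaluation, porosity calibration,
# voxelization.

# Threshold-free level-set value for family label `c` at angle arrays
# X = 2*pi*m*x/L, Y = 2*pi*n*y/L, Z = 2*pi*l*z/L. Single-period trigonometric
# approximants; the solid phase is {value - t <= 0}.
level_set_core <- function(c, X, Y, Z) {
  switch(as.integer(c),
    # 1: Gyroid
    sin(X) * cos(Y) + sin(Y) * cos(Z) + sin(Z) * cos(X),
    # 2: Primitive
    cos(X) + cos(Y) + cos(Z),
    # 3: Octo / I-WP
    2 * (cos(X) * cos(Y) + cos(Y) * cos(Z) + cos(Z) * cos(X)) -
      (cos(2 * X) + cos(2 * Y) + cos(2 * Z)),
    # 4: Diamond
    sin(X) * sin(Y) * sin(Z) + sin(X) * cos(Y) * cos(Z) +
      cos(X) * sin(Y) * cos(Z) + cos(X) * cos(Y) * sin(Z),
    stop_cfg("unknown cell-type label: %s", c)
  )
}

#' Evaluate the anisotropic TPMS level-set function
#'
#' Evaluates `U(x, y, z)` for the config's TPMS family with per-axis angular
#' frequencies `2*pi*m/L`, `2*pi*n/L`, `2*pi*l/L` and threshold offset `-t`.
#' The Primitive family, for example, is
#' `U = cos(2*pi*m*x/L) + cos(2*pi*n*y/L) + cos(2*pi*l*z/L) - t`.
#' The solid phase is the region where `U >= 0`, so increasing `t` shrinks the
#' solid set and raises the porosity (the calibrated threshold for the Gyroid
#' at 67% porosity with counts (7, 8, 3) is about +0.52 under this sign).
#'
#' @param config a [tpms_config()]. A missing `t` is treated as 0.
#' @param x,y,z coordinates in mm (vectorized, recycled to common length).
#' @return Numeric vector of level-set values.
#' @export
level_set <- function(config, x, y, z) {
  stopifnot(inherits(config, "tpms_config"))
  w <- 2 * pi / config$L
  level_set_core(config$c, w * config$m * x, w * config$n * y, w * config$l * z) -
    (config$t %||% 0)
}

# Threshold-free field sampled at the cell-centred voxel grid (R^3 array,
# axis order x, y, z). Voxel (i, j, k) has centre ((i-1/2)h, (j-1/2)h, (k-1/2)h).
tpms_field_grid <- function(c, m, n, l, L, R) {
  xs <- (seq_len(R) - 0.5) * (L / R)
  w <- 2 * pi / L
  AX <- array(w * m * xs, c(R, R, R))
  AY <- array(rep(w * n * xs, each = R), c(R, R, R))
  AZ <- array(rep(w * l * xs, each = R * R), c(R, R, R))
  level_set_core(c, AX, AY, AZ)
}

#' Voxelize the solid phase of a TPMS scaffold
#'
#' Samples the level-set function at the centres of an `R x R x R` cell-centred
#' grid spanning the design cube and marks a voxel solid where `U >= 0`.
#'
#' @param config a [tpms_config()] with `t` set (see [calibrate_t()]); a
#'   missing `t` is treated as 0.
#' @param R grid resolution (voxels per edge, >= 8).
#' @return A `voxel_model`: list with `occupancy` (logical `R^3` array, axis
#'   order x, y, z), `R`, `spacing` (mm), and `config`.
#' @export
voxelize <- function(config, R = 32) {
  stopifnot(inherits(config, "tpms_config"))
  R <- as.integer(R)
  if (R < 8L) stop_cfg("voxel resolution R must be >= 8, got %d", R)
  F <- tpms_field_grid(config$c, config$m, config$n, config$l, config$L, R)
  occ <- F >= (config$t %||% 0)
  sf <- mean(occ)
  if (sf == 0 || sf == 1)
    stop_cfg("degenerate geometry: solid fraction is %g at t = %g", sf, config$t %||% 0)
  structure(list(occupancy = occ, R = R, spacing = config$L / R, config = config),
            class = "voxel_model")
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf("Voxel model: %d^3 grid, spacing %.4g mm, solid fraction %.4f (%s)\n",
              x$R, x$spacing, mean(x$occupancy), tpms_family_name(x$config$c)))
  invisible(x)
}

#' Porosity of a voxel model
#'
#' @param v a `voxel_model` (or a logical occupancy array).
#' @return Void fraction `1 - solid fraction`.
#' @export
measure_porosity <- function(v) {
  occ <- if (inherits(v, "voxel_model")) v$occupancy else v
  1 - mean(occ)
}

# Session cache for calibrated thresholds. The multiset of level-set values on
# a cubic cell-centred grid is exactly invariant under permutations of
# (m, n, l) — coordinate relabellings and reflections map the grid onto itself
# — so t is cached on the sorted counts.
.t_cache <- new.env(parent = emptyenv())

#' Calibrate the level-set threshold to a target porosity
#'
#' Finds the threshold `t` such that the voxelized solid phase at resolution
#' `R` has void fraction `phi` within `tol`, by bisection on `t`. The solid
#' fraction is nonincreasing in `t` (solid = `{U >= 0}` with `U` carrying the
#' `-t` offset), so the bisection is monotone. The level-set field is sampled
#' once and each bisection step is a thresholding pass.
#'
#' @param c TPMS family label (1..4).
#' @param m,n,l unit-cell counts along x, y, z.
#' @param phi target porosity in (0.05, 0.95).
#' @param R calibration resolution (default 32).
#' @param tol porosity tolerance (default 0.002).
#' @param L cube edge length in mm (default 10; t is scale-free, L only fixes
#'   the sampling grid).
#' @param max_iter bisection iteration cap.
#' @param cache reuse thresholds already calibrated this session for the same
#'   `(c, sorted(m, n, l), phi, R)`.
#' @return The calibrated threshold `t`.
#' @export
calibrate_t <- function(c, m, n, l, phi, R = 32, tol = 0.002, L = 10,
                        max_iter = 100, cache = TRUE) {
  if (phi <= 0.05 || phi >= 0.95) stop_cfg("target porosity must be in (0.05, 0.95)")
  cnt <- sort(as.integer(c(m, n, l)))
  key <- sprintf("c%d|%d.%d.%d|phi%.10g|R%d", as.integer(c), cnt[1], cnt[2], cnt[3],
                 phi, as.integer(R))
  if (cache && !is.null(v <- cache_get(.t_cache, key))) return(v)
  F <- tpms_field_grid(c, m, n, l, L, R)
  target_solid <- 1 - phi
  lo <- min(F) - 1e-9; hi <- max(F) + 1e-9
  for (it in seq_len(max_iter)) {
    t <- (lo + hi) / 2
    sf <- mean(F >= t)  # solid fraction falls as t rises
    if (abs(sf - target_solid) <= tol) break
    if (sf > target_solid) lo <- t else hi <- t
    if (it == max_iter)
      stop_cfg("threshold calibration failed after %d iterations (solid %.4f vs %.4f)",
               max_iter, sf, target_solid)
  }
  if (cache) cache_set(.t_cache, key, t)
  t
}

#' Check desk-scale feasibility of a design point
#'
#' A design point is feasible at resolution `R` when its voxelized solid
#' phase (i) loses at most a fraction `max_floating` of its solid voxels to
#' floating islands, and (ii) after dropping those islands spans the cube
#' along all three axes (a load path exists for every load case). In the
#' continuum every design-space structure is connected; at coarse resolutions
#' thin necks can fall between voxel centres, which first sheds fragments
#' (degrading the effective stiffness unpredictably) and eventually severs
#' the load path. Both symptoms mark a structure as unresolvable at this
#' fidelity.
#'
#' @param config a [tpms_config()] with `t` set.
#' @param R voxel resolution.
#' @param max_floating largest tolerated floating-voxel fraction (default
#'   0.005).
#' @return `TRUE` or `FALSE`.
#' @export
is_feasible <- function(config, R, max_floating = 0.005) {
  occ <- tryCatch(voxelize(config, R)$occupancy, error = function(e) NULL)
  if (is.null(occ)) return(FALSE)
  flt <- filter_components(occ)
  if (flt$removed > max_floating * sum(occ)) return(FALSE)
  occ <- flt$occupancy
  all(vapply(1:3, function(d) {
    ix <- slice.index(occ, d)
    any(occ & ix == 1L) && any(occ & ix == dim(occ)[d])
  }, logical(1)))
}

#' Export a voxel model as a legacy-VTK structured-points file
#'
#' Writes the occupancy grid as ASCII VTK with one cell per voxel, for
#' inspection in ParaView or similar. Export only; not used in computation.
#'
#' @param v a `voxel_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_voxels <- function(v, path) {
  stopifnot(inherits(v, "voxel_model"))
  R <- v$R
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tpmsdesign voxel occupancy", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", R + 1L, R + 1L, R + 1L),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", v$spacing, v$spacing, v$spacing),
               sprintf("CELL_DATA %d", R^3),
               "SCALARS occupancy int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(paste(as.integer(v$occupancy), collapse = " "), con)
  invisible(path)
}
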