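#' Scaffold design point
#'
#' Bundles one anisotropic TPMS design point `X = (c, phi, t, m, n, l)` with
#' the global geometry and material constants. `c` labels the TPMS family
#' (1 = Gyroid, 2 = Primitive, 3 = Octo/I-WP, 4 = Diamond), `phi` is the target
#' porosity (void fraction), `t` the level-set threshold that realizes it, and
#' `m`, `n`, `l` are the unit-cell counts along x, y, z inside a cube of edge
#' `L`. Different counts along the three axes are what make the scaffold
#' anisotropic: more, thinner cells along an axis change the directional
#' stiffness while the outer dimensions stay fixed.
#'
#' @param c integer TPMS family label in 1..4.
#' @param phi target porosity, strictly between 0 and 1. The standard design
#'   space uses 0.50–0.75.
#' @param m,n,l unit-cell counts along x, y, z (integers >= 1; design space
#'   uses 3..8).
#' @param t level-set threshold. If `NULL` (default) it is left unset; use
#'   [calibrate_t()] to derive it from `phi`.
#' @param L cube edge length in mm (default 10).
#' @param E constituent Young's modulus in GPa (default 10).
#' @param nu constituent Poisson ratio (default 0.3).
#' @return An object of class `tpms_config`.
#' @examples
#' cfg <- tpms_config(c = 1, phi = 0.67, m = 7, n = 8, l = 3)
#' @export
tpms_config <- function(c, phi, m, n, l, t = NULL, L = 10, E = 10, nu = 0.3) {
  c <- as.integer(c); m <- as.integer(m); n <- as.integer(n); l <- as.integer(l)
  if (!c %in% 1:4) stop_cfg("cell-type label c must be in 1..4, got %s", c)
  if (any(c(m, n, l) < 1L)) stop_cfg("arrangement counts m, n, l must be >= 1")
  if (!is.numeric(phi) || phi <= 0 || phi >= 1) stop_cfg("porosity phi must be in (0, 1)")
  if (L <= 0) stop_cfg("edge length L must be positive")
  if (E <= 0) stop_cfg("Young's modulus E must be positive")
  if (nu <= -0.5 || nu >= 0.5) stop_cfg("Poisson ratio nu must be in (-0.5, 0.5)")
  structure(
    list(c = c, phi = phi, t = t, m = m, n = n, l = l, L = L, E = E, nu = nu),
    class = "tpms_config"
  )
}

#' @export
print.tpms_config <- function(x, ...) {
  cat(sprintf("TPMS design point: %s, phi = %.3f, t = %s, (m, n, l) = (%d, %d, %d)\n",
              tpms_family_name(x$c), x$phi,
              if (is.null(x$t)) "<uncalibrated>" else sprintf("%.4f", x$t),
              x$m, x$n, x$l))
  cat(sprintf("  cube L = %g mm, material E = %g GPa, nu = %g\n", x$L, x$E, x$nu))
  invisible(x)
}

#' TPMS family names
#'
#' Maps the integer family label to its conventional name.
#'
#' @param c integer label(s) in 1..4.
#' @return Character vector of family names.
#' @export
tpms_family_name <- function(c) {
  nm <- c("Gyroid", "Primitive", "Octo", "Diamond")
  if (any(!c %in% 1:4)) stop_cfg("unknown cell-type label: %s",
                                 paste(setdiff(c, 1:4), collapse = ", "))
  nm[c]
}

#' Default design-space ranges
#'
#' The standard sampling ranges for dataset generation and inverse search:
#' family label 1..4, porosity 0.50–0.75, cell counts 3..8 on each axis.
#'
#' @return A list with elements `c`, `phi` (min/max), and `mnl` (min/max).
#' @export
design_ranges <- function() {
  list(c = 1:4, phi = c(0.50, 0.75), mnl = c(3L, 8L))
}
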