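# Voxel finite-element homogenization: trilinear hexahedra, one element per
# solid voxel, displacement-driven compression and shear load cases.

#' Constituent material
#'
#' @param E Young's modulus in GPa.
#' @param nu Poisson ratio.
#' @return An object of class `material`.
#' @export
material <- function(E = 10, nu = 0.3) {
  if (E <= 0) stop_cfg("E must be positive")
  if (nu <= -0.5 || nu >= 0.5) stop_cfg("nu must be in (-0.5, 0.5)")
  structure(list(E = E, nu = nu), class = "material")
}

# 6x6 isotropic constitutive matrix (engineering shear strains).
iso_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Local node order of the hexahedron (signs of xi, eta, zeta).
.hex_xn <- c(-1, 1, 1, -1, -1, 1, 1, -1)
.hex_yn <- c(-1, -1, 1, 1, -1, -1, 1, 1)
.hex_zn <- c(-1, -1, -1, -1, 1, 1, 1, 1)

#' Element stiffness matrix of a cubic trilinear hexahedron
#'
#' Standard 8-node trilinear-displacement hexahedron of edge `h`, isotropic
#' constitutive law, 2x2x2 Gauss integration. DOF order is node-major
#' (ux, uy, uz per node). The matrix is symmetric positive semidefinite with
#' exactly six rigid-body zero-energy modes, and scales linearly with `h`.
#'
#' @param mat a [material()].
#' @param h voxel edge length in mm.
#' @return A 24x24 numeric matrix (GPa·mm).
#' @export
hex8_element_stiffness <- function(mat, h) {
  stopifnot(inherits(mat, "material"), h > 0)
  D <- iso_D(mat$E, mat$nu)
  g <- 1 / sqrt(3)
  Ke <- matrix(0, 24, 24)
  ix <- seq(1, 24, by = 3)
  for (xi in c(-g, g)) for (eta in c(-g, g)) for (zeta in c(-g, g)) {
    dNdx <- .hex_xn * (1 + eta * .hex_yn) * (1 + zeta * .hex_zn) / 8 * (2 / h)
    dNdy <- .hex_yn * (1 + xi * .hex_xn) * (1 + zeta * .hex_zn) / 8 * (2 / h)
    dNdz <- .hex_zn * (1 + xi * .hex_xn) * (1 + eta * .hex_yn) / 8 * (2 / h)
    B <- matrix(0, 6, 24)
    B[1, ix] <- dNdx; B[2, ix + 1] <- dNdy; B[3, ix + 2] <- dNdz
    B[4, ix + 1] <- dNdz; B[4, ix + 2] <- dNdy  # gamma_yz
    B[5, ix] <- dNdz; B[5, ix + 2] <- dNdx      # gamma_xz
    B[6, ix] <- dNdy; B[6, ix + 1] <- dNdx      # gamma_xy
    Ke <- Ke + crossprod(B, D %*% B) * (h / 2)^3
  }
  Ke
}

# Linear node id on the (R+1)^3 corner grid, axis order x fastest.
node_id <- function(i, j, k, Np) (k - 1L) * Np * Np + (j - 1L) * Np + i

# Node ids of one outer face of the grid.
face_nodes <- function(Np, axis, side) {
  idx <- if (side == "min") 1L else Np
  rng <- seq_len(Np)
  g <- switch(axis,
    x = expand.grid(i = idx, j = rng, k = rng),
    y = expand.grid(i = rng, j = idx, k = rng),
    z = expand.grid(i = rng, j = rng, k = idx),
    stop_cfg("unknown axis: %s", axis))
  node_id(g$i, g$j, g$k, Np)
}

# Drop solid voxels not face-connected to the largest solid component.
# Floating islands would make the constrained system singular.
filter_components <- function(occ) {
  R <- dim(occ)[1]
  lin <- array(0L, dim(occ))
  sol <- which(occ)
  lin[sol] <- seq_along(sol)
  edge_pairs <- function(shift_dim) {
    idx <- slice.index(occ, shift_dim)
    a <- which(occ & idx < R)
    step <- c(1L, R, R * R)[shift_dim]
    b <- a + step
    keep <- occ[b]
    cbind(lin[a[keep]], lin[b[keep]])
  }
  edges <- rbind(edge_pairs(1L), edge_pairs(2L), edge_pairs(3L))
  if (nrow(edges) == 0L) {
    keep <- sol[1]  # all voxels isolated: keep one, drop the rest
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(sol) - igraph::vcount(g)))
    comp <- igraph::components(g)
    keep <- sol[comp$membership == which.max(comp$csize)]
  }
  out <- array(FALSE, dim(occ))
  out[keep] <- TRUE
  list(occupancy = out, removed = length(sol) - length(keep))
}

#' Assemble the global sparse stiffness system of a voxel model
#'
#' One trilinear hexahedral element per solid voxel, sharing corner nodes with
#' face-adjacent solid voxels. Solid voxels not connected to the largest
#' face-connected component are removed before assembly (floating islands have
#' no load path and would make the system singular). Nodes belonging to no
#' solid element carry no stiffness and are excluded from every solve.
#'
#' @param v a `voxel_model`.
#' @param mat a [material()]; defaults to the model config's `E`, `nu`.
#' @return A `fem_system`: sparse symmetric `K`, element connectivity, node
#'   bookkeeping, and the number of removed floating voxels.
#' @export
assemble_system <- function(v, mat = NULL) {
  stopifnot(inherits(v, "voxel_model"))
  mat <- mat %||% material(v$config$E, v$config$nu)
  R <- v$R; Np <- R + 1L
  flt <- filter_components(v$occupancy)
  occ <- flt$occupancy
  sol <- which(occ, arr.ind = TRUE)
  if (nrow(sol) == 0L) stop_cfg("empty solid phase after component filtering")
  n000 <- node_id(sol[, 1], sol[, 2], sol[, 3], Np)
  conn <- cbind(n000,              n000 + 1L,
                n000 + 1L + Np,    n000 + Np,
                n000 + Np^2,       n000 + Np^2 + 1L,
                n000 + Np^2 + 1L + Np, n000 + Np^2 + Np)
  # conn column a corresponds to local node a of hex8_element_stiffness:
  # signs (-,-,-), (+,-,-), (+,+,-), (-,+,-), then the zeta = +1 layer.
  dofs <- matrix(0L, nrow(conn), 24L)
  for (a in 1:8) {
    base <- 3L * (conn[, a] - 1L)
    dofs[, (a - 1L) * 3L + 1:3] <- cbind(base + 1L, base + 2L, base + 3L)
  }
  Ke <- hex8_element_stiffness(mat, v$spacing)
  iv <- as.vector(dofs[, rep(1:24, times = 24)])
  jv <- as.vector(dofs[, rep(1:24, each = 24)])
  keep <- iv <= jv  # store the upper triangle once; K is symmetric
  ndof <- 3L * Np^3
  K <- Matrix::sparseMatrix(i = iv[keep], j = jv[keep],
                            x = rep(as.vector(Ke), each = nrow(conn))[keep],
                            dims = c(ndof, ndof), symmetric = TRUE)
  used_nodes <- sort(unique(as.vector(conn)))
  used_dofs <- as.vector(t(outer(3L * (used_nodes - 1L), 1:3, `+`)))
  sys <- structure(list(K = K, conn = conn, Np = Np, R = R, spacing = v$spacing,
                        L = v$config$L, mat = mat, occupancy = occ,
                        used_nodes = used_nodes, used_dofs = used_dofs,
                        removed_voxels = flt$removed,
                        factor_cache = new.env(parent = emptyenv())),
                   class = "fem_system")
  sys$boundary <- boundary_nodes(sys)
  sys
}

#' Displacement-driven load case
#'
#' @param kind `"compression"` or `"shear"`.
#' @param where for compression, the loading axis `"x"`, `"y"` or `"z"`; for
#'   shear, the plane `"yz"`, `"xz"` or `"xy"`.
#' @param d applied displacement in mm (default 0.1, i.e. 1% nominal strain on
#'   the 10 mm cube).
#' @return An object of class `load_case`.
#' @export
load_case <- function(kind = c("compression", "shear"),
                      where = "x", d = 0.1) {
  kind <- match.arg(kind)
  ok <- if (kind == "compression") c("x", "y", "z") else c("yz", "xz", "xy")
  if (!where %in% ok) stop_cfg("invalid '%s' target for %s: %s",
                               paste(ok, collapse = "/"), kind, where)
  structure(list(kind = kind, where = where, d = d), class = "load_case")
}

.ax_index <- c(x = 1L, y = 2L, z = 3L)
# shear plane -> (driven-face normal axis, displacement axis). The xy case
# drives the y-normal faces so that every axis transposition maps one
# canonical shear case exactly onto another (the realizations, not just the
# moduli, correspond): yz -> xz under x<->y, yz -> xy under x<->z.
.shear_axes <- list(yz = c("y", "z"), xz = c("x", "z"), xy = c("y", "x"))

# Displacement-gradient matrix of a load case: compression along a drives
# u_a = eps * x_a; shear in plane (a, b) drives u_b = gamma * x_a (adding the
# rotation to the symmetric shear strain changes nothing in linear elasticity).
case_gradient <- function(lc, L) {
  G <- matrix(0, 3, 3)
  if (lc$kind == "compression") {
    ai <- .ax_index[[lc$where]]
    G[ai, ai] <- lc$d / L
  } else {
    ab <- .shear_axes[[lc$where]]
    G[.ax_index[[ab[2]]], .ax_index[[ab[1]]]] <- lc$d / L
  }
  G
}

# Solid nodes on the outer box, with their coordinates (corner grid, mm).
boundary_nodes <- function(sys) {
  Np <- sys$Np
  nodes <- sort(unique(unlist(lapply(c("x", "y", "z"), function(a)
    c(face_nodes(Np, a, "min"), face_nodes(Np, a, "max"))))))
  nodes <- intersect(nodes, sys$used_nodes)
  k <- (nodes - 1L) %/% (Np * Np)
  j <- ((nodes - 1L) %% (Np * Np)) %/% Np
  i <- (nodes - 1L) %% Np
  list(nodes = nodes, coords = cbind(i, j, k) * sys$spacing)
}

# Prescribed dof set for a load case. `mode = "uniaxial"` prescribes the
# affine field u = G x on every solid node of the outer box (kinematic uniform
# boundary conditions), which makes reaction stresses stiffness-matrix columns
# and keeps the constrained dof set identical across load cases so one
# factorization serves all six. `mode = "free"` fixes the min face, drives the
# max face, and leaves the four side faces traction-free (apparent moduli).
prescribed_dofs <- function(sys, lc, mode) {
  check_span <- function(a) {
    lo <- intersect(face_nodes(sys$Np, a, "min"), sys$used_nodes)
    hi <- intersect(face_nodes(sys$Np, a, "max"), sys$used_nodes)
    if (length(lo) == 0L || length(hi) == 0L)
      stop_cfg("no spanning solid component along axis %s", a)
  }
  if (mode == "uniaxial") {
    a <- if (lc$kind == "compression") lc$where else .shear_axes[[lc$where]][1]
    check_span(a)
    bn <- sys$boundary
    G <- case_gradient(lc, sys$L)
    U <- bn$coords %*% t(G)   # nodes x 3 prescribed displacements
    idx <- as.vector(t(outer(3L * (bn$nodes - 1L), 1:3, `+`)))
    list(idx = idx, val = as.vector(t(U)))
  } else {
    idx <- integer(0); val <- numeric(0)
    add <- function(nodes, comp, value) {
      idx <<- c(idx, 3L * (nodes - 1L) + comp)
      val <<- c(val, rep(value, length(nodes)))
    }
    fnodes <- function(axis, side)
      intersect(face_nodes(sys$Np, axis, side), sys$used_nodes)
    a <- if (lc$kind == "compression") lc$where else .shear_axes[[lc$where]][1]
    check_span(a)
    lo <- fnodes(a, "min"); hi <- fnodes(a, "max")
    for (comp in 1:3) add(lo, comp, 0)
    if (lc$kind == "compression") {
      add(hi, .ax_index[[a]], lc$d)
    } else {
      ab <- .shear_axes[[lc$where]]
      add(hi, .ax_index[[ab[2]]], lc$d)
      add(hi, .ax_index[[ab[1]]], 0)
    }
    keep <- !duplicated(idx)
    list(idx = idx[keep], val = val[keep])
  }
}

#' Solve one displacement-driven load case
#'
#' Partitions the assembled system into prescribed and free DOFs, solves the
#' free block by sparse (supernodal) Cholesky factorization, and returns the
#' full displacement and reaction-force vectors.
#'
#' @param sys a `fem_system` from [assemble_system()].
#' @param lc a [load_case()].
#' @param mode `"uniaxial"` (default; outer box roller-constrained so that
#'   reaction stresses are stiffness-matrix entries) or `"free"` (only the two
#'   driven faces constrained; yields apparent moduli).
#' @return List with `u` (displacements, mm), `force` (nodal forces `K u`,
#'   GPa·mm²), and the prescribed dof set.
#' @export
solve_load_case <- function(sys, lc, mode = c("uniaxial", "free")) {
  stopifnot(inherits(sys, "fem_system"), inherits(lc, "load_case"))
  mode <- match.arg(mode)
  pres <- prescribed_dofs(sys, lc, mode)
  ndof <- nrow(sys$K)
  u <- numeric(ndof)
  u[pres$idx] <- pres$val
  free <- setdiff(sys$used_dofs, pres$idx)
  if (length(free) > 0L) {
    # the constrained dof set depends only on the mode (and, for "free", the
    # case), so the factorization is cached and reused across load cases
    ckey <- if (mode == "uniaxial") "kubc" else paste0("free|", lc$kind, lc$where)
    fc <- cache_get(sys$factor_cache, ckey)
    if (is.null(fc)) {
      Kff <- sys$K[free, free]
      ch <- tryCatch(
        Matrix::Cholesky(Kff, perm = TRUE, LDL = FALSE, super = TRUE),
        error = function(e)
          stop_cfg("singular stiffness system (%d constrained of %d used dofs): %s",
                   length(pres$idx), length(sys$used_dofs), conditionMessage(e)))
      fc <- list(ch = ch, free = free)
      cache_set(sys$factor_cache, ckey, fc)
    }
    b <- -(sys$K %*% u)[free]
    u[free] <- as.vector(Matrix::solve(fc$ch, b))
  }
  force <- as.vector(sys$K %*% u)
  list(u = u, force = force, prescribed = pres, mode = mode)
}

# Sum of reaction-force components `comp` over the outer face (axis, side).
face_reaction <- function(sys, force, axis, side, comp) {
  nodes <- intersect(face_nodes(sys$Np, axis, side), sys$used_nodes)
  sum(force[3L * (nodes - 1L) + comp])
}

#' Effective stiffness matrix by voxel FE homogenization
#'
#' Runs displacement-driven compression load cases along the requested axes
#' and simple-shear cases in the requested planes, and converts total face
#' reactions into entries of the effective 6x6 Voigt stiffness matrix
#' (1 = xx, 2 = yy, 3 = zz, 4 = yz, 5 = xz, 6 = xy):
#' `C_aa = (F_a / A) / (d / L)` for compression along `a`, likewise for shear,
#' and in `"uniaxial"` mode the off-diagonals `C12`, `C13`, `C23` from the
#' transverse roller reactions of the compression cases. The normal block is
#' symmetrized by averaging. Entries whose load case was not requested are
#' `NA`.
#'
#' @param v a `voxel_model`.
#' @param mat a [material()]; defaults to the config's constants.
#' @param compression axes to load in compression (subset of x, y, z).
#' @param shear planes to load in shear (subset of yz, xz, xy; character(0)
#'   to skip shear).
#' @param d applied displacement in mm.
#' @param mode boundary-condition mode, see [solve_load_case()].
#' @return A 6x6 `stiffness_matrix` (GPa) with metadata attributes.
#' @export
homogenize <- function(v, mat = NULL, compression = c("x", "y", "z"),
                       shear = c("yz", "xz", "xy"), d = 0.1,
                       mode = c("uniaxial", "free")) {
  stopifnot(inherits(v, "voxel_model"))
  mode <- match.arg(mode)
  mat <- mat %||% material(v$config$E, v$config$nu)
  sys <- assemble_system(v, mat)
  L <- sys$L; A <- L^2; eps <- d / L
  C <- matrix(NA_real_, 6, 6)
  for (a in compression) {
    ai <- .ax_index[[a]]
    sol <- solve_load_case(sys, load_case("compression", a, d), mode = mode)
    for (b in c("x", "y", "z")) {
      bi <- .ax_index[[b]]
      C[bi, ai] <- face_reaction(sys, sol$force, b, "max", bi) / A / eps
    }
  }
  for (p in shear) {
    vi <- match(p, c("yz", "xz", "xy")) + 3L
    ab <- .shear_axes[[p]]
    sol <- solve_load_case(sys, load_case("shear", p, d), mode = mode)
    C[vi, vi] <- face_reaction(sys, sol$force, ab[1], "max", .ax_index[[ab[2]]]) / A / eps
  }
  # average the normal block where both transposed entries were measured
  for (i in 1:3) for (j in 1:3) {
    if (i < j && !is.na(C[i, j]) && !is.na(C[j, i])) {
      m <- (C[i, j] + C[j, i]) / 2
      C[i, j] <- m; C[j, i] <- m
    }
  }
  if (mode == "free") {
    # free lateral faces carry no reaction: off-diagonals are not measurable
    blk <- C[1:3, 1:3]
    blk[diag(3) == 0] <- NA_real_
    C[1:3, 1:3] <- blk
  }
  structure(C, class = c("stiffness_matrix", class(C)),
            R = v$R, mode = mode, E = mat$E, nu = mat$nu, L = L,
            removed_voxels = sys$removed_voxels,
            config = v$config)
}

#' @export
print.stiffness_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Effective stiffness matrix (GPa), R = %s, mode = %s:\n",
              attr(x, "R"), attr(x, "mode")))
  m <- matrix(as.numeric(x), 6, 6,
              dimnames = list(paste0("C", 1:6, "."), paste0(".", 1:6)))
  print(round(m, digits))
  invisible(x)
}

#' Resolution-convergence check for one stiffness entry
#'
#' Homogenizes the same design point at a coarse and a fine resolution
#' (recalibrating the threshold at each) and reports the relative drift
#' `|C(coarse) - C(fine)| / |C(fine)|`. A drift above `warn_above` raises a
#' warning: the coarse grid is then too coarse to trust for this structure.
#'
#' @param config a [tpms_config()] (its `t` is recalibrated per resolution).
#' @param R_coarse,R_fine the two resolutions (defaults 32 and 48).
#' @param entry stiffness entry to track (default `"C11"`).
#' @param mat a [material()].
#' @param warn_above relative-drift warning threshold (default 0.10).
#' @return List with `coarse`, `fine` (GPa) and `drift` (fraction).
#' @export
resolution_drift <- function(config, R_coarse = 32, R_fine = 48,
                             entry = "C11", mat = NULL, warn_above = 0.10) {
  stopifnot(inherits(config, "tpms_config"))
  lc <- cases_for_entries(entry)
  value_at <- function(R) {
    t <- calibrate_t(config$c, config$m, config$n, config$l, config$phi,
                     R = R, L = config$L)
    cfg <- tpms_config(config$c, config$phi, config$m, config$n, config$l,
                       t = t, L = config$L, E = config$E, nu = config$nu)
    C <- homogenize(voxelize(cfg, R), mat, compression = lc$compression,
                    shear = lc$shear)
    extract_entries(C, entry)
  }
  coarse <- value_at(R_coarse)
  fine <- value_at(R_fine)
  drift <- abs(coarse - fine) / abs(fine)
  if (is.finite(drift) && drift > warn_above)
    warning(sprintf("%s drifts %.1f%% between R = %d and R = %d",
                    entry, 100 * drift, R_coarse, R_fine), call. = FALSE)
  list(coarse = unname(coarse), fine = unname(fine), drift = unname(drift))
}

#' Closed-form isotropic stiffness entries
#'
#' The fully dense isotropic reference values
#' `C11 = E(1-nu)/((1+nu)(1-2nu))`, `C12 = E nu/((1+nu)(1-2nu))`,
#' `C44 = E/(2(1+nu))`, used as the analytic oracle for a fully solid grid and
#' as Voigt upper bounds for porous structures.
#'
#' @param mat a [material()].
#' @return Named vector with `C11`, `C12`, `C44` (GPa).
#' @export
iso_stiffness <- function(mat) {
  E <- mat$E; nu <- mat$nu
  c(C11 = E * (1 - nu) / ((1 + nu) * (1 - 2 * nu)),
    C12 = E * nu / ((1 + nu) * (1 - 2 * nu)),
    C44 = E / (2 * (1 + nu)))
}
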