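# Regenerative genetic algorithm: searches (c, phi, m, n, l) for the design
# whose surrogate-predicted directional moduli best match a target partial
# stiffness matrix. The "regeneration" step evaluates each individual together
# with two axis-permuted siblings so that single-output forward networks yield
# moduli in all three directions.

primary_names <- c("C11", "C22", "C33")
secondary_names <- c("C44", "C55", "C66")
verification_names <- c("C12", "C13", "C23")

#' Design target: requested stiffness entries with roles
#'
#' The compressive moduli `C11, C22, C33` are the primary design target, the
#' shear moduli `C44, C55, C66` the secondary target, and the compression
#' off-diagonals `C12, C13, C23` are verification-only: they are reported
#' after FE re-verification but never enter the GA fitness.
#'
#' @param primary named numeric vector with names among C11, C22, C33 (GPa);
#'   at least one entry is required.
#' @param secondary named numeric vector with names among C44, C55, C66.
#' @param verification named numeric vector with names among C12, C13, C23.
#' @return A `design_target` data frame with columns `entry`, `value`, `role`.
#' @export
design_target <- function(primary, secondary = NULL, verification = NULL) {
  chk <- function(x, allowed, role) {
    if (is.null(x) || length(x) == 0L) return(NULL)
    if (is.null(names(x)) || !all(names(x) %in% allowed))
      stop_cfg("%s entries must be named among %s", role,
               paste(allowed, collapse = ", "))
    data.frame(entry = names(x), value = as.numeric(x), role = role)
  }
  tgt <- rbind(chk(primary, primary_names, "primary"),
               chk(secondary, secondary_names, "secondary"),
               chk(verification, verification_names, "verification"))
  if (is.null(tgt) || !any(tgt$role == "primary"))
    stop_cfg("design target needs at least one primary entry (C11/C22/C33)")
  if (anyDuplicated(tgt$entry)) stop_cfg("duplicate target entries")
  structure(tgt, class = c("design_target", "data.frame"))
}

#' Regenerate the axis-permuted siblings of a design point
#'
#' Returns the two arrangement transpositions that move the y-count and the
#' z-count into the canonical (x) loading slot: `(m, n, l) -> (n, m, l)` and
#' `(l, n, m)`. Probing the forward networks on the original and both siblings
#' yields the compressive moduli C11, C22, C33 and the shear moduli C44, C55,
#' C66 of the *original* structure: the sibling's canonical modulus equals the
#' original's modulus in the permuted direction. The threshold `t` is copied:
#' on a cubic voxel grid the solid fraction is exactly invariant under axis
#' relabelling (including the Gyroid's mirror), so recalibration is a no-op.
#'
#' @param config a [tpms_config()].
#' @return List of two `tpms_config` siblings.
#' @export
regenerate <- function(config) {
  stopifnot(inherits(config, "tpms_config"))
  sib <- function(m, n, l) tpms_config(config$c, config$phi, m, n, l,
                                       t = config$t, L = config$L,
                                       E = config$E, nu = config$nu)
  list(sib(config$n, config$m, config$l),   # x <-> y : canonical slot reads C22/C55
       sib(config$l, config$n, config$m))   # x <-> z : canonical slot reads C33/C66
}

# Ensure a population data frame has a calibrated threshold column.
fill_thresholds <- function(pop, cal_R, L = 10) {
  t <- numeric(nrow(pop))
  for (i in seq_len(nrow(pop)))
    t[i] <- calibrate_t(pop$c[i], pop$m[i], pop$n[i], pop$l[i], pop$phi[i],
                        R = cal_R, L = L)
  pop$t <- t
  pop
}

# Predicted directional moduli for a population data frame (c, phi, t, m, n, l).
# Returns a matrix with columns C11, C22, C33 (from bpnn1 on the individual and
# its two siblings) and C44, C55, C66 (same probes through bpnn2).
predict_directional <- function(pop, bpnn1, bpnn2 = NULL,
                                want_shear = !is.null(bpnn2)) {
  base <- function(m, n, l) cbind(c = pop$c, phi = pop$phi, t = pop$t,
                                  m = m, n = n, l = l)
  X0 <- base(pop$m, pop$n, pop$l)
  X1 <- base(pop$n, pop$m, pop$l)
  X2 <- base(pop$l, pop$n, pop$m)
  np <- nrow(pop)
  p1 <- as.vector(predict(bpnn1, rbind(X0, X1, X2)))
  out <- cbind(C11 = p1[seq_len(np)],
               C22 = p1[np + seq_len(np)],
               C33 = p1[2L * np + seq_len(np)])
  if (want_shear) {
    p2 <- as.vector(predict(bpnn2, rbind(X0, X1, X2)))
    out <- cbind(out,
                 C44 = p2[seq_len(np)],
                 C55 = p2[np + seq_len(np)],
                 C66 = p2[2L * np + seq_len(np)])
  }
  out
}

# Sum of absolute mismatches over the targeted (primary + secondary) entries.
population_fitness <- function(pop, target, bpnn1, bpnn2, cal_R) {
  pop <- fill_thresholds(pop, cal_R)
  tgt <- target[target$role %in% c("primary", "secondary"), ]
  pred <- predict_directional(pop, bpnn1, bpnn2,
                              want_shear = any(tgt$role == "secondary"))
  fit <- numeric(nrow(pop))
  for (r in seq_len(nrow(tgt)))
    fit <- fit + abs(pred[, tgt$entry[r]] - tgt$value[r])
  fit
}

#' Fitness of one individual
#'
#' Queries BPNN1 on the individual and its two regeneration siblings for
#' `C11, C22, C33`, and BPNN2 likewise for `C44, C55, C66`, then sums the
#' absolute differences to the targeted entries (smaller is better; entries
#' absent from the target contribute nothing; verification entries never enter).
#'
#' @param config a [tpms_config()] (its `t` is recalibrated at the surrogate's
#'   training resolution if missing).
#' @param target a [design_target()].
#' @param bpnn1,bpnn2 trained surrogates for the compressive and shear moduli.
#' @return Nonnegative scalar fitness.
#' @export
fitness <- function(config, target, bpnn1, bpnn2 = NULL) {
  stopifnot(inherits(config, "tpms_config"))
  cal_R <- bpnn1$meta$R %||% 32
  pop <- data.frame(c = config$c, phi = config$phi, m = config$m,
                    n = config$n, l = config$l)
  if (!is.null(config$t)) pop$t <- config$t
  if (is.null(pop$t)) pop <- fill_thresholds(pop, cal_R)
  tgt <- target[target$role %in% c("primary", "secondary"), ]
  if (any(tgt$role == "secondary") && is.null(bpnn2))
    stop_cfg("secondary target entries need a trained shear surrogate (bpnn2)")
  pred <- predict_directional(pop, bpnn1, bpnn2,
                              want_shear = any(tgt$role == "secondary"))
  sum(abs(pred[1, tgt$entry] - tgt$value))
}

#' Genetic-algorithm parameters
#'
#' @param population initial population size (default 4000; desk-scale runs
#'   use 400).
#' @param elite number of best individuals kept after merging parents and
#'   offspring each generation (default 2000; must not exceed `population`).
#' @param p_mut_max,p_mut_min rank-linear probability that an individual
#'   participates in variation: the worst individual varies with `p_mut_max`,
#'   the best with `p_mut_min`.
#' @param p_cross one-point crossover probability per participant pair.
#' @param p_gene per-gene probability of a +/-1 step on each of m, n, l.
#' @param p_phi probability of perturbing phi; `phi_sd` the Gaussian step.
#' @param p_cell probability of resampling the family label.
#' @param phi_sd standard deviation of the porosity perturbation.
#' @param patience stop after this many consecutive generations without
#'   improvement of the best fitness (default 20).
#' @param max_gen hard generation cap.
#' @param seed RNG seed for the whole run.
#' @return A `ga_params` list.
#' @export
ga_params <- function(population = 4000, elite = 2000, p_mut_max = 0.9,
                      p_mut_min = 0.2, p_cross = 0.8, p_gene = 0.3,
                      p_phi = 0.5, p_cell = 0.1, phi_sd = 0.02,
                      patience = 20, max_gen = 500, seed = 1) {
  if (elite > population) stop_cfg("elite count must not exceed population size")
  if (population < 2) stop_cfg("population must be at least 2")
  structure(list(population = population, elite = elite,
                 p_mut_max = p_mut_max, p_mut_min = p_mut_min,
                 p_cross = p_cross, p_gene = p_gene, p_phi = p_phi,
                 p_cell = p_cell, phi_sd = phi_sd, patience = patience,
                 max_gen = max_gen, seed = seed),
            class = "ga_params")
}

#' Initial random population
#'
#' @param nsize population size (>= 2).
#' @param ranges design-space ranges, see [design_ranges()].
#' @param seed RNG seed.
#' @return Data frame with columns `c, phi, m, n, l`.
#' @export
init_population <- function(nsize, ranges = design_ranges(), seed = 1) {
  if (nsize < 2) stop_cfg("population must be at least 2")
  with_seed(seed, {
    data.frame(c = sample(ranges$c, nsize, replace = TRUE),
               phi = stats::runif(nsize, ranges$phi[1], ranges$phi[2]),
               m = sample(seq(ranges$mnl[1], ranges$mnl[2]), nsize, TRUE),
               n = sample(seq(ranges$mnl[1], ranges$mnl[2]), nsize, TRUE),
               l = sample(seq(ranges$mnl[1], ranges$mnl[2]), nsize, TRUE))
  })
}

# Variation operators. `pop` must carry a `fitness` column.
vary_population <- function(pop, params, ranges) {
  N <- nrow(pop)
  rk <- rank(pop$fitness, ties.method = "first")  # 1 = best
  p_part <- params$p_mut_min +
    (params$p_mut_max - params$p_mut_min) * (rk - 1) / max(N - 1, 1)
  part <- which(stats::runif(N) < p_part)
  if (length(part) < 2L) part <- order(pop$fitness, decreasing = TRUE)[1:2]
  part <- part[sample.int(length(part))]
  if (length(part) %% 2L == 1L) part <- part[-length(part)]
  genes <- c("c", "phi", "m", "n", "l")
  kids <- pop[part, genes]
  # one-point crossover on the chromosome tuple
  for (i in seq(1L, length(part) - 1L, by = 2L)) {
    if (stats::runif(1) < params$p_cross) {
      cut <- sample.int(length(genes) - 1L, 1L)
      a <- kids[i, ]; b <- kids[i + 1L, ]
      kids[i, (cut + 1L):length(genes)] <- b[(cut + 1L):length(genes)]
      kids[i + 1L, (cut + 1L):length(genes)] <- a[(cut + 1L):length(genes)]
    }
  }
  nk <- nrow(kids)
  # +/-1 integer steps, clipped to bounds
  for (g in c("m", "n", "l")) {
    hit <- stats::runif(nk) < params$p_gene
    step <- sample(c(-1L, 1L), nk, replace = TRUE)
    kids[[g]] <- pmin(pmax(kids[[g]] + hit * step, ranges$mnl[1]), ranges$mnl[2])
  }
  hit <- stats::runif(nk) < params$p_phi
  kids$phi <- pmin(pmax(kids$phi + hit * stats::rnorm(nk, 0, params$phi_sd),
                        ranges$phi[1]), ranges$phi[2])
  hit <- stats::runif(nk) < params$p_cell
  kids$c[hit] <- sample(ranges$c, sum(hit), replace = TRUE)
  kids
}

#' One generation of the regenerative GA
#'
#' Individuals participate in variation with a probability that decreases
#' linearly with fitness rank (the best are mostly preserved), participants
#' undergo one-point crossover and bounded mutation, offspring are evaluated,
#' and the merged parent + offspring pool is truncated to the `elite` best.
#' Elitism guarantees the best fitness never increases.
#'
#' @param pop population data frame with an evaluated `fitness` column.
#' @param target a [design_target()].
#' @param bpnn1,bpnn2 trained surrogates.
#' @param params a [ga_params()].
#' @param ranges design-space ranges.
#' @param fitness_fn optional replacement fitness function
#'   `function(pop_df) -> numeric`, used mainly for testing the GA mechanics.
#' @return List with the truncated `pop` and the current `best` row.
#' @export
rga_step <- function(pop, target, bpnn1, bpnn2, params,
                     ranges = design_ranges(), fitness_fn = NULL) {
  eval_fn <- fitness_fn %||% function(p)
    population_fitness(p, target, bpnn1, bpnn2, cal_R = bpnn1$meta$R %||% 32)
  kids <- vary_population(pop, params, ranges)
  if (nrow(kids) > 0L) {
    kids$fitness <- eval_fn(kids)
    merged <- rbind(pop[, names(kids)], kids)
  } else merged <- pop
  merged <- merged[order(merged$fitness), ]
  keep <- merged[seq_len(min(params$elite, nrow(merged))), ]
  rownames(keep) <- NULL
  list(pop = keep, best = keep[1L, ])
}

#' Run the regenerative genetic algorithm
#'
#' Searches the scaffold design space for the structure whose surrogate-
#' predicted directional moduli best match the target. Iterates [rga_step()]
#' until the best fitness has not improved for `params$patience` consecutive
#' generations (or `params$max_gen` is reached). The whole run is
#' deterministic for a fixed `params$seed`.
#'
#' @inheritParams rga_step
#' @return A `design_result`: `best` (a [tpms_config()] with calibrated `t`),
#'   `predicted` (all six directional moduli at the winner), `fitness`,
#'   `generations`, `history` (per-generation best fitness), and `near_best`
#'   (distinct chromosomes within 5% of the best fitness in the final pool).
#' @export
run_rga <- function(target, bpnn1, bpnn2 = NULL, params = ga_params(),
                    ranges = design_ranges(), fitness_fn = NULL) {
  if (is.null(fitness_fn)) {
    stopifnot(inherits(bpnn1, "bpnn"))
    if (any(target$role == "secondary") && is.null(bpnn2))
      stop_cfg("secondary target entries need a trained shear surrogate (bpnn2)")
  }
  cal_R <- if (!is.null(bpnn1)) bpnn1$meta$R %||% 32 else 32
  eval_fn <- fitness_fn %||% function(p)
    population_fitness(p, target, bpnn1, bpnn2, cal_R = cal_R)
  with_seed(params$seed, {
    pop <- init_population(params$population, ranges,
                           seed = derive_seed(params$seed, "init"))
    pop$fitness <- eval_fn(pop)
    pop <- pop[order(pop$fitness), ]
    best <- pop$fitness[1L]
    history <- data.frame(generation = 1L, best_fitness = best)
    stall <- 0L
    gen <- 1L
    while (stall < params$patience && gen < params$max_gen) {
      st <- rga_step(pop, target, bpnn1, bpnn2, params, ranges, fitness_fn)
      pop <- st$pop
      gen <- gen + 1L
      if (st$best$fitness < best - 1e-12) {
        best <- st$best$fitness
        stall <- 0L
      } else stall <- stall + 1L
      history <- rbind(history,
                       data.frame(generation = gen, best_fitness = best))
    }
    # return the best individual whose geometry is realizable at the working
    # resolution (surrogate queries alone cannot tell a broken load path)
    wi <- 1L
    if (is.null(fitness_fn)) {
      while (wi <= nrow(pop)) {
        w <- pop[wi, ]
        cand <- tpms_config(w$c, w$phi, w$m, w$n, w$l,
                            t = calibrate_t(w$c, w$m, w$n, w$l, w$phi, R = cal_R))
        if (is_feasible(cand, cal_R)) break
        wi <- wi + 1L
      }
      if (wi > nrow(pop)) {
        warning("no individual in the final population is realizable at the ",
                "working resolution; returning the fitness-best one", call. = FALSE)
        wi <- 1L
      }
    }
    winner <- pop[wi, ]
    best_cfg <- tpms_config(winner$c, winner$phi, winner$m, winner$n, winner$l,
                            t = calibrate_t(winner$c, winner$m, winner$n,
                                            winner$l, winner$phi, R = cal_R))
    predicted <- if (is.null(fitness_fn)) {
      pw <- fill_thresholds(winner[, c("c", "phi", "m", "n", "l")], cal_R)
      drop(predict_directional(pw, bpnn1, bpnn2, want_shear = !is.null(bpnn2)))
    } else NULL
    thr <- if (winner$fitness > 0) winner$fitness * 1.05 else winner$fitness + 1e-9
    nb <- pop[pop$fitness <= thr, c("c", "phi", "m", "n", "l", "fitness")]
    nb <- nb[!duplicated(nb[, c("c", "phi", "m", "n", "l")]), ]
    structure(list(best = best_cfg, predicted = predicted,
                   fitness = winner$fitness, generations = gen,
                   history = history, near_best = nb, target = target,
                   params = params),
              class = "design_result")
  })
}

#' @export
print.design_result <- function(x, ...) {
  cat("Inverse-design result\n")
  print(x$best)
  cat(sprintf("  fitness %.4g after %d generations; %d near-best chromosomes\n",
              x$fitness, x$generations, nrow(x$near_best)))
  if (!is.null(x$predicted)) {
    cat("  predicted moduli (GPa):\n")
    print(round(x$predicted, 4))
  }
  invisible(x)
}
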