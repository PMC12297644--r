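#' Configuration for the Archimedes Optimization Algorithm
#'
#' The AOA is a population metaheuristic in which candidate solutions are
#' "objects" immersed in a fluid, carrying a density, a volume and an
#' acceleration that are updated by buoyancy-inspired rules. A transfer
#' operator moves the search from a collision-rich exploration phase to
#' an exploitation phase around the incumbent best.
#'
#' Two formula dialects are provided. `"canonical"` follows the AOA
#' literature (density factor `exp((max_iter - t)/max_iter) - t/max_iter`,
#' exploitation step anchored on the best position). `"paper"` keeps the
#' variant in which the density-factor exponent is negated and the
#' exploitation step scales a random object's position instead; it is
#' retained for fidelity checks and converges less reliably.
#'
#' @param dim problem dimension.
#' @param lower,upper numeric bounds, recycled to length `dim`.
#' @param pop_size number of objects (default 50).
#' @param max_iter number of iterations (default 100).
#' @param c_explore,c_exploit,c_T acceleration constants for the
#'   exploration step, the exploitation step and the time-scaled anchor
#'   (defaults 2, 6, 2).
#' @param K4 threshold constant of the direction flag (default 0.5).
#' @param chi,lam normalization span and floor for the acceleration
#'   (defaults 0.9 and 0.1; outputs lie in `[lam, lam + chi]`).
#' @param dialect `"canonical"` or `"paper"`.
#' @param seed optional integer seed; runs with the same seed are
#'   bitwise reproducible.
#' @return an object of class `aoa_config`.
#' @export
aoa_config <- function(dim, lower, upper, pop_size = 50L, max_iter = 100L,
                       c_explore = 2, c_exploit = 6, c_T = 2, K4 = 0.5,
                       chi = 0.9, lam = 0.1,
                       dialect = c("canonical", "paper"), seed = NULL) {
  dialect <- match.arg(dialect)
  if (!is_count(dim)) stopf("`dim` must be a positive integer")
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower > upper)) stopf("lower bounds must not exceed upper bounds")
  if (!is_count(pop_size) || pop_size < 2) stopf("`pop_size` must be >= 2")
  if (!is_count(max_iter)) stopf("`max_iter` must be a positive integer")
  if (chi <= 0 || lam < 0 || chi + lam > 1)
    stopf("need 0 < chi, 0 <= lam, chi + lam <= 1")
  structure(list(dim = as.integer(dim), lower = lower, upper = upper,
                 pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 c_explore = c_explore, c_exploit = c_exploit, c_T = c_T,
                 K4 = K4, chi = chi, lam = lam, dialect = dialect,
                 seed = seed),
            class = "aoa_config")
}

#' Transfer operator of the AOA
#'
#' `exp((t - max_t)/max_t)`: strictly increasing in `t`, equal to 1 at
#' the final iteration. Values at or below 0.5 select the exploration
#' (collision) branch; above 0.5, the exploitation branch.
#'
#' @param t iteration, `1 <= t <= max_t`.
#' @param max_t total iterations.
#' @return scalar in `(exp(-1), 1]`.
#' @export
aoa_transfer_operator <- function(t, max_t) {
  if (!is_count(max_t)) stopf("`max_t` must be a positive integer")
  exp((t - max_t) / max_t)
}

#' Density decrease factor of the AOA
#'
#' A step-size schedule that shrinks to exactly 0 at the final
#' iteration. The paper dialect is
#' `exp((t - max_t)/max_t) - t/max_t`; the canonical dialect is
#' `exp((max_t - t)/max_t) - t/max_t`.
#'
#' @inheritParams aoa_transfer_operator
#' @param dialect `"canonical"` or `"paper"`.
#' @return scalar, non-negative on `[1, max_t]`, zero at `t = max_t`.
#' @export
aoa_density_factor <- function(t, max_t, dialect = c("canonical", "paper")) {
  dialect <- match.arg(dialect)
  if (!is_count(max_t)) stopf("`max_t` must be a positive integer")
  if (dialect == "paper") exp((t - max_t) / max_t) - t / max_t
  else exp((max_t - t) / max_t) - t / max_t
}

#' Pull an object's density and volume toward the best object's
#'
#' `Den' = Den + R (Den_best - Den)` and likewise for the volume, with a
#' fresh uniform draw per component. The position is untouched.
#'
#' @param den,vol object density and volume vectors.
#' @param den_best,vol_best the incumbent best object's density/volume.
#' @param r optional forced uniform draws (for testing); default fresh
#'   `runif` per component.
#' @return list with elements `den` and `vol`.
#' @export
aoa_update_density_volume <- function(den, vol, den_best, vol_best, r = NULL) {
  r1 <- if (is.null(r)) runif(length(den)) else rep_len(r, length(den))
  r2 <- if (is.null(r)) runif(length(vol)) else rep_len(r, length(vol))
  list(den = den + r1 * (den_best - den),
       vol = vol + r2 * (vol_best - vol))
}

#' Object acceleration from a reference object
#'
#' `ACL' = (Den_ref + Vol_ref * ACL_ref) / (Den' * Vol')` componentwise,
#' where `Den'`/`Vol'` are the object's post-update density and volume.
#' In the exploration phase the reference is a random material (its
#' previous-iteration properties); in the exploitation phase it is the
#' best object. Denominators are floored at `eps` to avoid blow-ups.
#'
#' @param den_ref,vol_ref,acl_ref reference object properties.
#' @param den_new,vol_new the object's updated density and volume.
#' @param eps denominator floor (default 1e-12).
#' @return acceleration vector.
#' @export
aoa_acceleration <- function(den_ref, vol_ref, acl_ref, den_new, vol_new,
                             eps = 1e-12) {
  a <- (den_ref + vol_ref * acl_ref) / pmax(den_new * vol_new, eps)
  # raw accelerations can grow geometrically over long runs; clamp to a
  # large finite bound so the population-wide normalization stays defined
  pmin(pmax(a, -1e300), 1e300)
}

#' Normalize accelerations over the population
#'
#' Per component (column), rescale to `[lam, lam + chi]`:
#' `chi * (a - min)/(max - min) + lam`. When a column is constant the
#' value `lam + chi/2` is returned so motion never freezes.
#'
#' @param acl matrix, one row per object, one column per dimension.
#' @param chi,lam normalization span and floor.
#' @return matrix of the same shape with entries in `[lam, lam + chi]`.
#' @export
aoa_normalize_acceleration <- function(acl, chi = 0.9, lam = 0.1) {
  acl <- as.matrix(acl)
  lo <- apply(acl, 2, min)
  hi <- apply(acl, 2, max)
  span <- hi - lo
  out <- acl
  for (j in seq_len(ncol(acl))) {
    if (span[j] == 0) out[, j] <- lam + chi / 2
    else out[, j] <- chi * (acl[, j] - lo[j]) / span[j] + lam
  }
  out
}

#' Direction flag of the exploitation step
#'
#' Draws `R ~ U(0,1)`, sets `I = 2R - K4`, and returns `+1` when
#' `I <= 0.5`, else `-1`.
#'
#' @param r optional forced draw (for testing).
#' @param K4 threshold constant (default 0.5).
#' @return `+1` or `-1`.
#' @export
aoa_select_flag <- function(r = NULL, K4 = 0.5) {
  if (K4 < 0) stopf("`K4` must be non-negative")
  if (is.null(r)) r <- runif(1)
  if (2 * r - K4 <= 0.5) 1 else -1
}

#' One position update of the AOA
#'
#' Exploration (`phase = "exploration"`):
#' `Z' = Z + c_explore * R * ACL_norm * d * (Z_rand - Z)`.
#' Exploitation: `Z' = Z_best + flag * c_exploit * R * ACL_norm * d *
#' (Ts * Z_ref - Z)` with `Ts = c_T * TO`; the canonical dialect anchors
#' `Z_ref` on the best position, the paper dialect on a random object.
#' The result is clipped into the box.
#'
#' @param z current position; `z_rand` a random object's position;
#'   `z_best` the best position.
#' @param phase `"exploration"` or `"exploitation"`.
#' @param acl_norm normalized acceleration (vector).
#' @param d density factor; `to` transfer operator.
#' @param flag direction flag (exploitation only).
#' @param config an [aoa_config()].
#' @param r optional forced uniform draws per component.
#' @return updated position vector, inside `[lower, upper]`.
#' @export
aoa_update_position <- function(z, z_rand, z_best, phase, acl_norm, d, to,
                                flag = 1, config, r = NULL) {
  if (is.null(r)) r <- runif(length(z))
  if (phase == "exploration") {
    znew <- z + config$c_explore * r * acl_norm * d * (z_rand - z)
  } else {
    ts <- config$c_T * to
    z_ref <- if (config$dialect == "paper") z_rand else z_best
    znew <- z_best + flag * config$c_exploit * r * acl_norm * d *
      (ts * z_ref - z)
  }
  pmin(pmax(znew, config$lower), config$upper)
}

aoa_eval <- function(objective, Z) {
  apply(Z, 1, function(z) as.numeric(objective(z)))
}

#' Initialize an AOA population
#'
#' Positions and accelerations are drawn uniformly inside the box;
#' densities and volumes uniformly in (0, 1] (exact zeros rejected). The
#' best object is the minimum-fitness member, stored as a copy.
#'
#' @param config an [aoa_config()].
#' @param objective function mapping a length-`dim` numeric vector to a
#'   finite scalar (minimized).
#' @return an `aoa_state` list with matrices `Z`, `den`, `vol`, `acl`,
#'   fitness vector, `best` snapshot and iteration counter.
#' @export
aoa_init <- function(config, objective) {
  p <- config$pop_size; dm <- config$dim
  span <- config$upper - config$lower
  Z <- matrix(config$lower, p, dm, byrow = TRUE) +
    matrix(runif(p * dm), p, dm) * matrix(span, p, dm, byrow = TRUE)
  draw_pos <- function() {
    m <- matrix(runif(p * dm), p, dm)
    while (any(m == 0)) m[m == 0] <- runif(sum(m == 0))
    m
  }
  den <- draw_pos()
  vol <- draw_pos()
  acl <- matrix(config$lower, p, dm, byrow = TRUE) +
    matrix(runif(p * dm), p, dm) * matrix(span, p, dm, byrow = TRUE)
  fit <- aoa_eval(objective, Z)
  if (any(!is.finite(fit))) {
    bad <- which(!is.finite(fit))[1]
    stopf("objective is not finite at initial position (%s)",
          paste(signif(Z[bad, ], 6), collapse = ", "))
  }
  b <- which.min(fit)
  state <- list(Z = Z, den = den, vol = vol, acl = acl, fitness = fit,
                best = list(z = Z[b, ], den = den[b, ], vol = vol[b, ],
                            acl = acl[b, ], fitness = fit[b]),
                iter = 0L)
  class(state) <- "aoa_state"
  state
}

#' Advance the AOA by one iteration
#'
#' Updates every object's density and volume toward the best, computes
#' the transfer operator and density factor, takes the exploration or
#' exploitation branch accordingly (acceleration from a random material
#' or from the best object, normalized over the population), moves and
#' clips positions, re-evaluates the objective, and retains the best
#' solution greedily. An object whose objective evaluates to `NaN`
#' keeps its previous position (with a warning).
#'
#' @param state an `aoa_state`.
#' @inheritParams aoa_init
#' @return the advanced `aoa_state`.
#' @export
aoa_step <- function(state, objective, config) {
  p <- config$pop_size; dm <- config$dim
  t <- state$iter + 1L
  to <- aoa_transfer_operator(t, config$max_iter)
  d <- aoa_density_factor(t, config$max_iter, config$dialect)
  best <- state$best

  den_new <- state$den + matrix(runif(p * dm), p, dm) *
    (matrix(best$den, p, dm, byrow = TRUE) - state$den)
  vol_new <- state$vol + matrix(runif(p * dm), p, dm) *
    (matrix(best$vol, p, dm, byrow = TRUE) - state$vol)

  explore <- to <= 0.5
  acl_new <- matrix(0, p, dm)
  if (explore) {
    for (j in seq_len(p)) {
      mr <- sample.int(p, 1)
      acl_new[j, ] <- aoa_acceleration(state$den[mr, ], state$vol[mr, ],
                                       state$acl[mr, ],
                                       den_new[j, ], vol_new[j, ])
    }
  } else {
    for (j in seq_len(p)) {
      acl_new[j, ] <- aoa_acceleration(best$den, best$vol, best$acl,
                                       den_new[j, ], vol_new[j, ])
    }
  }
  acl_norm <- aoa_normalize_acceleration(acl_new, config$chi, config$lam)

  Z_new <- state$Z
  for (j in seq_len(p)) {
    zr <- state$Z[sample.int(p, 1), ]
    if (explore) {
      Z_new[j, ] <- aoa_update_position(state$Z[j, ], zr, best$z,
                                        "exploration", acl_norm[j, ], d, to,
                                        config = config)
    } else {
      fl <- aoa_select_flag(K4 = config$K4)
      Z_new[j, ] <- aoa_update_position(state$Z[j, ], zr, best$z,
                                        "exploitation", acl_norm[j, ], d, to,
                                        flag = fl, config = config)
    }
  }

  fit_new <- aoa_eval(objective, Z_new)
  nan <- is.nan(fit_new)
  if (any(nan)) {
    warning(sprintf("objective returned NaN for %d object(s); keeping their previous positions",
                    sum(nan)))
    Z_new[nan, ] <- state$Z[nan, , drop = FALSE]
    fit_new[nan] <- state$fitness[nan]
  }

  state$Z <- Z_new; state$den <- den_new; state$vol <- vol_new
  state$acl <- acl_new; state$fitness <- fit_new
  b <- which.min(fit_new)
  if (fit_new[b] < best$fitness) {
    state$best <- list(z = Z_new[b, ], den = den_new[b, ], vol = vol_new[b, ],
                       acl = acl_new[b, ], fitness = fit_new[b])
  }
  state$iter <- t
  state
}

#' Minimize an objective with the Archimedes Optimization Algorithm
#'
#' Runs `max_iter` iterations of [aoa_step()] from a fresh population
#' and returns the best position found, its fitness, and the best-so-far
#' fitness trace (non-increasing by construction). With a `seed` in the
#' config the run is bitwise reproducible.
#'
#' @inheritParams aoa_init
#' @return an object of class `aoa_result` with elements
#'   `best_position`, `best_fitness`, `history`, `dialect`, `config`.
#' @examples
#' cfg <- aoa_config(dim = 1, lower = 0, upper = 10, pop_size = 20,
#'                   max_iter = 50, seed = 1)
#' res <- aoa_optimize(function(z) (z - 3)^2, cfg)
#' res$best_position
#' @export
aoa_optimize <- function(objective, config) {
  stopifnot(inherits(config, "aoa_config"))
  local_seed(config$seed, {
    state <- aoa_init(config, objective)
    history <- numeric(config$max_iter)
    for (t in seq_len(config$max_iter)) {
      state <- aoa_step(state, objective, config)
      history[t] <- state$best$fitness
    }
    structure(list(best_position = state$best$z,
                   best_fitness = state$best$fitness,
                   history = history, dialect = config$dialect,
                   config = config),
              class = "aoa_result")
  })
}

#' @export
print.aoa_result <- function(x, ...) {
  cat("Archimedes Optimization Algorithm result (", x$dialect,
      " dialect)\n", sep = "")
  cat("  dimensions :", x$config$dim, "\n")
  cat("  budget     :", x$config$pop_size, "objects x",
      x$config$max_iter, "iterations\n")
  cat("  best f     :", format(x$best_fitness, digits = 8), "\n")
  cat("  best z     :", paste(signif(x$best_position, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.aoa_result <- function(x, ...) {
  plot(seq_along(x$history), x$history, type = "l",
       xlab = "iteration", ylab = "best fitness so far",
       main = "AOA convergence", ...)
  invisible(x)
}
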