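#' @title Ensemble calibration and model selection
#' @name calibrate
#' @description
#' Global parameter estimation of the kinetic model structures on culture
#' data, AIC-based structure selection, viable-parameter-space sampling, and
#' construction of an ensemble whose prediction is the mean of the member
#' trajectories.
NULL

#' Weighted sum-of-squares calibration cost
#'
#' `sum_states sum_t ((sim - obs) / scale_state)^2` with `scale_state` the
#' maximum observed value of that state, so all states contribute on a
#' comparable footing. States present in the simulation but absent from the
#' data are skipped with a warning.
#'
#' @param trajectory a `kinetic_trajectory` (or its `sampled` data frame).
#' @param data a `culture_timeseries`, or a data frame with a `time` column
#'   and state columns.
#' @param dw_per_cell conversion for `vcd` to biomass dry weight
#'   (default 250 pg/cell).
#' @return list with `cost` and `n_obs`.
#' @export
cost_function <- function(trajectory, data, dw_per_cell = 250e-12) {
  sim <- if (inherits(trajectory, "kinetic_trajectory")) trajectory$sampled
         else as.data.frame(trajectory)
  obs <- observation_table(data, dw_per_cell)
  i <- match(round(obs$time, 6), round(sim$time, 6))
  if (anyNA(i)) stop("trajectory not evaluated at all data times")
  states <- setdiff(names(obs), "time")
  missing <- setdiff(states, names(sim))
  if (length(missing)) {
    warning("states missing from simulation skipped: ",
            paste(missing, collapse = ", "))
    states <- setdiff(states, missing)
  }
  cost <- 0; n <- 0L
  for (st in states) {
    o <- obs[[st]]
    scale <- max(abs(o))
    if (!is.finite(scale) || scale <= 0) next
    r <- (sim[[st]][i] - o) / scale
    cost <- cost + sum(r^2)
    n <- n + length(r)
  }
  list(cost = cost, n_obs = n)
}

#' Turn a culture time series into a state observation table
#' @keywords internal
observation_table <- function(data, dw_per_cell = 250e-12) {
  if (inherits(data, "culture_timeseries")) {
    out <- data.frame(time = data$time)
    for (nm in names(data$concentrations)) out[[nm]] <- data$concentrations[[nm]]
    out$X <- data$vcd * dw_per_cell
    out$mAb <- data$titer
    out
  } else as.data.frame(data)
}

#' Log-uniform default calibration bounds
#'
#' A factor `span` below/above the reference value for every parameter.
#' @param p reference `parameter_set`.
#' @param span multiplicative half-range (default 10).
#' @return list with matrices `lower`, `upper` (named vectors).
#' @export
default_bounds <- function(p, span = 10) {
  list(lower = unclass(p) / span, upper = unclass(p) * span)
}

#' Global parameter estimation (scatter-search style)
#'
#' A documented scatter-search strategy in log-parameter space: a diverse
#' Latin-hypercube initial population, a reference set of the best and most
#' diverse members, pairwise convex/reflective combination of reference
#' solutions, and a final local polish of the incumbent with [stats::nlminb()]
#' (numerical gradients). The total number of cost evaluations is capped by
#' `budget`. Fully deterministic for a fixed `seed`.
#'
#' @param structure a `model_structure`.
#' @param data a `culture_timeseries` (or observation table) to fit.
#' @param schedule the `feed_schedule` used during the experiment.
#' @param init initial state of the culture.
#' @param fit names of the parameters to estimate (others fixed at `base`).
#' @param base full `parameter_set` supplying fixed values and the search
#'   centre (default [default_parameters()]).
#' @param bounds list(lower, upper) for the fitted parameters (default: a
#'   factor-10 log-range around `base`).
#' @param budget maximum cost evaluations (>= 100, default 1500).
#' @param seed RNG seed.
#' @param t_span simulation span (default: data span).
#' @return object of class `calibration_result`: `structure_id`, `params`
#'   (full set), `cost`, `n_obs`, `n_params`, `converged`, `seed`,
#'   `n_evaluations`.
#' @export
fit_parameters <- function(structure, data, schedule, init,
                           fit = names(default_parameters(structure)),
                           base = default_parameters(structure),
                           bounds = NULL, budget = 1500, seed = 1,
                           t_span = NULL) {
  if (budget < 100) stop("budget must be at least 100 evaluations")
  obs <- observation_table(data)
  if (is.null(t_span)) t_span <- range(obs$time)
  interval <- diff(obs$time)[1]
  if (is.null(bounds)) {
    b <- default_bounds(base)
    bounds <- list(lower = b$lower[fit], upper = b$upper[fit])
  }
  lo <- log10(bounds$lower[fit]); hi <- log10(bounds$upper[fit])
  k <- length(fit)
  n_eval <- 0L
  eval_cost <- function(z) {
    n_eval <<- n_eval + 1L
    p <- base
    p[fit] <- 10^pmin(pmax(z, lo), hi)
    tr <- tryCatch(
      simulate_model(structure, p, schedule, t_span, init,
                     dt_dense = interval, sample_interval = interval),
      error = function(e) NULL)
    if (is.null(tr)) return(1e10)
    cost_function(tr, data)$cost
  }
  set.seed(seed)
  n0 <- min(max(4L * k, 20L), floor(budget * 0.4))
  Z <- lhs::randomLHS(n0, k)
  pop <- matrix(lo, n0, k, byrow = TRUE) +
    Z * matrix(hi - lo, n0, k, byrow = TRUE)
  pop <- rbind(log10(unclass(base)[fit]), pop)
  costs <- apply(pop, 1, eval_cost)
  ref_n <- min(10L, nrow(pop))
  refset <- order(costs)[seq_len(ref_n)]
  local_budget <- min(60L * k, floor(budget * 0.4))
  while (n_eval < budget - local_budget) {
    i <- refset[1 + (n_eval %% (ref_n - 1L))]
    others <- refset[-match(i, refset)]
    j <- others[sample.int(length(others), 1)]
    a <- pop[i, ]; b <- pop[j, ]
    lam <- stats::runif(1, 0.3, 0.7)
    cand <- rbind(lam * a + (1 - lam) * b,            # convex combination
                  a + stats::runif(1, 0.5, 1.5) * (a - b))  # reflection
    for (r in seq_len(nrow(cand))) {
      if (n_eval >= budget - local_budget) break
      cz <- pmin(pmax(cand[r, ], lo), hi)
      cc <- eval_cost(cz)
      worst <- refset[which.max(costs[refset])]
      if (cc < costs[worst]) {
        pop <- rbind(pop, cz)
        costs <- c(costs, cc)
        refset[match(worst, refset)] <- nrow(pop)
      }
    }
  }
  best <- which.min(costs)
  polish <- stats::nlminb(pop[best, ], eval_cost, lower = lo, upper = hi,
                          control = list(eval.max = local_budget,
                                         iter.max = local_budget))
  z_best <- if (polish$objective <= costs[best]) polish$par else pop[best, ]
  c_best <- min(polish$objective, costs[best])
  p_best <- base
  p_best[fit] <- 10^z_best
  n_obs <- cost_function(
    simulate_model(structure, p_best, schedule, t_span, init,
                   dt_dense = interval, sample_interval = interval),
    data)$n_obs
  structure(list(structure_id = structure$variant_id, params = p_best,
                 cost = c_best, n_obs = n_obs, n_params = k,
                 converged = polish$convergence == 0, seed = seed,
                 n_evaluations = n_eval, fitted_names = fit),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> structure ", x$structure_id, ": cost ",
      format(x$cost, digits = 5), " (", x$n_params, " params, ", x$n_obs,
      " obs, ", x$n_evaluations, " evals, converged: ", x$converged, ")\n",
      sep = "")
  invisible(x)
}

#' Akaike information criterion for a calibration result
#'
#' Gaussian-residual form on the weighted cost:
#' `AIC = n ln(cost / n) + 2 k`; with `correction = TRUE` the small-sample
#' AICc adds `2 k (k + 1) / (n - k - 1)`.
#'
#' @param result a `calibration_result` (or list with `cost`, `n_obs`,
#'   `n_params`).
#' @param correction use AICc (default FALSE).
#' @return numeric AIC value.
#' @export
compute_aic <- function(result, correction = FALSE) {
  n <- result$n_obs; k <- result$n_params
  if (n <= k + 1) stop("degenerate sample size for AIC (n <= k + 1)")
  aic <- n * log(result$cost / n) + 2 * k
  if (correction) aic <- aic + 2 * k * (k + 1) / (n - k - 1)
  aic
}

#' Sample the viable parameter space
#'
#' Two-stage characterisation of the region where the calibration cost stays
#' below a threshold: (i) a flat-acceptance adaptive Metropolis random walk in
#' log-parameter space (any proposal below the threshold is accepted, the
#' proposal covariance adapts to the accepted history), (ii) ellipsoids
#' fitted to k-means clusters of the accepted points, resampled uniformly and
#' filtered by re-evaluation, which refines coverage of elongated regions.
#'
#' @param cost_fn function(named parameter vector) -> cost.
#' @param start named parameter vector with `cost_fn(start) <= threshold`.
#' @param threshold viability cost threshold.
#' @param n_samples minimum number of viable points to return.
#' @param seed RNG seed.
#' @param step initial proposal scale in log10 units (default 0.08).
#' @param max_iter walk iteration cap.
#' @return list with `samples` (matrix of viable parameter vectors, linear
#'   scale), `ranges` (per-parameter min/max), `acceptance_rate`, `threshold`.
#' @export
sample_viable_space <- function(cost_fn, start, threshold, n_samples = 200,
                                seed = 1, step = 0.08,
                                max_iter = 50L * n_samples) {
  c0 <- cost_fn(start)
  if (!is.finite(c0) || c0 > threshold)
    stop("no viable point: cost at start (", format(c0),
         ") exceeds threshold (", format(threshold), ")")
  set.seed(seed)
  k <- length(start)
  nm <- names(start)
  x <- log10(start)
  acc <- matrix(x, nrow = 1)
  n_try <- 0L
  sigma <- diag(step^2, k)
  target1 <- ceiling(n_samples * 0.7)
  while (nrow(acc) < target1 && n_try < max_iter) {
    n_try <- n_try + 1L
    prop <- as.numeric(x + t(chol(sigma)) %*% stats::rnorm(k))
    names(prop) <- nm
    cc <- cost_fn(10^prop)
    if (is.finite(cc) && cc <= threshold) {
      x <- prop
      acc <- rbind(acc, prop)
      if (nrow(acc) %% 25L == 0L && nrow(acc) > k + 2L) {
        emp <- stats::cov(acc)
        sigma <- 2.4^2 / k * emp + diag(1e-8, k)
      }
    }
  }
  if (nrow(acc) < 2L) stop("viable-space walk failed to move from the start")
  # stage 2: ellipsoid resampling around clusters of accepted points
  n_clust <- min(3L, nrow(acc) - 1L)
  cl <- stats::kmeans(acc, centers = n_clust, nstart = 3)
  extra <- list()
  want <- n_samples - nrow(acc)
  per_cluster <- max(ceiling(max(want, n_samples * 0.3) / n_clust), 5L)
  for (g in seq_len(n_clust)) {
    pts <- acc[cl$cluster == g, , drop = FALSE]
    if (nrow(pts) < 2L) next
    m <- colMeans(pts)
    Cv <- stats::cov(pts) + diag(1e-10, k)
    L <- t(chol(Cv))
    md <- sqrt(max(stats::mahalanobis(pts, m, Cv)))
    for (s in seq_len(per_cluster)) {
      u <- stats::rnorm(k)
      u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / k)
      cand <- as.numeric(m + md * (L %*% u))
      names(cand) <- nm
      cc <- cost_fn(10^cand)
      if (is.finite(cc) && cc <= threshold)
        extra[[length(extra) + 1L]] <- cand
    }
  }
  all_pts <- rbind(acc, do.call(rbind, extra))
  # top up with further walk steps if the two stages fell short
  n_top <- 0L
  while (nrow(all_pts) < n_samples && n_top < max_iter) {
    n_top <- n_top + 1L
    prop <- as.numeric(x + t(chol(sigma)) %*% stats::rnorm(k))
    names(prop) <- nm
    cc <- cost_fn(10^prop)
    if (is.finite(cc) && cc <= threshold) {
      x <- prop
      all_pts <- rbind(all_pts, prop)
    }
  }
  samples <- 10^all_pts
  colnames(samples) <- nm
  ranges <- apply(samples, 2, range)
  rownames(ranges) <- c("min", "max")
  list(samples = samples, ranges = ranges,
       acceptance_rate = nrow(acc) / max(n_try, 1L), threshold = threshold)
}

#' Build an ensemble from calibration results
#'
#' Structures within `delta_aic` of the best structure are retained; for each
#' retained structure the `top_n` (default 5) lowest-cost parameter sets are
#' kept, pooling the calibration results with any extra candidate sets (e.g.
#' viable-space samples with their re-evaluated costs).
#'
#' @param results list of `calibration_result` objects.
#' @param extra_sets optional list of lists with `structure_id`, `params`,
#'   `cost` to pool as additional candidates.
#' @param delta_aic structure retention band (default 10).
#' @param top_n parameter sets kept per structure (default 5).
#' @return object of class `ensemble_model`: `members` (each with
#'   `structure`, `params`, `cost`), `selected_structures`, `aic_table`.
#' @export
build_ensemble <- function(results, extra_sets = NULL, delta_aic = 10,
                           top_n = 5) {
  if (!length(results)) stop("no calibration results")
  sids <- vapply(results, `[[`, integer(1), "structure_id")
  aic_by_structure <- tapply(seq_along(results), sids, function(ix) {
    min(vapply(results[ix], compute_aic, numeric(1)))
  })
  best <- min(aic_by_structure)
  keep_sid <- as.integer(names(aic_by_structure)[aic_by_structure <=
                                                   best + delta_aic])
  cand <- lapply(results, function(r)
    list(structure_id = r$structure_id, params = r$params, cost = r$cost))
  cand <- c(cand, extra_sets)
  members <- list()
  for (sid in keep_sid) {
    sub <- Filter(function(cc) cc$structure_id == sid, cand)
    sub <- sub[order(vapply(sub, `[[`, numeric(1), "cost"))]
    sub <- sub[seq_len(min(top_n, length(sub)))]
    members <- c(members, lapply(sub, function(cc)
      list(structure = model_structure(sid), params = cc$params,
           cost = cc$cost)))
  }
  members <- members[order(vapply(members, `[[`, numeric(1), "cost"))]
  aic_table <- data.frame(structure_id = as.integer(names(aic_by_structure)),
                          aic = as.numeric(aic_by_structure))
  structure(list(members = members, selected_structures = keep_sid,
                 aic_table = aic_table),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> ", length(x$members), " members over structures {",
      paste(x$selected_structures, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Ensemble prediction: mean trajectory and min-max band
#'
#' Simulates every ensemble member under the given schedule; the combined
#' prediction is the pointwise mean of the member trajectories, and the band
#' is the pointwise minimum/maximum (the whole range of member predictions).
#' Members whose integration fails are excluded and logged.
#'
#' @param ensemble an `ensemble_model`.
#' @param schedule a `feed_schedule`.
#' @param t_span simulation span \[h\].
#' @param init initial state.
#' @return list with `mean` (data frame on the sampling grid), `band`
#'   (list of `min`/`max` data frames), `member_trajectories`, `failed`
#'   (indices of excluded members).
#' @export
ensemble_predict <- function(ensemble, schedule, t_span, init) {
  sims <- list(); failed <- integer(0)
  for (i in seq_along(ensemble$members)) {
    m <- ensemble$members[[i]]
    tr <- tryCatch(
      simulate_model(m$structure, m$params, schedule, t_span, init),
      error = function(e) NULL)
    if (is.null(tr)) failed <- c(failed, i) else sims[[length(sims) + 1L]] <- tr
  }
  if (length(failed))
    warning("ensemble members excluded after integration failure: ",
            paste(failed, collapse = ", "))
  if (!length(sims)) stop("all ensemble members failed to simulate")
  grids <- lapply(sims, function(tr) as.matrix(tr$sampled[, -1]))
  tt <- sims[[1]]$sampled$time
  arr <- simplify2array(grids)
  mn <- apply(arr, c(1, 2), mean)
  lo <- apply(arr, c(1, 2), min)
  hi <- apply(arr, c(1, 2), max)
  wrap <- function(m) {
    df <- as.data.frame(m)
    df <- cbind(time = tt, df)
    df
  }
  list(mean = wrap(mn), band = list(min = wrap(lo), max = wrap(hi)),
       member_trajectories = sims, failed = failed)
}

#' Morris elementary-effects screening
#'
#' Radial one-at-a-time design: for each of `r` base points (Latin hypercube
#' in the unit cube mapped to `ranges`), each parameter is perturbed by half
#' the unit range and the scaled effect recorded. Reports the mean absolute
#' elementary effect (mu_star), its signed mean and standard deviation, and
#' the ranking by mu_star.
#'
#' @param fn scalar function of a named parameter vector.
#' @param ranges list(lower, upper) named numeric vectors.
#' @param r number of base points (default 8).
#' @param seed RNG seed.
#' @return data frame sorted by decreasing `mu_star` with columns
#'   `parameter`, `mu`, `mu_star`, `sigma`, `rank`.
#' @export
global_sensitivity <- function(fn, ranges, r = 8, seed = 1) {
  lo <- ranges$lower; hi <- ranges$upper
  nm <- names(lo)
  k <- length(lo)
  if (r < 2) stop("need at least 2 base points")
  set.seed(seed)
  U <- lhs::randomLHS(r, k) * 0.5        # base points in [0, 0.5]^k
  delta <- 0.5
  ee <- matrix(NA_real_, r, k, dimnames = list(NULL, nm))
  to_x <- function(u) {
    x <- lo + u * (hi - lo)
    names(x) <- nm
    x
  }
  for (i in seq_len(r)) {
    u0 <- U[i, ]
    f0 <- fn(to_x(u0))
    for (j in seq_len(k)) {
      u1 <- u0
      u1[j] <- u1[j] + delta
      ee[i, j] <- (fn(to_x(u1)) - f0) / delta
    }
  }
  out <- data.frame(parameter = nm,
                    mu = colMeans(ee),
                    mu_star = colMeans(abs(ee)),
                    sigma = apply(ee, 2, stats::sd))
  out <- out[order(-out$mu_star), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
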