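ref_spec <- default_spec("HSD_CONTROL")

test_that("cost function is zero on itself and one per scale-unit residual", {
  ds <- generate_dataset(ref_spec, seed = 1)
  obs <- chomet:::observation_table(ds)
  expect_equal(cost_function(obs, ds)$cost, 0)
  obs2 <- obs
  obs2$Glc[4] <- obs2$Glc[4] + max(abs(obs$Glc))
  expect_equal(cost_function(obs2, ds)$cost, 1, tolerance = 1e-12)
})

test_that("cost function equals a brute-force double loop", {
  ds <- generate_dataset(ref_spec, seed = 2)
  obs <- chomet:::observation_table(ds)
  set.seed(5)
  sim <- obs
  for (nm in setdiff(names(sim), "time"))
    sim[[nm]] <- sim[[nm]] * (1 + stats::rnorm(nrow(sim), 0, 0.1))
  got <- cost_function(sim, ds)
  want <- 0
  for (nm in setdiff(names(obs), "time")) {
    sc <- max(abs(obs[[nm]]))
    for (i in seq_len(nrow(obs)))
      want <- want + ((sim[[nm]][i] - obs[[nm]][i]) / sc)^2
  }
  expect_equal(got$cost, want, tolerance = 1e-12)
  expect_equal(got$n_obs, (ncol(obs) - 1L) * nrow(obs))
})

test_that("AIC follows the Gaussian-residual formula", {
  mk <- function(cost, n, k) list(cost = cost, n_obs = n, n_params = k)
  expect_equal(compute_aic(mk(50, 50, 0)), 0)             # ln(1) = 0
  expect_equal(compute_aic(mk(50, 50, 3)) - compute_aic(mk(50, 50, 2)), 2)
  expect_equal(compute_aic(mk(20, 100, 7)) - compute_aic(mk(20, 100, 4)), 6)
  aicc <- compute_aic(mk(20, 100, 4), correction = TRUE)
  expect_equal(aicc - compute_aic(mk(20, 100, 4)), 2 * 4 * 5 / 95)
  expect_error(compute_aic(mk(1, 4, 4)), "degenerate")
})

test_that("noise-free parameters are recovered to the stated tolerance", {
  spec <- ref_spec
  spec$noise_cv <- c(concentration = 0, vcd = 0, titer = 0)
  ds <- generate_dataset(spec, seed = 1)
  st <- model_structure(1)
  fit <- c("vmax_gly", "ki_lac", "vmax_up")
  res <- fit_parameters(st, ds, spec$schedule, spec$init, fit = fit,
                        budget = 300, seed = 4)
  expect_lte(res$cost, 1e-4)
  truth <- default_parameters(st)
  expect_equal(unclass(res$params[fit]), unclass(truth[fit]),
               tolerance = 0.02)
  expect_equal(res$n_params, 3L)
})

test_that("calibration is bit-reproducible for a fixed seed", {
  spec <- ref_spec
  ds <- generate_dataset(spec, seed = 3)
  st <- model_structure(1)
  a <- fit_parameters(st, ds, spec$schedule, spec$init, fit = "vmax_gly",
                      budget = 120, seed = 9)
  b <- fit_parameters(st, ds, spec$schedule, spec$init, fit = "vmax_gly",
                      budget = 120, seed = 9)
  expect_identical(a$params, b$params)
  expect_identical(a$cost, b$cost)
})

test_that("viable-space sampler recovers an analytic ball", {
  centre <- c(a = 1, b = 1, c = 1)
  radius <- 0.3
  cost_fn <- function(x) sum(log10(x / centre)^2)
  out <- sample_viable_space(cost_fn, centre, threshold = radius^2,
                             n_samples = 150, seed = 2)
  # every returned point re-evaluates below the threshold
  re <- apply(out$samples, 1, cost_fn)
  expect_gte(mean(re <= radius^2 + 1e-12), 0.95)
  # per-parameter viable range is the ball diameter in log space
  half_range <- log10(out$ranges["max", ] / out$ranges["min", ]) / 2
  expect_true(all(abs(half_range - radius) / radius < 0.35))
  expect_gte(nrow(out$samples), 150)
})

test_that("viable-space sampler fails explicitly without a viable start", {
  cost_fn <- function(x) sum(log10(x)^2) + 5
  expect_error(
    sample_viable_space(cost_fn, c(a = 1), threshold = 1, seed = 1),
    "no viable point")
})

test_that("ensemble keeps the five lowest-cost sets per retained structure", {
  st <- model_structure(1)
  p <- default_parameters(st)
  mk <- function(cost, sid = 1L)
    structure(list(structure_id = sid, params = p, cost = cost, n_obs = 143,
                   n_params = 8, converged = TRUE, seed = 1),
              class = "calibration_result")
  res <- lapply(c(5, 3, 8, 1, 9, 2, 7), mk)
  ens <- build_ensemble(res)
  expect_length(ens$members, 5)
  expect_equal(vapply(ens$members, `[[`, numeric(1), "cost"),
               c(1, 2, 3, 5, 7))
  # a structure far worse in AIC is dropped entirely
  res2 <- c(res, list(mk(exp(50 / 143) * 1, sid = 2L)))  # delta AIC = 50
  ens2 <- build_ensemble(res2)
  expect_equal(ens2$selected_structures, 1L)
  # identical structures/sets stay as identical members
  ens3 <- build_ensemble(list(mk(2), mk(2), mk(2)))
  expect_length(ens3$members, 3)
  expect_true(all(vapply(ens3$members, `[[`, numeric(1), "cost") == 2))
})

test_that("ensemble mean equals a brute-force per-point average", {
  st <- model_structure(1)
  base <- default_parameters(st)
  members <- lapply(seq(0.85, 1.15, length.out = 15), function(f) {
    p <- base
    p["qp"] <- base[["qp"]] * f
    list(structure = st, params = p, cost = 1)
  })
  ens <- structure(list(members = members, selected_structures = 1L),
                   class = "ensemble_model")
  sch <- condition_schedule("HSD_CONTROL", 12)
  pred <- ensemble_predict(ens, sch, c(0, 288), initial_state("HSD_CONTROL"))
  # brute-force recomputation of the mean and band
  mats <- lapply(pred$member_trajectories,
                 function(tr) as.matrix(tr$sampled[, -1]))
  want <- Reduce(`+`, mats) / length(mats)
  expect_equal(as.matrix(pred$mean[, -1]), want, tolerance = 1e-12)
  lo <- Reduce(pmin, mats); hi <- Reduce(pmax, mats)
  expect_equal(as.matrix(pred$band$min[, -1]), lo, tolerance = 1e-12)
  expect_equal(as.matrix(pred$band$max[, -1]), hi, tolerance = 1e-12)
  # identical members collapse to a zero-width band
  ens1 <- structure(list(members = members[c(1, 1)],
                         selected_structures = 1L),
                    class = "ensemble_model")
  pred1 <- ensemble_predict(ens1, sch, c(0, 288),
                            initial_state("HSD_CONTROL"))
  expect_equal(pred1$band$min, pred1$band$max, tolerance = 1e-12)
  expect_equal(as.matrix(pred1$mean[, -1]),
               as.matrix(pred1$member_trajectories[[1]]$sampled[, -1]),
               tolerance = 1e-12)
})

test_that("Morris screening reports exact effects for a linear function", {
  fn <- function(x) 3 * x[["a"]] + x[["b"]] + 0 * x[["c"]]
  out <- global_sensitivity(fn, list(lower = c(a = 0, b = 0, c = 0),
                                     upper = c(a = 1, b = 1, c = 1)),
                            r = 6, seed = 3)
  mu <- stats::setNames(out$mu_star, out$parameter)
  expect_equal(unname(mu[["a"]] / mu[["b"]]), 3, tolerance = 1e-9)
  expect_equal(unname(mu[["c"]]), 0)
  expect_equal(out$parameter[1], "a")
})

test_that("key lactate-shift parameters rank as influential on the cost", {
  ds <- generate_dataset(ref_spec, seed = 6)
  st <- model_structure(1)
  base <- default_parameters(st)
  pars <- c("vmax_gly", "ki_lac", "vmax_up", "km_glc", "km_asp",
            "km_ile", "km_leu", "km_glu")
  sch <- ref_spec$schedule
  fn <- function(x) {
    p <- base
    p[names(x)] <- x
    tr <- simulate_model(st, p, sch, c(0, 288), ref_spec$init,
                         dt_dense = 24)
    cost_function(tr, ds)$cost
  }
  rng <- list(lower = unclass(base[pars]) / 3, upper = unclass(base[pars]) * 3)
  out <- global_sensitivity(fn, rng, r = 4, seed = 8)
  top_half <- out$parameter[seq_len(4)]
  expect_true("vmax_gly" %in% top_half)
  expect_true("ki_lac" %in% top_half)
})
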