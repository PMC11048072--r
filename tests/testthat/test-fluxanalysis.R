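test_that("measurement constraints follow the ±10% rule", {
  net <- default_network()
  q <- c(glc = -10, lac = 5, asn = 0)
  cn <- apply_measurement_constraints(net, q)
  rx <- cn$reactions
  expect_equal(rx$lower_bound[rx$id == "EX_glc"], -11)
  expect_equal(rx$upper_bound[rx$id == "EX_glc"], -9)
  expect_equal(rx$lower_bound[rx$id == "EX_lac"], 4.5)
  expect_equal(rx$upper_bound[rx$id == "EX_lac"], 5.5)
  expect_equal(rx$lower_bound[rx$id == "EX_asn"], 0)
  expect_equal(rx$upper_bound[rx$id == "EX_asn"], 0)
  # unmeasured: irreversible at 0, reversible at -1000, upper 1000
  expect_equal(rx$lower_bound[rx$id == "GLCt"], 0)
  expect_equal(rx$lower_bound[rx$id == "LACt"], -1000)
  expect_equal(rx$upper_bound[rx$id == "PDH"], 1000)
  expect_error(apply_measurement_constraints(net, c(unobtainium = 1)),
               "no matching exchange")
})

test_that("full synthetic measurement sets give straddling bounds", {
  net <- default_network()
  fx <- make_consistent_flux_set(net, magnitude = 10, seed = 4)
  cn <- apply_measurement_constraints(net, fx$q)
  ids <- chomet:::measured_exchange_ids(net, names(fx$q))
  i <- match(ids, cn$reactions$id)
  expect_true(all(cn$reactions$lower_bound[i] <= fx$q + 1e-12))
  expect_true(all(cn$reactions$upper_bound[i] >= fx$q - 1e-12))
})

test_that("FBA solves the linear chain to its uptake cap", {
  net <- chain_network(uptake_cap = 5)
  fd <- solve_fba(net, "EX_B")
  expect_equal(fd$status, "optimal")
  expect_equal(fd$objective_value, 5, tolerance = 1e-8)
  S <- stoichiometric_matrix(net)
  expect_lt(max(abs(S %*% fd$v)), 1e-8)
})

test_that("FBA optimum matches exhaustive vertex enumeration", {
  net <- branched_network()
  S <- stoichiometric_matrix(net)
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  cc <- as.numeric(net$reactions$id == "EX_P")
  fd <- solve_fba(net, "EX_P")
  want <- vertex_enumeration_lp(S, lb, ub, cc)
  expect_equal(fd$objective_value, want, tolerance = 1e-7)
})

test_that("FBA objective is monotone under bound widening", {
  net <- branched_network()
  base <- solve_fba(net, "EX_P")$objective_value
  set.seed(21)
  for (k in 1:20) {
    n2 <- net
    i <- sample(nrow(n2$reactions), 1)
    n2$reactions$lower_bound[i] <- n2$reactions$lower_bound[i] -
      stats::runif(1, 0, 5)
    n2$reactions$upper_bound[i] <- n2$reactions$upper_bound[i] +
      stats::runif(1, 0, 5)
    expect_gte(solve_fba(n2, "EX_P")$objective_value, base - 1e-8)
  }
})

test_that("infeasible constraint sets are surfaced, not zeroed", {
  net <- chain_network()
  net <- set_bounds(net, "EX_A", 0, 0)       # no uptake
  net <- set_bounds(net, "EX_B", 2, 1000)    # but forced secretion
  fd <- solve_fba(net, "EX_B")
  expect_equal(fd$status, "infeasible")
  expect_true(is.na(fd$objective_value))
})

test_that("optimal flux distributions respect S v = 0 and all bounds", {
  net <- default_network()
  fx <- make_consistent_flux_set(net, magnitude = 10, seed = 9,
                                 noise_cv = 0.05)
  cn <- apply_measurement_constraints(net, fx$q)
  fd <- solve_fba(cn, "biomass")
  if (fd$status == "optimal") {
    S <- stoichiometric_matrix(cn)
    expect_lt(max(abs(S %*% fd$v)), 1e-6)
    expect_true(all(fd$v >= cn$reactions$lower_bound - 1e-6))
    expect_true(all(fd$v <= cn$reactions$upper_bound + 1e-6))
  }
  mfa <- run_mfa(net, fx$q)
  S <- stoichiometric_matrix(net)
  expect_lt(max(abs(S %*% mfa$v_fit$v)), 1e-6)
  expect_true(all(mfa$v_fit$v >= net$reactions$lower_bound - 1e-6))
})

test_that("MFA reproduces consistent measurements exactly", {
  net <- default_network()
  fx <- make_consistent_flux_set(net, magnitude = 10, seed = 1)
  mfa <- run_mfa(net, fx$q)
  expect_equal(mfa$r_squared, 1, tolerance = 1e-6)
  expect_lt(max(abs(mfa$residuals)), 1e-4)
})

test_that("MFA projects an inconsistent chain measurement in closed form", {
  net <- chain_network(uptake_cap = 1000)
  # both exchange fluxes measured but inconsistent: the chain forces
  # v_EX_A = -v_EX_B, so the weighted fit is the projection onto that line
  q <- c(A = -4, B = 5)
  mfa <- run_mfa(net, q)
  w <- 1 / pmax(q^2, 1e-6)
  # minimize w1 (v + s)^2 + w2 (s - q2)^2 over secretion s with v = -s
  s_star <- (w[1] * (-q[1]) + w[2] * q[2]) / (w[1] + w[2])
  expect_equal(unname(mfa$v_fit$v[["EX_B"]]), unname(s_star),
               tolerance = 1e-5)
  expect_equal(unname(mfa$v_fit$v[["EX_A"]]), -unname(s_star),
               tolerance = 1e-5)
})

test_that("MFA achieves the validation threshold on noisy consistent sets", {
  net <- default_network()
  r2 <- vapply(1:6, function(sd) {
    fx <- make_consistent_flux_set(net, magnitude = 10, seed = sd,
                                   noise_cv = 0.05)
    run_mfa(net, fx$q)$r_squared
  }, numeric(1))
  expect_gte(stats::median(r2), 0.98)
})

test_that("MFA never exceeds the cost at the FBA start point", {
  net <- default_network()
  fx <- make_consistent_flux_set(net, magnitude = 10, seed = 13,
                                 noise_cv = 0.05)
  cn <- apply_measurement_constraints(net, fx$q)
  fba <- solve_fba(cn, "biomass")
  mfa <- run_mfa(net, fx$q, v_start = fba)
  ids <- chomet:::measured_exchange_ids(net, names(fx$q))
  w <- 1 / pmax(fx$q^2, 1e-6)
  cost_start <- sum(w * (fba$v[ids] - fx$q)^2)
  expect_lte(mfa$objective, cost_start + 1e-9)
})

test_that("lactate/glucose ratio encodes the uptake semantics", {
  r1 <- lactate_glucose_ratio(list(glc = -10, lac = 5))
  expect_equal(r1$ratio, -0.5)
  expect_equal(r1$regime, "lactate_production")
  r2 <- lactate_glucose_ratio(list(glc = -10, lac = -5))
  expect_equal(r2$ratio, 0.5)
  expect_equal(r2$regime, "efficient_co_consumption")
  r3 <- lactate_glucose_ratio(list(glc = -2, lac = -4))
  expect_equal(r3$ratio, 2)
  expect_equal(r3$regime, "lactate_primary")
  r4 <- lactate_glucose_ratio(list(glc = 0, lac = -4))
  expect_true(is.na(r4$ratio))
})

test_that("phase windows follow the per-condition evaluation days", {
  w <- phase_windows("STD_FB")
  expect_equal(c(w$start_day, w$end_day), c(4, 13))
  expect_equal(unname(w$objective_by_day[["4"]]), "biomass")
  expect_equal(unname(w$objective_by_day[["8"]]), "product")
  expect_equal(w$changeover_day, 7)
  w2 <- phase_windows("HSD_LAC_CYS")
  expect_equal(c(w2$start_day, w2$end_day), c(2, 13))
  w3 <- phase_windows("HSD_CONTROL")
  expect_equal(c(w3$start_day, w3$end_day), c(0, 11))
  w4 <- phase_windows("HSD_BM", changeover_day = 9)
  expect_equal(unname(w4$objective_by_day[["8"]]), "biomass")
  expect_error(phase_windows("XXX"), "unknown condition")
})
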