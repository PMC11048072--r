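#' @title Synthetic fed-batch datasets
#' @name synthetic_data
#' @description
#' Generates culture datasets with the statistical and process structure the
#' analysis pipeline assumes — four culture conditions (standard fed-batch and
#' three high-seeding-density regimes), 13 sampling points at daily intervals,
#' multiplicative measurement noise — plus steady-state-consistent flux sets
#' for exercising MFA. The underlying truth (noise-free trajectory and true
#' parameters) is returned alongside so recovery tests can compare against it.
NULL

#' Default synthetic specification for a condition
#'
#' High-seeding-density conditions seed at 10 million cells/mL and run 12
#' days; the standard fed-batch seeds at 0.7 million cells/mL and runs 14
#' days. All conditions have 13 sampling points (daily for the 12-day runs,
#' every 28 h for the 14-day run). Default noise: 5% CV on concentrations and
#' titer, 8% on viable cell density.
#'
#' @param condition `"STD_FB"`, `"HSD_CONTROL"`, `"HSD_LAC_CYS"` or
#'   `"HSD_BM"`.
#' @return object of class `synthetic_spec`.
#' @export
default_spec <- function(condition) {
  conditions <- c("STD_FB", "HSD_CONTROL", "HSD_LAC_CYS", "HSD_BM")
  if (!condition %in% conditions) stop("unknown condition: ", condition)
  duration <- if (condition == "STD_FB") 14 else 12
  n_samples <- 13L
  structure(list(condition = condition,
                 seeding_density = if (condition == "STD_FB") 0.7e6 else 10e6,
                 duration_days = duration,
                 n_samples = n_samples,
                 sample_interval = duration * 24 / (n_samples - 1L),
                 noise_cv = c(concentration = 0.05, vcd = 0.08, titer = 0.05),
                 truth = list(structure = model_structure(1L),
                              params = default_parameters(model_structure(1L))),
                 schedule = condition_schedule(condition, duration),
                 init = initial_state(condition)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$condition, ": seed ",
      format(x$seeding_density, scientific = TRUE), " cells/mL, ",
      x$duration_days, " days, ", x$n_samples, " samples\n", sep = "")
  invisible(x)
}

#' Generate a synthetic culture dataset
#'
#' Simulates the kinetic truth model under the condition's feed schedule,
#' samples it on the specification's grid, and applies multiplicative
#' Gaussian noise per variable (clipped at zero). Viability is emulated as a
#' smooth decline consistent with first-order death. The noise-free truth
#' (trajectory and parameters) is attached as the `truth` attribute so
#' parameter-recovery experiments can stay blind by simply not reading it.
#'
#' @param spec a `synthetic_spec` (see [default_spec()]).
#' @param seed RNG seed.
#' @param dw_per_cell dry weight per cell (default 250 pg).
#' @return a `culture_timeseries`; attribute `truth` holds the
#'   `kinetic_trajectory` and the true `parameter_set`.
#' @export
generate_dataset <- function(spec, seed = 1, dw_per_cell = 250e-12) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tr <- simulate_model(spec$truth$structure, spec$truth$params, spec$schedule,
                       c(0, spec$duration_days * 24), spec$init,
                       dt_dense = spec$sample_interval,
                       sample_interval = spec$sample_interval)
  s <- tr$sampled
  set.seed(seed)
  cv <- spec$noise_cv
  noisy <- function(x, cvx) pmax(x * (1 + stats::rnorm(length(x), 0, cvx)), 0)
  mets <- c("Glc", "Lac", "Amm", "Asn", "Asp", "Glu", "Ser", "Ile", "Leu")
  conc <- as.data.frame(lapply(stats::setNames(mets, mets), function(nm)
    noisy(s[[nm]], cv[["concentration"]])))
  vcd_true <- s$X / dw_per_cell
  viability <- 0.97 * exp(-spec$truth$params[["kd"]] *
                            pmax(s$time - 72, 0) / 2)
  # the attached feed record carries the boluses as actually applied
  # (scheduled plus threshold-triggered), the way an operator would log them
  feed_asrun <- spec$schedule
  feed_asrun$boluses <- if (nrow(tr$bolus_log)) tr$bolus_log else NULL
  feed_asrun$glucose_control <- NULL
  feed_asrun$lactate_control <- NULL
  culture_timeseries(
    time = s$time,
    concentrations = conc,
    vcd = noisy(vcd_true, cv[["vcd"]]),
    viability = pmin(pmax(viability, 0), 1),
    titer = noisy(s$mAb, cv[["titer"]]),
    volume = s$V,
    feed = feed_asrun) -> out
  attr(out, "truth") <- list(trajectory = tr, params = spec$truth$params,
                             structure = spec$truth$structure)
  out
}

#' Steady-state-consistent synthetic flux set
#'
#' Samples a flux distribution in the network's steady-state polytope by
#' taking a random convex combination of LP vertices (random objective
#' directions with exchanges bounded to ±`magnitude` and glucose uptake
#' forced), so `S v = 0` holds exactly. The exchange fluxes of the measured
#' set are reported as "measurements", optionally perturbed with
#' multiplicative Gaussian noise.
#'
#' @param network a `metabolic_network`.
#' @param magnitude exchange flux scale \[µmol/g_DW/h\] (default 10).
#' @param seed RNG seed.
#' @param noise_cv relative noise on the reported measurements (default 0).
#' @param n_vertices number of LP vertices combined (default 4).
#' @return list with `q` (named measured exchange rates, metabolite names),
#'   `v_true` (full flux vector), `q_true` (noise-free measurements).
#' @export
make_consistent_flux_set <- function(network, magnitude = 10, seed = 1,
                                     noise_cv = 0, n_vertices = 4) {
  stopifnot(inherits(network, "metabolic_network"))
  if (magnitude == 0) {
    rx <- network$reactions
    v <- stats::setNames(rep(0, nrow(rx)), rx$id)
    q <- flux_measurements(network, v)
    return(list(q = q, v_true = v, q_true = q))
  }
  set.seed(seed)
  rx <- network$reactions
  net <- network
  ex <- rx$is_exchange
  net$reactions$lower_bound[ex] <- pmax(rx$lower_bound[ex], -magnitude)
  net$reactions$upper_bound[ex] <- pmin(rx$upper_bound[ex], magnitude)
  i_glc <- which(rx$id == "EX_glc")
  if (length(i_glc)) {
    net$reactions$lower_bound[i_glc] <- -magnitude
    net$reactions$upper_bound[i_glc] <- -0.5 * magnitude
  }
  S <- stoichiometric_matrix(net)
  b <- network_bounds(net)
  verts <- list()
  for (kk in seq_len(n_vertices)) {
    cc <- stats::rnorm(ncol(S))
    sol <- lp_polytope(S, b$lb, b$ub, cc, maximize = TRUE)
    if (sol$status == "optimal") verts[[length(verts) + 1L]] <- sol$v
  }
  if (!length(verts)) stop("degenerate flux polytope: no vertex found")
  wts <- stats::runif(length(verts))
  wts <- wts / sum(wts)
  v <- Reduce(`+`, Map(`*`, verts, wts))
  q_true <- flux_measurements(network, v)
  q <- q_true
  if (noise_cv > 0)
    q <- q * (1 + stats::rnorm(length(q), 0, noise_cv))
  list(q = q, v_true = v, q_true = q_true)
}

#' Extract the measured exchange fluxes from a flux vector
#' @keywords internal
flux_measurements <- function(network, v) {
  rx <- network$reactions
  ids <- rx$id[rx$is_exchange & rx$is_measured]
  mets <- vapply(ids, function(id) {
    m <- names(network$stoichiometry[[id]])[1]
    sub("_e$", "", m)
  }, character(1))
  stats::setNames(v[ids], mets)
}
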