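#' @title Flux balance and metabolic flux analysis
#' @name fluxanalysis
#' @description
#' FBA with measurement-derived exchange constraints (±10% of the measured
#' specific rates; unmeasured reactions bounded at 0 or -1000 below and 1000
#' above), LP solution maximising biomass or product, least-squares MFA
#' refinement fitted to the measured fluxes, and derived efficiency metrics
#' such as the lactate/glucose uptake ratio.
NULL

#' Map measured metabolite names to exchange reactions
#'
#' A measured metabolite `m` matches the exchange reaction draining `m_e`
#' (or `m` itself for networks without compartment suffixes).
#' @keywords internal
measured_exchange_ids <- function(network, measured_names) {
  rx <- network$reactions
  ex_ids <- rx$id[rx$is_exchange]
  met_of <- vapply(ex_ids, function(id) {
    st <- network$stoichiometry[[id]]
    names(st)[1]
  }, character(1))
  aliases <- c(amm = "nh4", ammonia = "nh4", ammonium = "nh4")
  out <- vapply(measured_names, function(nm) {
    nml <- tolower(nm)
    if (nml %in% names(aliases)) nml <- aliases[[nml]]
    hit <- ex_ids[tolower(met_of) %in% c(paste0(nml, "_e"), nml)]
    if (!length(hit)) NA_character_ else hit[1]
  }, character(1))
  if (anyNA(out))
    stop("measured flux with no matching exchange reaction: ",
         paste(measured_names[is.na(out)], collapse = ", "))
  out
}

#' Apply measurement constraints to a network
#'
#' Each measured exchange reaction j receives the bounds
#' `[q_j - 0.1 |q_j|, q_j + 0.1 |q_j|]` (a zero measurement pins the flux to
#' zero). Unmeasured reactions keep lower bound 0 if irreversible or -1000 if
#' reversible, and upper bound 1000.
#'
#' @param network a `metabolic_network`.
#' @param q named numeric vector of measured specific rates
#'   \[µmol/g_DW/h\], names = metabolite names (consumption negative).
#' @param tolerance half-width of the measurement band relative to `|q|`
#'   (default 0.1).
#' @return the constrained network.
#' @export
apply_measurement_constraints <- function(network, q, tolerance = 0.1) {
  stopifnot(inherits(network, "metabolic_network"), is.numeric(q))
  ids <- measured_exchange_ids(network, names(q))
  rx <- network$reactions
  unmeas <- !(rx$id %in% ids)
  network$reactions$lower_bound[unmeas] <- ifelse(rx$reversible[unmeas], -1000, 0)
  network$reactions$upper_bound[unmeas] <- 1000
  i <- match(ids, network$reactions$id)
  network$reactions$lower_bound[i] <- q - tolerance * abs(q)
  network$reactions$upper_bound[i] <- q + tolerance * abs(q)
  network
}

#' Solve flux balance analysis
#'
#' Maximises the biomass or product flux over `S v = 0` within the current
#' bounds. Among alternate optima the minimum-2-norm optimal flux
#' distribution is reported, so results are reproducible. Infeasibility is
#' surfaced in `status`, never silently zeroed.
#'
#' @param network a (constrained) `metabolic_network`.
#' @param objective `"biomass"`, `"product"`, or a reaction id.
#' @return object of class `flux_distribution`: `v` (named), `objective_value`,
#'   `objective_id`, `status`.
#' @export
solve_fba <- function(network, objective = c("biomass", "product")) {
  stopifnot(inherits(network, "metabolic_network"))
  rx <- network$reactions
  obj_id <- if (length(objective) == 1L && objective %in% rx$id) {
    objective
  } else {
    objective <- match.arg(objective)
    sub <- if (objective == "biomass") "biomass" else "product"
    cand <- rx$id[rx$subsystem == sub & !rx$is_exchange]
    if (!length(cand)) cand <- rx$id[rx$subsystem == sub]
    if (!length(cand)) stop("no ", objective, " reaction in network")
    cand[1]
  }
  S <- stoichiometric_matrix(network)
  b <- network_bounds(network)
  cc <- numeric(ncol(S))
  cc[match(obj_id, colnames(S))] <- 1
  sol <- lp_polytope(S, b$lb, b$ub, cc, maximize = TRUE)
  structure(list(v = sol$v, objective_value = sol$obj, objective_id = obj_id,
                 status = sol$status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> status: ", x$status, "; ", x$objective_id, " = ",
      format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Metabolic flux analysis (weighted least-squares reconciliation)
#'
#' Minimises \eqn{\sum_j w_j (v_j - q_j)^2} over the measured exchange set,
#' subject to `S v = 0` and the network's (irreversibility) bounds, with
#' relative weights \eqn{w_j = 1 / \max(q_j^2, \epsilon)}. Unmeasured fluxes
#' carry a vanishing ridge towards the FBA start point to keep the quadratic
#' programme positive definite. Reports the pooled coefficient of
#' determination \eqn{R^2 = 1 - SSR/SST} across measured fluxes.
#'
#' @param network a `metabolic_network` whose bounds encode irreversibility
#'   (not the ±10% measurement bands).
#' @param q named numeric vector of measured rates (see
#'   [apply_measurement_constraints()] for the name convention).
#' @param v_start a `flux_distribution` used as starting/anchor point
#'   (typically the FBA solution), or `NULL`.
#' @param eps weight floor (default 1e-6).
#' @return object of class `mfa_result`: `v_fit` (a `flux_distribution`),
#'   `r_squared`, `residuals` (fitted minus measured), `objective`.
#' @export
run_mfa <- function(network, q, v_start = NULL, eps = 1e-6) {
  stopifnot(inherits(network, "metabolic_network"), is.numeric(q))
  if (!length(q)) stop("no measured fluxes")
  ids <- measured_exchange_ids(network, names(q))
  S <- stoichiometric_matrix(network)
  b <- network_bounds(network)
  n <- ncol(S)
  j <- match(ids, colnames(S))
  w <- rep(0, n)
  w[j] <- 1 / pmax(q^2, eps)
  ridge <- 1e-8 * stats::median(w[j])
  w[-j] <- ridge
  target <- numeric(n)
  target[j] <- q
  if (!is.null(v_start)) {
    vs <- if (inherits(v_start, "flux_distribution")) v_start$v else v_start
    target[-j] <- vs[-j]
  }
  sol <- qp_wls(S, b$lb, b$ub, w, target)
  v <- sol$v
  fitted <- v[j]
  resid <- fitted - q
  sst <- sum((q - mean(q))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else NA_real_
  obj <- sum(w[j] * resid^2)
  vfit <- structure(list(v = v, objective_value = obj, objective_id = "MFA",
                         status = sol$status),
                    class = "flux_distribution")
  structure(list(v_fit = vfit, r_squared = r2,
                 residuals = stats::setNames(resid, names(q)),
                 objective = obj),
            class = "mfa_result")
}

#' @export
print.mfa_result <- function(x, ...) {
  cat("<mfa_result> R^2 = ", format(x$r_squared, digits = 4),
      "; weighted SSR = ", format(x$objective, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Weighted least squares over the flux polytope
#'
#' `min (v - target)' diag(w) (v - target)` s.t. `S v = 0`, `lb <= v <= ub`,
#' solved with quadprog in weight-scaled variables (`u = sqrt(w) v`) so the
#' quadratic form is the identity regardless of the weight spread.
#' @keywords internal
qp_wls <- function(S, lb, ub, w, target, big = 999) {
  n <- ncol(S)
  sw <- sqrt(w)
  Ssc <- sweep(S, 2, sw, "/")
  qrS <- qr(t(Ssc))
  keep <- qrS$pivot[seq_len(qrS$rank)]
  Sk <- Ssc[keep, , drop = FALSE]
  meq <- nrow(Sk)
  lbu <- lb * sw
  ubu <- ub * sw
  act_lb <- which(lb > -big)
  act_ub <- which(ub < big)
  extra_lb <- integer(0); extra_ub <- integer(0)
  for (outer in 1:25) {
    elb <- union(act_lb, extra_lb)
    eub <- union(act_ub, extra_ub)
    Amat <- cbind(t(Sk),
                  diag(n)[, elb, drop = FALSE],
                  -diag(n)[, eub, drop = FALSE])
    bvec <- c(numeric(meq), lbu[elb], -ubu[eub])
    u <- tryCatch(
      quadprog::solve.QP(diag(n), sw * target, Amat, bvec, meq = meq)$solution,
      error = function(e) e)
    if (inherits(u, "error")) {
      if (grepl("inconsistent", conditionMessage(u)))
        return(list(v = stats::setNames(rep(NA_real_, n), colnames(S)),
                    status = "infeasible"))
      stop(u)
    }
    v <- u / sw
    viol_lb <- which(v < lb - 1e-7)
    viol_ub <- which(v > ub + 1e-7)
    if (!length(viol_lb) && !length(viol_ub)) {
      names(v) <- colnames(S)
      if (max(abs(S %*% v)) > 1e-6)
        return(list(v = stats::setNames(rep(NA_real_, n), colnames(S)),
                    status = "infeasible"))
      return(list(v = v, status = "optimal"))
    }
    extra_lb <- union(extra_lb, viol_lb)
    extra_ub <- union(extra_ub, viol_ub)
  }
  stop("MFA active-set loop did not converge")
}

#' Lactate/glucose uptake-flux ratio
#'
#' The ratio `q_lac / q_glc` with the sign semantics of uptake fluxes: a
#' positive ratio means glucose and lactate are consumed in parallel
#' (values in (0, 1) flag an efficient metabolic state, values above 1 mean
#' lactate is the primary carbon source), a negative ratio means lactate is
#' produced while glucose is consumed.
#'
#' @param flux a `specific_flux_series` with `glc` and `lac` columns, or a
#'   list/data frame with numeric `glc` and `lac`.
#' @param eps glucose fluxes with `|q_glc| < eps` yield `NA` (default 1e-9).
#' @return data frame with `time` (if available), `ratio`, and `regime`
#'   (`"efficient_co_consumption"`, `"lactate_primary"`, `"lactate_production"`,
#'   or `NA`).
#' @export
lactate_glucose_ratio <- function(flux, eps = 1e-9) {
  pick <- function(tbl, nm) {
    i <- match(nm, tolower(names(tbl)))
    if (is.na(i)) stop("missing series: ", nm)
    tbl[[i]]
  }
  if (inherits(flux, "specific_flux_series")) {
    qg <- pick(flux$q, "glc"); ql <- pick(flux$q, "lac"); tt <- flux$time
  } else {
    qg <- pick(flux, "glc"); ql <- pick(flux, "lac")
    tt <- if (!is.null(flux$time)) flux$time else seq_along(qg)
  }
  ratio <- ifelse(abs(qg) < eps, NA_real_, ql / qg)
  regime <- rep(NA_character_, length(ratio))
  regime[!is.na(ratio) & ratio > 0 & ratio < 1] <- "efficient_co_consumption"
  regime[!is.na(ratio) & ratio >= 1] <- "lactate_primary"
  regime[!is.na(ratio) & ratio < 0] <- "lactate_production"
  data.frame(time = tt, ratio = ratio, regime = regime,
             stringsAsFactors = FALSE)
}

#' FBA evaluation windows per culture condition
#'
#' The analysis window excludes the lag phase: standard fed-batch uses days
#' 4–13; the high-seeding-density control ran only 11 days and is evaluated on
#' days 0–11; the supplemented conditions use days 2–13. Within the window
#' each day is tagged with the biomass objective (growth phase) up to the
#' changeover day and the product objective afterwards.
#'
#' @param condition one of `"STD_FB"`, `"HSD_CONTROL"`, `"HSD_LAC_CYS"`,
#'   `"HSD_BM"`.
#' @param changeover_day growth-to-production objective switch (default 7).
#' @return object of class `phase_windows`: `condition`, `start_day`,
#'   `end_day`, `changeover_day`, and `objective_by_day` (named character
#'   vector over the window's days).
#' @export
phase_windows <- function(condition, changeover_day = 7) {
  win <- switch(condition,
                STD_FB      = c(4, 13),
                HSD_CONTROL = c(0, 11),
                HSD_LAC_CYS = c(2, 13),
                HSD_BM      = c(2, 13),
                stop("unknown condition: ", condition))
  days <- seq(win[1], win[2])
  obj <- ifelse(days < changeover_day, "biomass", "product")
  names(obj) <- days
  structure(list(condition = condition, start_day = win[1], end_day = win[2],
                 changeover_day = changeover_day, objective_by_day = obj),
            class = "phase_windows")
}

#' @export
print.phase_windows <- function(x, ...) {
  cat("<phase_windows> ", x$condition, ": days ", x$start_day, "-", x$end_day,
      ", objective switch at day ", x$changeover_day, "\n", sep = "")
  invisible(x)
}
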