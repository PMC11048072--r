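#' @title Feed-composition simulation studies
#' @name feedscan
#' @description
#' Simulation experiments on the asparagine content of the feed: scanning
#' relative asparagine multipliers across the calibrated ensemble, detecting
#' the lactate production-to-consumption shift, comparing conditions by
#' phase-wise lactate ratios, and extracting all kinetic rates at selected
#' days (by default days 2 and 5, marking the two metabolic phases).
NULL

#' Feed-corrected daily net production of a state
#'
#' From a simulated trajectory, computes per daily interval the change in
#' total amount (`C * V`) minus everything the feed added (continuous feed
#' plus all logged boluses, including triggered control boluses), i.e. the
#' net biological volumetric production \[mmol per interval\]; negative values
#' mean net consumption.
#'
#' @param trajectory a `kinetic_trajectory`.
#' @param state state name (e.g. `"Lac"`).
#' @return data frame with `day` (interval start, in days) and `net` \[mmol\].
#' @export
net_production <- function(trajectory, state) {
  s <- trajectory$sampled
  bl <- trajectory$bolus_log
  sch <- trajectory$schedule
  amt <- s[[state]] * s$V
  FF <- if (is.null(sch)) 0 else sch$continuous$rate
  comp <- if (is.null(sch)) list() else sch$continuous$composition
  cfeed <- if (state %in% names(comp)) comp[[state]] else 0
  fed <- FF * cfeed * diff(s$time)
  if (nrow(bl)) {
    col <- paste0("conc_", state)
    for (k in seq_len(nrow(bl))) {
      # the trajectory records the pre-event state at the event time, so a
      # bolus at time t contributes to the interval starting at t
      i <- findInterval(bl$time_h[k] + 1e-9, s$time)
      cc <- if (col %in% names(bl)) bl[[col]][k] else 0
      if (i >= 1 && i <= length(fed)) fed[i] <- fed[i] + cc * bl$volume_L[k]
    }
  }
  data.frame(day = s$time[-nrow(s)] / 24, net = diff(amt) - fed)
}

#' Detect the lactate shift in a trajectory
#'
#' The shift day is the first day at which the feed-corrected net volumetric
#' lactate rate becomes negative and stays negative for at least `sustain_h`
#' hours (default 48 h, i.e. two consecutive daily intervals); `NA` if no
#' such day exists. The sustain rule suppresses single-day dips.
#'
#' @param trajectory a `kinetic_trajectory`, or a data frame as returned by
#'   [net_production()].
#' @param sustain_h minimum sustained consumption \[h\] (default 48).
#' @return shift day (numeric) or `NA`.
#' @export
detect_lactate_shift <- function(trajectory, sustain_h = 48) {
  np <- if (inherits(trajectory, "kinetic_trajectory"))
    net_production(trajectory, "Lac") else as.data.frame(trajectory)
  if (nrow(np) < 5L) stop("trajectory must cover at least 5 days")
  need <- max(1L, ceiling(sustain_h / 24))
  neg <- np$net < 0
  for (i in seq_len(length(neg) - need + 1L)) {
    if (all(neg[i:(i + need - 1L)])) return(np$day[i])
  }
  NA_real_
}

#' Scan the asparagine content of the feed across an ensemble
#'
#' Each factor scales the asparagine concentration of the continuous feed and
#' of the bolus-medium composition; everything else is unchanged. Every
#' ensemble member is simulated per factor; the reported trajectory is the
#' ensemble mean and the shift day is detected on it.
#'
#' @param ensemble an `ensemble_model` (see [build_ensemble()]).
#' @param condition culture condition whose schedule is scanned.
#' @param factors positive asparagine multipliers (defaults 0.75, 1, 2:
#'   modest reduction, original, strong elevation).
#' @param duration_days cultivation length (default per condition).
#' @param phases list of `c(start_day, end_day)` phases for the per-phase
#'   lactate production rate (defaults: growth D0-D5, production D5-D10).
#' @return list of `scan_result` objects (one per factor): `factor`,
#'   `mean_trajectory`, `member_trajectories`, `shift_day`,
#'   `lactate_production_rate` \[mmol/L/day per phase\], `titer_final`.
#' @export
scan_feed_asparagine <- function(ensemble, condition = "HSD_CONTROL",
                                 factors = c(0.75, 1, 2),
                                 duration_days = NULL,
                                 phases = list(c(0, 5), c(5, 10))) {
  if (any(factors <= 0)) stop("factors must be positive")
  if (is.null(duration_days))
    duration_days <- if (condition == "STD_FB") 14 else 12
  init <- initial_state(condition)
  lapply(factors, function(fac) {
    schedule <- condition_schedule(condition, duration_days,
                                   asn_feed_factor = fac)
    sims <- ensemble_predict(ensemble, schedule, c(0, duration_days * 24),
                             init)
    tr <- sims$member_trajectories[[1]]
    mean_tr <- tr
    mean_tr$sampled <- sims$mean
    shift <- detect_lactate_shift(mean_member_net(sims$member_trajectories))
    rate <- vapply(phases, function(ph) {
      sel <- sims$mean$time / 24 >= ph[1] & sims$mean$time / 24 <= ph[2]
      lac <- sims$mean$Lac[sel]
      tt <- sims$mean$time[sel] / 24
      if (sum(sel) < 2) return(NA_real_)
      (lac[length(lac)] - lac[1]) / (tt[length(tt)] - tt[1])
    }, numeric(1))
    structure(list(factor = fac, mean_trajectory = sims$mean,
                   member_trajectories = sims$member_trajectories,
                   band = sims$band, shift_day = shift,
                   lactate_production_rate = rate,
                   titer_final = sims$mean$mAb[nrow(sims$mean)]),
              class = "scan_result")
  })
}

#' Ensemble-mean feed-corrected net lactate production
#' @keywords internal
mean_member_net <- function(members) {
  nets <- lapply(members, net_production, state = "Lac")
  out <- nets[[1]]
  out$net <- Reduce(`+`, lapply(nets, `[[`, "net")) / length(nets)
  out
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> Asn factor ", x$factor, "; shift day: ",
      if (is.na(x$shift_day)) "none" else x$shift_day,
      "; final titer ", round(x$titer_final), " mg/L\n", sep = "")
  invisible(x)
}

#' Compare two runs by phase-wise lactate ratios
#'
#' For each phase, reports the ratio of mean lactate concentrations
#' (`run_a / run_b`) and the mean net volumetric lactate production rates of
#' both runs, mirroring an enhanced-feed versus control comparison.
#'
#' @param run_a,run_b `kinetic_trajectory` objects on the same time grid.
#' @param phases list of `c(start_day, end_day)` pairs.
#' @return data frame with one row per phase.
#' @export
compare_conditions <- function(run_a, run_b,
                               phases = list(c(0, 5), c(5, 10))) {
  if (!isTRUE(all.equal(run_a$sampled$time, run_b$sampled$time)))
    stop("runs must share the sampling grid")
  na <- net_production(run_a, "Lac")
  nb <- net_production(run_b, "Lac")
  rows <- lapply(phases, function(ph) {
    sel <- run_a$sampled$time / 24 >= ph[1] & run_a$sampled$time / 24 <= ph[2]
    seln <- na$day >= ph[1] & na$day < ph[2]
    mb <- mean(run_b$sampled$Lac[sel])
    data.frame(start_day = ph[1], end_day = ph[2],
               lac_conc_ratio = if (abs(mb) < 1e-12) NA_real_ else
                 mean(run_a$sampled$Lac[sel]) / mb,
               net_rate_a = mean(na$net[seln]),
               net_rate_b = mean(nb$net[seln]))
  })
  do.call(rbind, rows)
}

#' Extract all kinetic rates at selected days
#'
#' Evaluates every rate law of the model on the stored state at each
#' requested day (default days 2 and 5, time points marking the two metabolic
#' phases).
#'
#' @param trajectory a `kinetic_trajectory`.
#' @param days days at which to evaluate (default `c(2, 5)`).
#' @return tidy data frame (`day`, `reaction`, `rate`).
#' @export
extract_rates_at_days <- function(trajectory, days = c(2, 5)) {
  s <- trajectory$sampled
  rows <- lapply(days, function(d) {
    i <- which(abs(s$time - d * 24) < 1e-6)
    if (!length(i)) stop("day ", d, " outside the simulated span")
    state <- unlist(s[i, kinetic_states()])
    r <- all_rates(state, trajectory$params, trajectory$structure)
    data.frame(day = d, reaction = names(r), rate = unname(r))
  })
  do.call(rbind, rows)
}
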