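#' Construct a fed-batch feed schedule
#'
#' Holds the continuous feed (a constant pump rate with a fixed composition),
#' scheduled boluses, and the two threshold-triggered controls evaluated at the
#' daily checkpoints: the glucose refill (all conditions) and the lactate
#' bolus of the LAC+CYS condition. Trigger volumes are computed from the
#' mixing rule so the post-bolus concentration equals the control target.
#'
#' @param rate continuous feed rate \[L/h\] (>= 0).
#' @param composition named list/vector of feed concentrations \[mmol/L\].
#' @param boluses data frame with columns `time_h`, `volume_L`, `kind` and
#'   `conc_<State>` columns \[mmol/L\]; may be `NULL`.
#' @param glucose_control list(threshold, target, stock_conc) \[mmol/L\] or
#'   `NULL`.
#' @param lactate_control list(window_h = c(t0, t1), threshold, target,
#'   stock_conc) or `NULL`.
#' @param check_times daily checkpoint times \[h\].
#' @return object of class `feed_schedule`.
#' @export
feed_schedule <- function(rate = 0, composition = list(), boluses = NULL,
                          glucose_control = NULL, lactate_control = NULL,
                          check_times = seq(24, 336, by = 24)) {
  if (rate < 0) stop("feed rate must be non-negative")
  if (!is.null(boluses) && nrow(boluses) && any(boluses$volume_L <= 0))
    stop("bolus volumes must be positive")
  structure(list(continuous = list(rate = rate,
                                   composition = as.list(composition)),
                 boluses = boluses, glucose_control = glucose_control,
                 lactate_control = lactate_control,
                 check_times = sort(unique(check_times))),
            class = "feed_schedule")
}

#' @export
print.feed_schedule <- function(x, ...) {
  nb <- if (is.null(x$boluses)) 0L else nrow(x$boluses)
  cat("<feed_schedule> F = ", x$continuous$rate, " L/h; ", nb,
      " scheduled boluses; glucose control: ",
      !is.null(x$glucose_control), "; lactate control: ",
      !is.null(x$lactate_control), "\n", sep = "")
  invisible(x)
}

#' Default feed schedule for a culture condition
#'
#' Encodes the condition-specific feeding regime: a continuous feed in all
#' conditions plus a glucose-threshold bolus; amino-acid-enriched bolus medium
#' (BM) on days 1–6 for HSD+BM; lactate boluses triggered below 2 g/L
#' (22.2 mmol/L) on days 3–13 and fixed 7 mL cysteine-equivalent volume
#' boluses on days 1–5 for HSD+LAC+CYS (cysteine is not a model state, so
#' these act through dilution only). All absolute compositions are documented
#' synthetic defaults.
#'
#' @param condition `"STD_FB"`, `"HSD_CONTROL"`, `"HSD_LAC_CYS"` or `"HSD_BM"`.
#' @param duration_days cultivation length (defaults per condition, see
#'   [default_spec()]).
#' @param asn_feed_factor multiplier on the asparagine content of the
#'   continuous feed and the BM (used by feed scans; default 1).
#' @return a `feed_schedule`.
#' @export
condition_schedule <- function(condition, duration_days = NULL,
                               asn_feed_factor = 1) {
  conditions <- c("STD_FB", "HSD_CONTROL", "HSD_LAC_CYS", "HSD_BM")
  if (!condition %in% conditions)
    stop("unknown condition: ", condition)
  if (is.null(duration_days))
    duration_days <- if (condition == "STD_FB") 14 else 12
  horizon <- duration_days * 24
  check_times <- seq(24, horizon, by = 24)
  comp <- list(Glc = 500, Asn = 150 * asn_feed_factor, Ser = 25, Ile = 12,
               Leu = 12, Asp = 5, Glu = 5)
  boluses <- NULL
  if (condition == "HSD_BM") {
    bm_days <- 1:6
    boluses <- data.frame(time_h = bm_days * 24, volume_L = 0.04,
                          kind = "bolus_medium",
                          conc_Asn = 60 * asn_feed_factor, conc_Asp = 15,
                          conc_Glu = 15, conc_Ser = 40, conc_Ile = 25,
                          conc_Leu = 25)
  }
  lactate_control <- NULL
  if (condition == "HSD_LAC_CYS") {
    cys <- data.frame(time_h = (1:5) * 24, volume_L = 0.007,
                      kind = "cysteine_volume")
    boluses <- cys
    lactate_control <- list(window_h = c(3, 13) * 24,
                            threshold = 22.2,   # 2 g/L sodium-lactate trigger
                            target = 28, stock_conc = 1000)
  }
  glucose_control <- list(threshold = 11, target = 33, stock_conc = 2500)
  feed_schedule(rate = 0.0012, composition = comp, boluses = boluses,
                glucose_control = glucose_control,
                lactate_control = lactate_control, check_times = check_times)
}

#' Default initial state for a culture condition
#'
#' Seeding at 10 million cells/mL for the high-seeding-density conditions and
#' 0.7 million cells/mL for the standard fed-batch, converted to dry weight
#' with 250 pg/cell. Absolute metabolite scales are documented synthetic
#' defaults (glucose 40, asparagine 10, lactate 1 mmol/L, other measured
#' metabolites 1–5 mmol/L).
#'
#' @param condition culture condition (see [condition_schedule()]).
#' @param dw_per_cell cell dry weight \[g/cell\] (default 250 pg).
#' @return named initial state vector.
#' @export
initial_state <- function(condition, dw_per_cell = 250e-12) {
  seeding <- if (condition == "STD_FB") 0.7e6 else 10e6   # cells/mL
  X0 <- seeding * 1000 * dw_per_cell                       # g_DW/L
  c(Glc = 40, Pyr = 0.2, Lac = 1, Amm = 1, Asn = 10, Asp = 2, Glu = 2,
    Ser = 3, Ile = 2, Leu = 2, X = X0, mAb = 0, V = 1.5)
}
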