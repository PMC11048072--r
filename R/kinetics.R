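#' @title Reduced kinetic model of CHO fed-batch metabolism
#' @name kinetics
#' @description
#' A 12-state (plus volume) ODE model of central carbon metabolism in fed-batch
#' CHO culture: glucose, pyruvate, lactate, ammonium, asparagine, aspartate,
#' glutamate, serine, isoleucine, leucine, viable biomass, product (mAb) and
#' reactor volume. Rate laws are multiplicative Michaelis–Menten terms; the
#' lactate production-to-consumption shift is carried by four coupled
#' regulations: activation of glycolysis by asparagine, feedback inhibition of
#' lactate dehydrogenase by lactate (with a parametric Hill-type exponent), an
#' inverse coupling of lactate uptake to the glycolytic rate, and inhibition of
#' pyruvate entry into the TCA cycle by asparagine.
NULL

#' State variable names of the kinetic model
#' @export
kinetic_states <- function() {
  c("Glc", "Pyr", "Lac", "Amm", "Asn", "Asp", "Glu", "Ser", "Ile", "Leu",
    "X", "mAb", "V")
}

#' Model structure variants
#'
#' All variants share the common lactate-shift core (glycolysis lump, forward
#' and reverse lactate dehydrogenase, pyruvate-to-TCA lump, asparagine
#' degradation, aspartate-to-glutamate transamination, glutamate/serine/
#' isoleucine/leucine consumption lumps, growth, death, mAb synthesis).
#' Variant 2 additionally makes the glutamate/aspartate interconversion
#' reversible (adds a Glu-to-Asp lump); variant 3 adds a serine-to-pyruvate
#' lump.
#'
#' @param variant_id 1, 2 or 3.
#' @return object of class `model_structure`.
#' @export
model_structure <- function(variant_id = 1L) {
  if (!variant_id %in% 1:3) stop("variant_id must be 1, 2 or 3")
  structure(list(variant_id = as.integer(variant_id),
                 has_glu_to_asp = variant_id == 2L,
                 has_ser_to_pyr = variant_id == 3L),
            class = "model_structure")
}

#' @export
print.model_structure <- function(x, ...) {
  extras <- c(if (x$has_glu_to_asp) "Glu->Asp", if (x$has_ser_to_pyr) "Ser->Pyr")
  cat("<model_structure> variant ", x$variant_id,
      if (length(extras)) paste0(" (+", paste(extras, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Reference parameter set
#'
#' Documented reference ("truth") values used by the synthetic-data generator
#' and as calibration starting ranges. Orders of magnitude follow the usual
#' literature ranges for CHO central metabolism (Km of order 0.01–1 mmol/L for
#' intracellular steps, a few mmol/L for transport-level lumps; vmax of order
#' 0.01–1 mmol/g_DW/h). Units: vmax \[mmol/g_DW/h\], Km/Ki/Ka \[mmol/L\],
#' mumax/kd \[1/h\], qp \[mg/g_DW/h\], y_xs \[g_DW/mmol\].
#'
#' @param structure a `model_structure` (or variant id).
#' @return named numeric vector of class `parameter_set`.
#' @export
default_parameters <- function(structure = model_structure(1L)) {
  if (is.numeric(structure)) structure <- model_structure(structure)
  p <- c(
    vmax_gly = 0.08, km_glc = 0.5, ka_asn_gly = 3.0,
    vmax_ldh = 0.20, km_pyr = 0.30, ki_lac = 12, n_lac = 2,
    vmax_up = 0.13, km_lac = 3, alpha_gly = 0.008,
    vmax_tca = 0.30, km_pyr_tca = 0.30, ki_asn_tca = 4.0,
    vmax_asn = 0.02, km_asn = 1.2, y_amm_asn = 1.0,
    vmax_asp = 0.010, km_asp = 1.0,
    vmax_glu = 0.004, km_glu = 1.0,
    vmax_ser = 0.005, km_ser = 0.5,
    vmax_ile = 0.003, km_ile = 0.5,
    vmax_leu = 0.003, km_leu = 0.5,
    mumax = 0.022, kx_glc = 0.3, kx_asn = 0.4, kx_ser = 0.15,
    kx_ile = 0.1, kx_leu = 0.1,
    kd = 0.005, qp = 0.9, y_xs = 0.35)
  if (structure$has_glu_to_asp)
    p <- c(p, vmax_gluasp = 0.006, km_gluasp = 1.0)
  if (structure$has_ser_to_pyr)
    p <- c(p, vmax_serpyr = 0.008, km_serpyr = 0.5)
  class(p) <- c("parameter_set", "numeric")
  p
}

#' Read / write a parameter set as YAML
#' @param p a `parameter_set` (named numeric vector).
#' @param path file path.
#' @export
write_parameters_yaml <- function(p, path) {
  yaml::write_yaml(as.list(unclass(p)), path)
  invisible(p)
}

#' @rdname write_parameters_yaml
#' @export
read_parameters_yaml <- function(path) {
  p <- unlist(yaml::read_yaml(path))
  class(p) <- c("parameter_set", "numeric")
  p
}

#' Glycolysis rate: glucose-limited, asparagine-activated
#'
#' `r_gly = vmax_gly * Glc/(km_glc + Glc) * Asn/(ka_asn_gly + Asn)`
#'
#' @param state named state vector (needs `Glc`, `Asn`).
#' @param p a `parameter_set`.
#' @return rate \[mmol/g_DW/h\].
#' @export
rate_glycolysis <- function(state, p) {
  Glc <- max(state[["Glc"]], 0); Asn <- max(state[["Asn"]], 0)
  p[["vmax_gly"]] * Glc / (p[["km_glc"]] + Glc) *
    Asn / (p[["ka_asn_gly"]] + Asn)
}

#' Lactate production rate (LDH forward) with product feedback inhibition
#'
#' `r_ldh = vmax_ldh * Pyr/(km_pyr + Pyr) *
#'   ki_lac^n_lac / (ki_lac^n_lac + Lac^n_lac)`
#'
#' @inheritParams rate_glycolysis
#' @export
rate_lactate_production <- function(state, p) {
  Pyr <- max(state[["Pyr"]], 0); Lac <- max(state[["Lac"]], 0)
  kin <- p[["ki_lac"]]^p[["n_lac"]]
  p[["vmax_ldh"]] * Pyr / (p[["km_pyr"]] + Pyr) * kin / (kin + Lac^p[["n_lac"]])
}

#' Lactate uptake rate, inversely coupled to glycolytic activity
#'
#' `r_up = vmax_up * Lac/(km_lac + Lac) * alpha_gly/(alpha_gly + r_gly)`.
#' The inverse coupling to the glycolytic rate is implemented as a saturating
#' inverse term rather than a literal reciprocal, avoiding the singularity at
#' zero glycolytic flux while preserving strict monotone decrease in `r_gly`.
#'
#' @inheritParams rate_glycolysis
#' @param r_gly the current glycolytic rate (from [rate_glycolysis()]).
#' @export
rate_lactate_uptake <- function(state, p, r_gly) {
  stopifnot(r_gly >= 0)
  Lac <- max(state[["Lac"]], 0)
  p[["vmax_up"]] * Lac / (p[["km_lac"]] + Lac) *
    p[["alpha_gly"]] / (p[["alpha_gly"]] + r_gly)
}

#' Pyruvate entry into the TCA cycle, inhibited by asparagine
#'
#' `r_tca = vmax_tca * Pyr/(km_pyr_tca + Pyr) * ki_asn_tca/(ki_asn_tca + Asn)`
#'
#' @inheritParams rate_glycolysis
#' @export
rate_pyruvate_to_tca <- function(state, p) {
  Pyr <- max(state[["Pyr"]], 0); Asn <- max(state[["Asn"]], 0)
  p[["vmax_tca"]] * Pyr / (p[["km_pyr_tca"]] + Pyr) *
    p[["ki_asn_tca"]] / (p[["ki_asn_tca"]] + Asn)
}

#' Specific growth rate: multiplicative Monod terms
#' @keywords internal
rate_growth <- function(state, p) {
  mm <- function(C, k) { C <- max(C, 0); C / (k + C) }
  p[["mumax"]] * mm(state[["Glc"]], p[["kx_glc"]]) *
    mm(state[["Asn"]], p[["kx_asn"]]) * mm(state[["Ser"]], p[["kx_ser"]]) *
    mm(state[["Ile"]], p[["kx_ile"]]) * mm(state[["Leu"]], p[["kx_leu"]])
}

#' Evaluate all lumped reaction rates at a state
#'
#' @param state named state vector.
#' @param p a `parameter_set`.
#' @param structure a `model_structure`.
#' @return named vector of rates \[mmol/g_DW/h\] (growth `mu` in 1/h, `qp` in
#'   mg/g_DW/h).
#' @export
all_rates <- function(state, p, structure = model_structure(1L)) {
  mm <- function(C, k) { C <- max(C, 0); C / (k + C) }
  r_gly <- rate_glycolysis(state, p)
  r <- c(
    gly = r_gly,
    ldh = rate_lactate_production(state, p),
    lac_up = rate_lactate_uptake(state, p, r_gly),
    tca = rate_pyruvate_to_tca(state, p),
    asn_deg = p[["vmax_asn"]] * mm(state[["Asn"]], p[["km_asn"]]),
    asp_glu = p[["vmax_asp"]] * mm(state[["Asp"]], p[["km_asp"]]),
    glu_deg = p[["vmax_glu"]] * mm(state[["Glu"]], p[["km_glu"]]),
    ser_deg = p[["vmax_ser"]] * mm(state[["Ser"]], p[["km_ser"]]),
    ile_deg = p[["vmax_ile"]] * mm(state[["Ile"]], p[["km_ile"]]),
    leu_deg = p[["vmax_leu"]] * mm(state[["Leu"]], p[["km_leu"]]),
    mu = rate_growth(state, p),
    qp = p[["qp"]])
  if (structure$has_glu_to_asp)
    r["glu_asp"] <- p[["vmax_gluasp"]] * mm(state[["Glu"]], p[["km_gluasp"]])
  if (structure$has_ser_to_pyr)
    r["ser_pyr"] <- p[["vmax_serpyr"]] * mm(state[["Ser"]], p[["km_serpyr"]])
  r
}

#' Stoichiometry of the kinetic lumps over the modelled states
#'
#' Rows are metabolite states, columns the lumped reactions. Carbon that
#' leaves the modelled states (full oxidation, TCA-pool carbon of deaminated
#' amino acids, biomass) is tracked in the virtual rows `CO2_sink`,
#' `TCA_sink` and `biomass_sink` so that every lump is carbon-closed; these
#' rows are bookkeeping only and are not integrated.
#'
#' @param structure a `model_structure`.
#' @param p a `parameter_set` (yields enter the growth column).
#' @return numeric matrix (states + virtual sinks) x lumps.
#' @export
kinetic_stoichiometry <- function(structure, p) {
  lumps <- c("gly", "ldh", "lac_up", "tca", "asn_deg", "asp_glu", "glu_deg",
             "ser_deg", "ile_deg", "leu_deg", "growth",
             if (structure$has_glu_to_asp) "glu_asp",
             if (structure$has_ser_to_pyr) "ser_pyr")
  rows <- c("Glc", "Pyr", "Lac", "Amm", "Asn", "Asp", "Glu", "Ser", "Ile",
            "Leu", "CO2_sink", "TCA_sink", "biomass_sink")
  N <- matrix(0, length(rows), length(lumps), dimnames = list(rows, lumps))
  N["Glc", "gly"] <- -1; N["Pyr", "gly"] <- 2
  N["Pyr", "ldh"] <- -1; N["Lac", "ldh"] <- 1
  N["Lac", "lac_up"] <- -1; N["Pyr", "lac_up"] <- 1
  N["Pyr", "tca"] <- -1; N["CO2_sink", "tca"] <- 3
  N["Asn", "asn_deg"] <- -1; N["Asp", "asn_deg"] <- 1
  N["Amm", "asn_deg"] <- p[["y_amm_asn"]]
  N["Asp", "asp_glu"] <- -1; N["Glu", "asp_glu"] <- 1
  N["TCA_sink", "asp_glu"] <- -1          # Asp(C4) + TCA carbon -> Glu(C5)
  N["Glu", "glu_deg"] <- -1; N["Amm", "glu_deg"] <- 1
  N["TCA_sink", "glu_deg"] <- 5
  N["Ser", "ser_deg"] <- -1; N["Amm", "ser_deg"] <- 1
  N["TCA_sink", "ser_deg"] <- 3
  N["Ile", "ile_deg"] <- -1; N["Amm", "ile_deg"] <- 1
  N["TCA_sink", "ile_deg"] <- 6
  N["Leu", "leu_deg"] <- -1; N["Amm", "leu_deg"] <- 1
  N["TCA_sink", "leu_deg"] <- 6
  N["Glc", "growth"] <- -1 / p[["y_xs"]]
  N["biomass_sink", "growth"] <- 6 / p[["y_xs"]]  # carbon atoms per g_DW formed
  if (structure$has_glu_to_asp) {
    N["Glu", "glu_asp"] <- -1; N["Asp", "glu_asp"] <- 1
    N["TCA_sink", "glu_asp"] <- 1
  }
  if (structure$has_ser_to_pyr) {
    N["Ser", "ser_pyr"] <- -1; N["Pyr", "ser_pyr"] <- 1
    N["Amm", "ser_pyr"] <- 1
  }
  N
}

#' Carbon count per modelled species (virtual sinks count single C units)
#' @keywords internal
kinetic_carbon <- function() {
  c(Glc = 6, Pyr = 3, Lac = 3, Amm = 0, Asn = 4, Asp = 4, Glu = 5, Ser = 3,
    Ile = 6, Leu = 6, CO2_sink = 1, TCA_sink = 1, biomass_sink = 1)
}

#' Right-hand side of the kinetic fed-batch model
#'
#' For each concentration `dC/dt = (N r) X + (F/V)(C_feed - C)`, with
#' `dX/dt = (mu - kd) X - (F/V) X`, `dmAb/dt = qp X - (F/V) mAb` and
#' `dV/dt = F`. Bolus additions are handled as instantaneous events by
#' [simulate_model()], not in the right-hand side. Negative state excursions
#' are clipped to zero for rate evaluation.
#'
#' @param t time \[h\].
#' @param state named state vector (see [kinetic_states()]).
#' @param p a `parameter_set`.
#' @param structure a `model_structure`.
#' @param schedule a `feed_schedule` or `NULL`.
#' @return list with the derivative vector (deSolve convention).
#' @export
ode_rhs <- function(t, state, p, structure = model_structure(1L),
                    schedule = NULL, N = NULL) {
  s <- pmax(state, 0)
  r <- all_rates(s, p, structure)
  if (is.null(N)) N <- kinetic_stoichiometry(structure, p)
  lumps <- setdiff(colnames(N), "growth")
  rr <- c(r[lumps], growth = unname(r[["mu"]]))
  names(rr) <- c(lumps, "growth")
  mets <- c("Glc", "Pyr", "Lac", "Amm", "Asn", "Asp", "Glu", "Ser", "Ile", "Leu")
  dC_bio <- as.vector(N[mets, c(lumps, "growth"), drop = FALSE] %*%
                        rr[c(lumps, "growth")]) * s[["X"]]
  FF <- if (is.null(schedule)) 0 else schedule$continuous$rate
  V <- s[["V"]]
  cf <- numeric(length(mets)); names(cf) <- mets
  if (!is.null(schedule)) {
    comp <- schedule$continuous$composition
    shared <- intersect(names(comp), mets)
    cf[shared] <- unlist(comp[shared])
  }
  dil <- if (V > 0) FF / V else 0
  dC <- dC_bio + dil * (cf - s[mets])
  dX <- (r[["mu"]] - p[["kd"]]) * s[["X"]] - dil * s[["X"]]
  dmAb <- r[["qp"]] * s[["X"]] - dil * s[["mAb"]]
  dV <- FF
  d <- c(dC, dX, dmAb, dV)
  names(d) <- kinetic_states()
  list(unname(d[names(state)]))
}

#' Simulate the kinetic fed-batch model
#'
#' Stiff-capable integration (lsoda) with bolus additions applied as
#' instantaneous, perfectly mixed state jumps at daily checkpoints:
#' `C+ = (C V + C_b V_b) / (V + V_b)`, `V+ = V + V_b`. Scheduled boluses
#' (e.g. bolus medium, cysteine volume), the glucose-threshold refill and the
#' condition-specific lactate trigger are all evaluated at the daily
#' checkpoints, mirroring once-daily sampling-and-feeding operation. All
#' applied boluses are logged.
#'
#' @param structure a `model_structure`.
#' @param p a `parameter_set`.
#' @param schedule a `feed_schedule` or `NULL`.
#' @param t_span `c(t0, t1)` in hours, within \[0, 336\].
#' @param init named initial state (see [kinetic_states()]).
#' @param dt_dense dense output step \[h\] (default 1).
#' @param sample_interval sampling grid spacing \[h\] (default 24).
#' @param clamp_states names of states held fixed at their initial value
#'   (derivative zeroed, events reset them); used for mechanistic what-if
#'   experiments such as keeping asparagine at its seeding level.
#' @return object of class `kinetic_trajectory`: data frame `dense` (hourly),
#'   data frame `sampled` (24 h grid), `bolus_log` data frame, and the inputs.
#' @export
simulate_model <- function(structure, p, schedule, t_span, init,
                           dt_dense = 1, sample_interval = 24,
                           clamp_states = character(0)) {
  stopifnot(t_span[1] >= 0, t_span[2] <= 336, t_span[2] > t_span[1])
  states <- kinetic_states()
  if (!all(states %in% names(init))) stop("init missing states")
  y0 <- init[states]
  times <- sort(unique(c(seq(t_span[1], t_span[2], by = dt_dense), t_span[2])))
  check_times <- if (is.null(schedule)) numeric(0) else
    schedule$check_times[schedule$check_times > t_span[1] &
                         schedule$check_times <= t_span[2]]
  times <- sort(unique(c(times, check_times)))
  log_env <- new.env()
  log_env$rows <- list()
  eventfun <- function(t, y, parms) {
    names(y) <- states
    y <- apply_daily_events(t, y, schedule, log_env)
    y[clamp_states] <- y0[clamp_states]
    y
  }
  fast <- make_fast_rhs(p, structure, schedule)
  clamp_idx <- match(clamp_states, states)
  rhs <- function(t, y, parms) {
    d <- fast(t, y)
    if (length(clamp_idx)) d[[1]][clamp_idx] <- 0
    d
  }
  out <- deSolve::ode(y = unname(y0), times = times, func = rhs, parms = NULL,
                      method = "lsoda",
                      events = if (length(check_times))
                        list(func = eventfun, time = check_times) else NULL,
                      rtol = 1e-7, atol = 1e-7)
  if (attr(out, "istate")[1] < 0)
    stop("integration failure (istate ", attr(out, "istate")[1],
         ") for parameter set: ",
         paste(names(p), signif(unclass(p), 3), sep = "=", collapse = ", "))
  dense <- as.data.frame(out)
  names(dense) <- c("time", states)
  grid <- seq(t_span[1], t_span[2], by = sample_interval)
  sampled <- dense[dense$time %in% grid, , drop = FALSE]
  rownames(sampled) <- NULL
  bl <- if (length(log_env$rows)) do.call(rbind, log_env$rows) else
    data.frame(time_h = numeric(0), volume_L = numeric(0), kind = character(0))
  structure(list(dense = dense, sampled = sampled, bolus_log = bl,
                 structure = structure, params = p, schedule = schedule),
            class = "kinetic_trajectory")
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  cat("<kinetic_trajectory> t = [", min(x$dense$time), ", ", max(x$dense$time),
      "] h; ", nrow(x$bolus_log), " boluses applied\n", sep = "")
  invisible(x)
}

#' Scalar-arithmetic right-hand side used by the integrator
#'
#' Closure over unpacked parameters; algebraically identical to [ode_rhs()]
#' (asserted by the test suite) but avoids per-call allocation of names and
#' stoichiometry, which dominates integration time otherwise.
#' State order: Glc, Pyr, Lac, Amm, Asn, Asp, Glu, Ser, Ile, Leu, X, mAb, V.
#' @keywords internal
make_fast_rhs <- function(p, structure, schedule) {
  vg <- p[["vmax_gly"]]; kg <- p[["km_glc"]]; ka <- p[["ka_asn_gly"]]
  vl <- p[["vmax_ldh"]]; kp <- p[["km_pyr"]]
  kin <- p[["ki_lac"]]^p[["n_lac"]]; nl <- p[["n_lac"]]
  vu <- p[["vmax_up"]]; kl <- p[["km_lac"]]; al <- p[["alpha_gly"]]
  vt <- p[["vmax_tca"]]; kpt <- p[["km_pyr_tca"]]; kit <- p[["ki_asn_tca"]]
  va <- p[["vmax_asn"]]; kasn <- p[["km_asn"]]; yam <- p[["y_amm_asn"]]
  vap <- p[["vmax_asp"]]; kap <- p[["km_asp"]]
  vgl <- p[["vmax_glu"]]; kgl <- p[["km_glu"]]
  vse <- p[["vmax_ser"]]; kse <- p[["km_ser"]]
  vil <- p[["vmax_ile"]]; kil <- p[["km_ile"]]
  vle <- p[["vmax_leu"]]; kle <- p[["km_leu"]]
  mumax <- p[["mumax"]]; kxg <- p[["kx_glc"]]; kxa <- p[["kx_asn"]]
  kxs <- p[["kx_ser"]]; kxi <- p[["kx_ile"]]; kxl <- p[["kx_leu"]]
  kd <- p[["kd"]]; qp <- p[["qp"]]; yxs <- p[["y_xs"]]
  v2 <- structure$has_glu_to_asp
  v3 <- structure$has_ser_to_pyr
  vga <- if (v2) p[["vmax_gluasp"]] else 0
  kga <- if (v2) p[["km_gluasp"]] else 1
  vsp <- if (v3) p[["vmax_serpyr"]] else 0
  ksp <- if (v3) p[["km_serpyr"]] else 1
  FF <- if (is.null(schedule)) 0 else schedule$continuous$rate
  comp <- if (is.null(schedule)) list() else schedule$continuous$composition
  cf <- numeric(10)
  fd_names <- c("Glc", "Pyr", "Lac", "Amm", "Asn", "Asp", "Glu", "Ser",
                "Ile", "Leu")
  for (i in seq_along(fd_names))
    if (fd_names[i] %in% names(comp)) cf[i] <- comp[[fd_names[i]]]
  function(t, y) {
    Glc <- max(y[1], 0); Pyr <- max(y[2], 0); Lac <- max(y[3], 0)
    Amm <- max(y[4], 0); Asn <- max(y[5], 0); Asp <- max(y[6], 0)
    Glu <- max(y[7], 0); Ser <- max(y[8], 0); Ile <- max(y[9], 0)
    Leu <- max(y[10], 0); X <- max(y[11], 0); V <- y[13]
    r_gly <- vg * Glc / (kg + Glc) * Asn / (ka + Asn)
    r_ldh <- vl * Pyr / (kp + Pyr) * kin / (kin + Lac^nl)
    r_up <- vu * Lac / (kl + Lac) * al / (al + r_gly)
    r_tca <- vt * Pyr / (kpt + Pyr) * kit / (kit + Asn)
    r_asn <- va * Asn / (kasn + Asn)
    r_asp <- vap * Asp / (kap + Asp)
    r_glu <- vgl * Glu / (kgl + Glu)
    r_ser <- vse * Ser / (kse + Ser)
    r_ile <- vil * Ile / (kil + Ile)
    r_leu <- vle * Leu / (kle + Leu)
    r_ga <- if (v2) vga * Glu / (kga + Glu) else 0
    r_sp <- if (v3) vsp * Ser / (ksp + Ser) else 0
    mu <- mumax * Glc / (kxg + Glc) * Asn / (kxa + Asn) *
      Ser / (kxs + Ser) * Ile / (kxi + Ile) * Leu / (kxl + Leu)
    dil <- if (V > 0) FF / V else 0
    d1 <- (-r_gly - mu / yxs) * X + dil * (cf[1] - Glc)
    d2 <- (2 * r_gly + r_up + r_sp - r_ldh - r_tca) * X + dil * (cf[2] - Pyr)
    d3 <- (r_ldh - r_up) * X + dil * (cf[3] - Lac)
    d4 <- (yam * r_asn + r_glu + r_ser + r_ile + r_leu + r_sp) * X +
      dil * (cf[4] - Amm)
    d5 <- -r_asn * X + dil * (cf[5] - Asn)
    d6 <- (r_asn - r_asp + r_ga) * X + dil * (cf[6] - Asp)
    d7 <- (r_asp - r_glu - r_ga) * X + dil * (cf[7] - Glu)
    d8 <- (-r_ser - r_sp) * X + dil * (cf[8] - Ser)
    d9 <- -r_ile * X + dil * (cf[9] - Ile)
    d10 <- -r_leu * X + dil * (cf[10] - Leu)
    d11 <- (mu - kd) * X - dil * X
    d12 <- qp * X - dil * max(y[12], 0)
    list(c(d1, d2, d3, d4, d5, d6, d7, d8, d9, d10, d11, d12, FF))
  }
}

#' Apply the daily bolus/control events to a state
#' @keywords internal
apply_daily_events <- function(t, y, schedule, log_env = NULL) {
  states <- kinetic_states()
  conc_states <- setdiff(states, "V")
  mix <- function(y, vol, conc, kind) {
    if (vol <= 0) stop("bolus volume must be positive")
    V <- y[["V"]]
    cb <- numeric(length(conc_states)); names(cb) <- conc_states
    shared <- intersect(names(conc), conc_states)
    cb[shared] <- unlist(conc[shared])
    y[conc_states] <- (y[conc_states] * V + cb * vol) / (V + vol)
    y[["V"]] <- V + vol
    if (!is.null(log_env)) {
      row <- data.frame(time_h = t, volume_L = vol, kind = kind)
      for (nm in conc_states) row[[paste0("conc_", nm)]] <- cb[[nm]]
      log_env$rows[[length(log_env$rows) + 1L]] <- row
    }
    y
  }
  if (is.null(schedule)) return(y)
  bl <- schedule$boluses
  if (!is.null(bl) && nrow(bl)) {
    hit <- which(abs(bl$time_h - t) < 1e-6)
    for (k in hit) {
      cc <- as.list(bl[k, grep("^conc_", names(bl)), drop = FALSE])
      names(cc) <- sub("^conc_", "", names(cc))
      y <- mix(y, bl$volume_L[k], cc, kind = bl$kind[k])
    }
  }
  lc <- schedule$lactate_control
  if (!is.null(lc) && t >= lc$window_h[1] && t <= lc$window_h[2] &&
      y[["Lac"]] < lc$threshold) {
    vol <- y[["V"]] * (lc$target - y[["Lac"]]) / (lc$stock_conc - lc$target)
    if (vol > 0) y <- mix(y, vol, list(Lac = lc$stock_conc), "lactate_control")
  }
  gc <- schedule$glucose_control
  if (!is.null(gc) && y[["Glc"]] < gc$threshold) {
    vol <- y[["V"]] * (gc$target - y[["Glc"]]) / (gc$stock_conc - gc$target)
    if (vol > 0) y <- mix(y, vol, list(Glc = gc$stock_conc), "glucose_control")
  }
  y
}
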