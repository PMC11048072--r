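# Independent oracles and small fixtures used across the suite.

# --- toy networks ---------------------------------------------------------

toy_metabolites <- function(ids, carbon = 3, nitrogen = 0) {
  data.frame(id = ids, name = ids,
             compartment = ifelse(grepl("_e$", ids), "extracellular", "cytosol"),
             carbon = carbon, nitrogen = nitrogen, stringsAsFactors = FALSE)
}

toy_reaction_row <- function(id, equation, reversible = FALSE, lb = 0,
                             ub = 1000, exch = FALSE, meas = FALSE,
                             subsystem = "transport") {
  data.frame(id = id, equation = equation, reversible = reversible,
             lower_bound = lb, upper_bound = ub, is_exchange = exch,
             is_measured = meas, subsystem = subsystem,
             stringsAsFactors = FALSE)
}

# linear chain A_ext -> A -> B -> B_ext with uptake cap
chain_network <- function(uptake_cap = 5) {
  rx <- rbind(
    toy_reaction_row("EX_A", "A_e ->", TRUE, -uptake_cap, 0, exch = TRUE,
                     meas = TRUE),
    toy_reaction_row("T_A", "A_e -> A"),
    toy_reaction_row("R1", "A -> B"),
    toy_reaction_row("T_B", "B -> B_e"),
    toy_reaction_row("EX_B", "B_e ->", FALSE, 0, 1000, exch = TRUE,
                     meas = TRUE))
  build_network(rx, toy_metabolites(c("A_e", "A", "B", "B_e")),
                objective = "EX_B")
}

# branched: A splits into B and C with different yields of the product P
branched_network <- function() {
  rx <- rbind(
    toy_reaction_row("EX_A", "A_e ->", TRUE, -10, 0, exch = TRUE),
    toy_reaction_row("T_A", "A_e -> A"),
    toy_reaction_row("R1", "A -> P", ub = 6),
    toy_reaction_row("R2", "A -> 2 P", ub = 3),
    toy_reaction_row("EX_P", "P ->", FALSE, 0, 1000, exch = TRUE))
  mets <- toy_metabolites(c("A_e", "A", "P"))
  mets$carbon <- c(6, 6, 6)
  # R2 doubles P, so set P carbon to 3 to keep elements closed
  mets$carbon[mets$id == "P"] <- 3
  rx$equation[rx$id == "R1"] <- "A -> P + P_sink"
  mets <- rbind(mets, data.frame(id = "P_sink", name = "P_sink",
                                 compartment = "cytosol", carbon = 3,
                                 nitrogen = 0))
  rx <- rbind(rx, toy_reaction_row("EX_SINK", "P_sink ->", FALSE, 0, 1000,
                                   exch = TRUE))
  build_network(rx, mets, objective = "EX_P")
}

# --- brute-force LP oracle ------------------------------------------------

# enumerate candidate vertices of {S v = 0, lb <= v <= ub} by fixing every
# subset of free variables at a bound and solving the equality system for the
# rest; returns the maximum of the objective over feasible candidates
vertex_enumeration_lp <- function(S, lb, ub, cc) {
  n <- ncol(S)
  ns_dim <- n - qr(S)$rank
  if (ns_dim > 6) stop("oracle limited to small polytopes")
  best <- -Inf
  idx <- seq_len(n)
  combos <- utils::combn(n, ns_dim, simplify = FALSE)
  for (fix in combos) {
    grid <- expand.grid(rep(list(c(1, 2)), ns_dim))
    for (g in seq_len(nrow(grid))) {
      vals <- ifelse(unlist(grid[g, ]) == 1, lb[fix], ub[fix])
      free <- setdiff(idx, fix)
      A <- S[, free, drop = FALSE]
      b <- -as.vector(S[, fix, drop = FALSE] %*% vals)
      sol <- tryCatch(qr.solve(A, b, tol = 1e-10), error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n); v[fix] <- vals; v[free] <- sol
      if (max(abs(S %*% v)) > 1e-7) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      best <- max(best, sum(cc * v))
    }
  }
  best
}

# --- per-point tricube weighted least squares (LOWESS oracle) -------------

lowess_wls_oracle <- function(x, y, frac) {
  n <- length(x)
  k <- max(2L, floor(frac * n))
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[k]
    w <- (1 - pmin(d / max(h, .Machine$double.eps), 1)^3)^3
    use <- w > 0
    fit <- stats::lm.wfit(cbind(1, x[use]), y[use], w[use])
    sum(fit$coefficients * c(1, x[i]))
  }, numeric(1))
}

# --- element accounting over a reaction table (network oracle) ------------

element_surplus_oracle <- function(reaction_file, metabolite_file) {
  rx <- utils::read.delim(reaction_file, stringsAsFactors = FALSE)
  mt <- utils::read.delim(metabolite_file, stringsAsFactors = FALSE)
  cC <- stats::setNames(mt$carbon, mt$id)
  cN <- stats::setNames(mt$nitrogen, mt$id)
  internal <- !rx$is_exchange &
    !rx$subsystem %in% c("biomass", "product", "energy")
  out <- data.frame(id = rx$id[internal], c_sur = NA_real_, n_sur = NA_real_)
  for (r in seq_len(nrow(out))) {
    eq <- rx$equation[rx$id == out$id[r]]
    sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
    if (length(sides) == 1L) sides <- c(sides, "")
    tally <- function(txt, sgn) {
      txt <- trimws(txt)
      if (!nzchar(txt)) return(c(0, 0))
      total <- c(0, 0)
      for (tm in trimws(strsplit(txt, "+", fixed = TRUE)[[1]])) {
        parts <- strsplit(tm, "[[:space:]]+")[[1]]
        coef <- if (length(parts) == 2L) as.numeric(parts[1]) else 1
        id <- parts[length(parts)]
        total <- total + sgn * coef * c(cC[[id]], cN[[id]])
      }
      total
    }
    s <- tally(sides[1], -1) + tally(sides[2], 1)
    out$c_sur[r] <- s[1]; out$n_sur[r] <- s[2]
  }
  out
}

# --- misc -----------------------------------------------------------------

default_network_files <- function() {
  c(reactions = system.file("extdata", "default_network_reactions.tsv",
                            package = "chomet"),
    metabolites = system.file("extdata", "default_network_metabolites.tsv",
                              package = "chomet"))
}

# ATP-yield scenarios on the default network (used by several tests)
atp_yield_network <- function(net, oxidative) {
  net <- set_bounds(net, "EX_glc", -1, -1)
  for (ex in c("EX_asn", "EX_asp", "EX_glu", "EX_ser", "EX_ile", "EX_leu",
               "EX_biomass", "EX_mab"))
    net <- set_bounds(net, ex, 0, 0)
  if (oxidative) {
    net <- set_bounds(net, "EX_lac", 0, 0)
    net <- set_bounds(net, "EX_o2", -1000, 0)
    net <- set_bounds(net, "EX_co2", 0, 1000)
    net <- set_bounds(net, "EX_nh4", 0, 0)
  } else {
    net <- set_bounds(net, "EX_o2", 0, 0)
    net <- set_bounds(net, "EX_co2", 0, 0)
    net <- set_bounds(net, "EX_lac", 0, 1000)
  }
  net
}

reference_trajectory <- function(condition = "HSD_CONTROL", factor = 1,
                                 days = NULL, ...) {
  if (is.null(days)) days <- if (condition == "STD_FB") 14 else 12
  st <- model_structure(1)
  simulate_model(st, default_parameters(st),
                 condition_schedule(condition, days, asn_feed_factor = factor),
                 c(0, days * 24), initial_state(condition), ...)
}
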