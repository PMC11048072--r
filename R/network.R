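#' @title Metabolic network construction and validation
#' @name network
#' @description
#' A `metabolic_network` holds the metabolites and stoichiometric reactions of
#' a reduced central-carbon-metabolism model of CHO cells, together with flux
#' bounds, exchange flags and an objective reaction. It is the substrate for
#' flux balance analysis ([solve_fba()]) and metabolic flux analysis
#' ([run_mfa()]).
NULL

#' Parse a reaction equation string
#'
#' Equations use the native table format `"A + 2 B -> C"`. Coefficients default
#' to 1; an empty side denotes an exchange/drain (e.g. `"glc_e ->"`).
#'
#' @param equation character scalar.
#' @return named numeric vector of signed stoichiometric coefficients
#'   (negative = consumed).
#' @keywords internal
parse_equation <- function(equation) {
  stopifnot(is.character(equation), length(equation) == 1L)
  sides <- strsplit(equation, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2L) stop("malformed equation: ", equation)
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1; id <- parts
      } else if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) stop("bad coefficient in term '", tm, "'")
        id <- parts[2]
      } else stop("bad term '", tm, "' in equation: ", equation)
      out[id] <- (if (is.na(out[id])) 0 else out[id]) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (id in names(rhs)) st[id] <- (if (id %in% names(st)) st[id] else 0) + rhs[id]
  st <- st[st != 0]
  if (!length(st)) stop("equation has empty stoichiometry: ", equation)
  st
}

#' Render stoichiometry back into an equation string
#' @keywords internal
format_equation <- function(st) {
  fmt <- function(x, ids) {
    if (!length(ids)) return("")
    paste(vapply(ids, function(i) {
      cf <- abs(x[[i]])
      if (cf == 1) i else paste(format(cf, digits = 15), i)
    }, character(1)), collapse = " + ")
  }
  lhs <- fmt(st, names(st)[st < 0])
  rhs <- fmt(st, names(st)[st > 0])
  paste(lhs, "->", rhs)
}

#' Build a validated metabolic network
#'
#' Assembles a `metabolic_network` from a reaction table and a metabolite
#' table, resolving equation strings into stoichiometries and (by default)
#' enforcing carbon/nitrogen balance of every internal reaction. Exchange,
#' biomass, product and energy-drain reactions are exempt from element
#' balancing, since they represent boundary drains or pseudo-reactions whose
#' elemental composition is not modelled.
#'
#' @param reactions data frame with columns `id`, `equation`, `reversible`,
#'   `lower_bound`, `upper_bound`, `is_exchange`, `is_measured`, `subsystem`.
#' @param metabolites data frame with columns `id`, `name`, `compartment`,
#'   `carbon`, `nitrogen`.
#' @param objective id of the objective reaction (default `"BIOMASS"`).
#' @param balance one of `"error"` (default), `"warn"`, `"ignore"`: what to do
#'   when an internal reaction is element-imbalanced.
#' @return an object of class `metabolic_network`.
#' @export
build_network <- function(reactions, metabolites, objective = "BIOMASS",
                          balance = c("error", "warn", "ignore")) {
  balance <- match.arg(balance)
  if (is.null(reactions) || nrow(reactions) == 0L) stop("empty network")
  need_r <- c("id", "equation", "reversible", "lower_bound", "upper_bound",
              "is_exchange", "is_measured", "subsystem")
  need_m <- c("id", "compartment", "carbon", "nitrogen")
  if (!all(need_r %in% names(reactions)))
    stop("reaction table missing columns: ",
         paste(setdiff(need_r, names(reactions)), collapse = ", "))
  if (!all(need_m %in% names(metabolites)))
    stop("metabolite table missing columns: ",
         paste(setdiff(need_m, names(metabolites)), collapse = ", "))
  if (anyDuplicated(reactions$id)) stop("duplicate reaction id")
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite id")
  if (any(metabolites$carbon < 0) || any(metabolites$nitrogen < 0))
    stop("negative element count")
  stoich <- lapply(reactions$equation, parse_equation)
  names(stoich) <- reactions$id
  used <- unique(unlist(lapply(stoich, names)))
  unknown <- setdiff(used, metabolites$id)
  if (length(unknown))
    stop("unknown metabolite in stoichiometry: ", paste(unknown, collapse = ", "))
  bad <- reactions$lower_bound > reactions$upper_bound
  if (any(bad)) stop("lower_bound > upper_bound for: ",
                     paste(reactions$id[bad], collapse = ", "))
  irr <- !reactions$reversible & reactions$lower_bound < 0
  if (any(irr)) stop("irreversible reaction with negative lower bound: ",
                     paste(reactions$id[irr], collapse = ", "))
  if (!objective %in% reactions$id) stop("objective reaction not in network")
  net <- structure(list(metabolites = as.data.frame(metabolites),
                        reactions = as.data.frame(reactions),
                        stoichiometry = stoich,
                        objective_id = objective),
                   class = "metabolic_network")
  if (balance != "ignore") {
    rep <- check_balances(net)
    rep <- rep[!rep$exempt, ]
    flag <- rep[abs(rep$carbon_surplus) > 1e-9 |
                  abs(rep$nitrogen_surplus) > 1e-9, ]
    if (nrow(flag)) {
      msg <- paste0("unbalanced internal reaction(s): ",
                    paste(flag$id, collapse = ", "))
      if (balance == "error") stop(msg) else warning(msg)
    }
  }
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions; objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' The default CHO central-carbon network
#'
#' A documented ~44-reaction network covering glycolysis, oxidative PPP entry,
#' the TCA cycle, anaplerosis (pyruvate carboxylase and a malic-enzyme route),
#' lactate exchange, catabolism of asparagine, aspartate, glutamate, serine,
#' isoleucine and leucine, ammonium release, biomass and mAb pseudo-reactions,
#' an ATP drain, and oxidative phosphorylation with P/O = 3 for mitochondrial
#' NADH and 2 for FADH2 (cytosolic NADH enters at FADH2 yield through a
#' glycerol-3-phosphate-shuttle equivalent, so complete oxidation of glucose
#' yields 36 ATP). Shipped as editable tab-separated tables so users can
#' substitute their own reaction list.
#'
#' @return a `metabolic_network`.
#' @export
default_network <- function() {
  rf <- system.file("extdata", "default_network_reactions.tsv",
                    package = "chomet", mustWork = TRUE)
  mf <- system.file("extdata", "default_network_metabolites.tsv",
                    package = "chomet", mustWork = TRUE)
  read_network_tsv(rf, mf)
}

#' Read / write a network in the native tab-separated format
#'
#' @param reaction_file,metabolite_file paths to the two TSV tables.
#' @param objective objective reaction id; defaults to `"BIOMASS"` when present,
#'   else the first reaction.
#' @return `read_network_tsv`: a `metabolic_network`.
#' @export
read_network_tsv <- function(reaction_file, metabolite_file, objective = NULL) {
  rx <- utils::read.delim(reaction_file, stringsAsFactors = FALSE)
  mt <- utils::read.delim(metabolite_file, stringsAsFactors = FALSE)
  if (is.null(objective))
    objective <- if ("BIOMASS" %in% rx$id) "BIOMASS" else rx$id[1]
  build_network(rx, mt, objective = objective)
}

#' @rdname read_network_tsv
#' @param network a `metabolic_network`.
#' @export
write_network_tsv <- function(network, reaction_file, metabolite_file) {
  stopifnot(inherits(network, "metabolic_network"))
  rx <- network$reactions
  rx$equation <- vapply(network$stoichiometry[rx$id], format_equation, character(1))
  utils::write.table(rx, reaction_file, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(network$metabolites, metabolite_file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(network)
}

#' Stoichiometric matrix of a network
#'
#' @param network a `metabolic_network`.
#' @return numeric matrix S (metabolites x reactions); `S[i, j]` is the
#'   coefficient of metabolite i in reaction j, columns in reaction order.
#' @export
stoichiometric_matrix <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  mets <- network$metabolites$id
  rxns <- network$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in rxns) {
    st <- network$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

#' Reactions exempt from element balancing
#' @keywords internal
balance_exempt <- function(network) {
  rx <- network$reactions
  rx$is_exchange | rx$subsystem %in% c("biomass", "product", "energy")
}

#' Carbon/nitrogen balance report
#'
#' Computes the per-reaction carbon and nitrogen surplus (products minus
#' substrates) of every internal reaction. Exchange, biomass, product and
#' energy-drain reactions are exempt and reported with `exempt = TRUE`.
#'
#' @param network a `metabolic_network`.
#' @return data frame with columns `id`, `carbon_surplus`, `nitrogen_surplus`,
#'   `exempt`; a clean network has zero surplus on all non-exempt rows.
#' @export
check_balances <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  cC <- stats::setNames(network$metabolites$carbon, network$metabolites$id)
  cN <- stats::setNames(network$metabolites$nitrogen, network$metabolites$id)
  ex <- balance_exempt(network)
  ids <- network$reactions$id
  cs <- ns <- numeric(length(ids))
  for (k in seq_along(ids)) {
    st <- network$stoichiometry[[ids[k]]]
    cs[k] <- sum(st * cC[names(st)])
    ns[k] <- sum(st * cN[names(st)])
  }
  out <- data.frame(id = ids, carbon_surplus = cs, nitrogen_surplus = ns,
                    exempt = ex, stringsAsFactors = FALSE)
  out[out$exempt, c("carbon_surplus", "nitrogen_surplus")] <- NA_real_
  out
}

#' Flux bounds of a network
#' @keywords internal
network_bounds <- function(network) {
  list(lb = stats::setNames(network$reactions$lower_bound, network$reactions$id),
       ub = stats::setNames(network$reactions$upper_bound, network$reactions$id))
}

#' Set bounds on named reactions
#'
#' @param network a `metabolic_network`.
#' @param id reaction id(s).
#' @param lb,ub new bounds (recycled); `NULL` leaves a bound unchanged.
#' @return the modified network.
#' @export
set_bounds <- function(network, id, lb = NULL, ub = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  i <- match(id, network$reactions$id)
  if (anyNA(i)) stop("unknown reaction id: ", paste(id[is.na(i)], collapse = ", "))
  if (!is.null(lb)) network$reactions$lower_bound[i] <- rep_len(lb, length(i))
  if (!is.null(ub)) network$reactions$upper_bound[i] <- rep_len(ub, length(i))
  bad <- network$reactions$lower_bound > network$reactions$upper_bound
  if (any(bad)) stop("lower_bound > upper_bound after edit: ",
                     paste(network$reactions$id[bad], collapse = ", "))
  network
}
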