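#' Exact linear programming over the flux polytope via regularised QP
#'
#' Maximises `c'v` subject to `S v = rhs` and `lb <= v <= ub` using
#' [quadprog::solve.QP()]. The problem solved is `min ||v||^2 - t c'v`; for a
#' compact polytope, once `t` exceeds a finite threshold the solution is
#' exactly the minimum-norm point of the optimal face of the LP (the objective
#' gradient is orthogonal to that face), so escalating `t` until the objective
#' stabilises yields the exact LP optimum together with the minimum-2-norm
#' optimal flux distribution. Variables are internally rescaled by `1/t` and
#' near-infinite bounds (|bound| >= `big`) are enforced lazily through an outer
#' active-set loop, both of which keep the quadratic subproblems
#' well-conditioned.
#'
#' @param S constraint matrix (rows = metabolites).
#' @param lb,ub flux bounds.
#' @param cc objective coefficient vector (length ncol(S)).
#' @param rhs right-hand side of the equality constraints (default zero).
#' @param maximize logical.
#' @param big bounds with absolute value at or above this are treated lazily.
#' @return list with `v` (named flux vector), `obj`, `status`
#'   (`"optimal"`/`"infeasible"`).
#' @keywords internal
lp_polytope <- function(S, lb, ub, cc, rhs = NULL, maximize = TRUE, big = 999) {
  n <- ncol(S)
  stopifnot(length(lb) == n, length(ub) == n, length(cc) == n)
  if (is.null(rhs)) rhs <- numeric(nrow(S))
  if (!maximize) cc <- -cc
  fixed <- (ub - lb) < 1e-12
  rr <- rhs - as.vector(S[, fixed, drop = FALSE] %*% lb[fixed])
  Sf <- S[, !fixed, drop = FALSE]
  nf <- ncol(Sf)
  if (nf == 0L) {
    v <- lb
    names(v) <- colnames(S)
    ok <- max(abs(as.vector(S %*% v) - rhs)) < 1e-8
    return(list(v = v, obj = if (maximize) sum(cc * v) else -sum(cc * v),
                status = if (ok) "optimal" else "infeasible"))
  }
  qrS <- qr(t(Sf))
  keep <- qrS$pivot[seq_len(qrS$rank)]
  Sk <- Sf[keep, , drop = FALSE]
  rk <- rr[keep]
  meq <- nrow(Sk)
  lbf <- lb[!fixed]; ubf <- ub[!fixed]; ccf <- cc[!fixed]
  tight_lb <- which(lbf > -big)
  tight_ub <- which(ubf < big)
  Dm <- diag(nf)
  solve_t <- function(tt, elb, eub) {
    Amat <- cbind(t(Sk),
                  diag(nf)[, elb, drop = FALSE],
                  -diag(nf)[, eub, drop = FALSE])
    bvec <- c(rk / tt, lbf[elb] / tt, -ubf[eub] / tt)
    quadprog::solve.QP(Dm, ccf, Amat, bvec, meq = meq)$solution * tt
  }
  extra_lb <- integer(0); extra_ub <- integer(0)
  for (outer in 1:25) {
    elb <- union(tight_lb, extra_lb)
    eub <- union(tight_ub, extra_ub)
    tt <- 1; zprev <- NA_real_; sol <- NULL
    repeat {
      sol <- tryCatch(solve_t(tt, elb, eub), error = function(e) e)
      if (inherits(sol, "error")) {
        if (grepl("inconsistent", conditionMessage(sol)))
          return(list(v = stats::setNames(rep(NA_real_, n), colnames(S)),
                      obj = NA_real_, status = "infeasible"))
        stop(sol)
      }
      # if the path escapes a lazily handled bound, add it right away rather
      # than escalating further (the objective cannot stabilise otherwise)
      if (any(sol < lbf - 1e-7) || any(sol > ubf + 1e-7)) break
      z <- sum(ccf * sol)
      if (!is.na(zprev) && abs(z - zprev) <= 1e-9 * (1 + abs(z))) break
      zprev <- z
      tt <- tt * 2
      if (tt > 2^44) stop("LP objective did not stabilise")
    }
    viol_lb <- which(sol < lbf - 1e-7)
    viol_ub <- which(sol > ubf + 1e-7)
    if (!length(viol_lb) && !length(viol_ub)) {
      v <- numeric(n)
      v[fixed] <- lb[fixed]
      v[!fixed] <- sol
      names(v) <- colnames(S)
      # check full equality system (dropped dependent rows must be consistent)
      if (max(abs(as.vector(S %*% v) - rhs)) > 1e-6)
        return(list(v = stats::setNames(rep(NA_real_, n), colnames(S)),
                    obj = NA_real_, status = "infeasible"))
      obj <- sum(cc * v)
      return(list(v = v, obj = if (maximize) obj else -obj, status = "optimal"))
    }
    extra_lb <- union(extra_lb, viol_lb)
    extra_ub <- union(extra_ub, viol_ub)
  }
  stop("LP active-set loop did not converge")
}
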