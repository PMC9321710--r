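#' Linear programming over flux spaces
#'
#' The constraint-based analyses (FBA, FVA, pFBA) are all linear programs of
#' the form: optimize c'x subject to A x = b and lb <= x <= ub. No LP solver
#' library is assumed; the package ships a dense two-phase primal simplex
#' for bounded variables. Problem sizes here (tens of reactions) are far
#' below anything that needs a production solver; correctness is checked in
#' the test suite against an independent vertex-enumeration oracle.
#'
#' @name lp_engine
NULL

#' Solve a bounded-variable linear program
#'
#' Maximizes (or minimizes) `obj' x` subject to `A x = b` and
#' `lb <= x <= ub`. Bounds may be infinite. Two-phase primal simplex with
#' Bland's rule engaged under prolonged degeneracy.
#'
#' @param obj Objective coefficient vector (length n).
#' @param A Constraint matrix (m x n), dense or sparse.
#' @param b Right-hand side (length m), default all zero.
#' @param lb,ub Variable bounds (length n); `-Inf`/`Inf` allowed.
#' @param maximize Logical; minimizes when `FALSE`.
#' @param tol Optimality/feasibility tolerance (default 1e-9).
#' @return List with `status` ("optimal", "infeasible" or "unbounded"),
#'   `x` (primal solution when optimal) and `objective`.
#' @export
solve_lp <- function(obj, A, b = NULL, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  if (is.null(b)) b <- numeric(m)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == m)
  obj <- as.numeric(obj); lb <- as.numeric(lb); ub <- as.numeric(ub)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  sgn <- if (maximize) 1 else -1

  # initial point: each nonbasic variable sits exactly on a finite bound
  # (the one of smaller magnitude); doubly-infinite variables are free at 0
  x0 <- numeric(n)
  st0 <- integer(n)  # 1 at lower, 2 at upper, 3 free at value
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && is.finite(ub[j])) {
      if (abs(lb[j]) <= abs(ub[j])) { x0[j] <- lb[j]; st0[j] <- 1L }
      else { x0[j] <- ub[j]; st0[j] <- 2L }
    } else if (is.finite(lb[j])) { x0[j] <- lb[j]; st0[j] <- 1L }
    else if (is.finite(ub[j])) { x0[j] <- ub[j]; st0[j] <- 2L }
    else { x0[j] <- 0; st0[j] <- 3L }
  }

  r <- as.numeric(b - A %*% x0)
  art_sign <- ifelse(r >= 0, 1, -1)
  Aa <- cbind(A, diag(m))
  lo <- c(lb, ifelse(art_sign > 0, 0, -Inf))
  hi <- c(ub, ifelse(art_sign > 0, Inf, 0))
  x <- c(x0, r)
  status <- c(st0, rep(0L, m))
  basis <- n + seq_len(m)
  c1 <- c(numeric(n), -art_sign)  # maximize -(sum |artificial|)

  ph1 <- simplex_core(Aa, c1, lo, hi, x, basis, status, tol)
  if (ph1$status != "optimal" || ph1$objective < -1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  # lock artificials at zero for phase II
  lo[n + seq_len(m)] <- 0
  hi[n + seq_len(m)] <- 0
  x <- ph1$x
  x[n + seq_len(m)][abs(x[n + seq_len(m)]) < 1e-7] <- 0
  c2 <- c(sgn * obj, numeric(m))
  ph2 <- simplex_core(Aa, c2, lo, hi, x, ph1$basis, ph1$status_vec, tol)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = sgn * Inf))
  }
  xs <- ph2$x[seq_len(n)]
  xs <- pmin(pmax(xs, lb), ub)  # clamp tiny bound violations
  list(status = "optimal", x = xs, objective = sum(obj * xs))
}

# Core bounded-variable primal simplex (maximization). `status` codes:
# 0 basic, 1 nonbasic at lower, 2 nonbasic at upper, 3 nonbasic free.
simplex_core <- function(A, cost, lo, hi, x, basis, status, tol) {
  m <- nrow(A); N <- ncol(A)
  pivtol <- 1e-10
  maxit <- 5000L + 200L * N
  degen <- 0L
  for (it in seq_len(maxit)) {
    B <- A[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cost[basis]),
                  error = function(e) NULL)
    if (is.null(y)) stop("singular basis in simplex", call. = FALSE)
    d <- cost - as.numeric(crossprod(A, y))
    d[basis] <- 0
    movable <- hi - lo > pivtol | status == 3L
    elig <- which(((status == 1L & d > tol) |
                   (status == 2L & d < -tol) |
                   (status == 3L & abs(d) > tol)) & movable)
    if (!length(elig)) {
      return(list(status = "optimal", x = x, basis = basis,
                  status_vec = status, objective = sum(cost * x)))
    }
    q <- if (degen > 50L) min(elig) else elig[which.max(abs(d[elig]))]
    s <- if (status[q] == 2L || (status[q] == 3L && d[q] < 0)) -1 else 1

    w <- solve(B, A[, q])
    rate <- -s * w  # d x_basic / d t

    t_own <- if (status[q] == 3L) Inf else hi[q] - lo[q]
    t_best <- t_own; leave <- 0L
    for (i in seq_len(m)) {
      bi <- basis[i]
      if (rate[i] > pivtol) {
        if (is.finite(hi[bi])) {
          lim <- (hi[bi] - x[bi]) / rate[i]
          if (lim < t_best - pivtol ||
              (lim < t_best + pivtol && (leave == 0L || bi < basis[leave]))) {
            t_best <- max(lim, 0); leave <- i
          }
        }
      } else if (rate[i] < -pivtol) {
        if (is.finite(lo[bi])) {
          lim <- (x[bi] - lo[bi]) / (-rate[i])
          if (lim < t_best - pivtol ||
              (lim < t_best + pivtol && (leave == 0L || bi < basis[leave]))) {
            t_best <- max(lim, 0); leave <- i
          }
        }
      }
    }
    if (!is.finite(t_best)) {
      return(list(status = "unbounded", x = x, basis = basis,
                  status_vec = status, objective = Inf))
    }
    degen <- if (t_best < tol) degen + 1L else 0L

    x[q] <- x[q] + s * t_best
    x[basis] <- x[basis] + rate * t_best
    if (leave == 0L) {
      # entering variable runs to its opposite bound; basis unchanged
      status[q] <- if (status[q] == 1L) 2L else 1L
      x[q] <- if (status[q] == 1L) lo[q] else hi[q]
    } else {
      out <- basis[leave]
      hit_upper <- rate[leave] > 0
      status[out] <- if (hit_upper) 2L else 1L
      x[out] <- if (hit_upper) hi[out] else lo[out]
      basis[leave] <- q
      status[q] <- 0L
    }
  }
  stop("simplex iteration limit exceeded", call. = FALSE)
}

model_lp_parts <- function(model) {
  list(A = as.matrix(model$S), b = numeric(length(model$metabolite_ids)),
       lb = unname(model$lb), ub = unname(model$ub), obj = unname(model$obj))
}

new_flux_state <- function(model, v, objective_value, status) {
  structure(list(v = stats::setNames(v, model$reaction_ids),
                 objective_value = objective_value, status = status),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("<flux_state> status=%s objective=%.6g (%d reactions)\n",
              x$status, x$objective_value, length(x$v)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the model's linear objective (c'v, usually biomass flux) over
#' the steady-state polytope `S v = 0`, `lb <= v <= ub`.
#'
#' @param model A `stoich_model` with a non-zero objective vector.
#' @return A `flux_state` with fields `v`, `objective_value` and `status`
#'   (`"optimal"`, `"infeasible"` or `"unbounded"`). At an optimum,
#'   `max |S v|` is below 1e-6.
#' @export
fba <- function(model) {
  validate_model(model)
  if (all(model$obj == 0)) {
    stop("degenerate model: all-zero objective vector", call. = FALSE)
  }
  p <- model_lp_parts(model)
  sol <- solve_lp(p$obj, p$A, p$b, p$lb, p$ub, maximize = TRUE)
  if (sol$status != "optimal") {
    return(new_flux_state(model, rep(NA_real_, length(p$obj)),
                          NA_real_, sol$status))
  }
  new_flux_state(model, sol$x, sol$objective, "optimal")
}

# Extend the LP with the objective-floor constraint c'v >= fraction * opt,
# encoded as the equality c'v - z = 0 with slack z in [fraction*opt, Inf).
lp_with_objective_floor <- function(p, floor_value) {
  m <- nrow(p$A); n <- ncol(p$A)
  A2 <- rbind(cbind(p$A, numeric(m)), c(p$obj, -1))
  list(A = A2, b = c(p$b, 0),
       lb = c(p$lb, floor_value), ub = c(p$ub, Inf))
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' model objective stays at or above `fraction_of_optimum` times its FBA
#' optimum: 2n LP solves.
#'
#' @param model A `stoich_model`.
#' @param fraction_of_optimum Scalar in (0, 1]; default 1.
#' @param reactions Reactions to analyse (default: all).
#' @return A data frame (`flux_range`) with columns `reaction`, `min`,
#'   `max`; attribute `fraction_of_optimum`.
#' @export
fva <- function(model, fraction_of_optimum = 1.0, reactions = NULL) {
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  base <- fba(model)
  if (base$status != "optimal") {
    stop(sprintf("FVA requires an optimal base model (FBA status: %s)",
                 base$status), call. = FALSE)
  }
  if (is.null(reactions)) reactions <- model$reaction_ids
  stopifnot(all(reactions %in% model$reaction_ids))
  p <- model_lp_parts(model)
  ext <- lp_with_objective_floor(p, fraction_of_optimum * base$objective_value)
  n <- ncol(p$A)
  vmin <- vmax <- numeric(length(reactions))
  for (k in seq_along(reactions)) {
    j <- match(reactions[k], model$reaction_ids)
    e <- numeric(n + 1L); e[j] <- 1
    lo <- solve_lp(e, ext$A, ext$b, ext$lb, ext$ub, maximize = FALSE)
    hi <- solve_lp(e, ext$A, ext$b, ext$lb, ext$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop(sprintf("FVA subproblem not optimal for reaction '%s'",
                   reactions[k]), call. = FALSE)
    }
    vmin[k] <- lo$objective; vmax[k] <- hi$objective
  }
  swap <- vmin > vmax
  if (any(swap)) {  # numerical guard only
    tmp <- vmin[swap]; vmin[swap] <- vmax[swap]; vmax[swap] <- tmp
  }
  structure(data.frame(reaction = reactions, min = vmin, max = vmax,
                       stringsAsFactors = FALSE),
            fraction_of_optimum = fraction_of_optimum,
            class = c("flux_range", "data.frame"))
}

#' Parsimonious FBA
#'
#' Fixes the objective at its FBA optimum (optionally with a relative
#' slack), then minimizes the total absolute flux `sum |v_i|` through the
#' standard split-variable reformulation `v = p - q`, `p, q >= 0`. Removes
#' flux through futile cycles and other degenerate optima that carry no
#' biological meaning.
#'
#' @param model A `stoich_model`.
#' @param relative_slack Allowed relative shortfall of the objective below
#'   the FBA optimum; 0 (default) pins it exactly.
#' @return A `flux_state`; attribute `total_flux` holds `sum |v|`.
#' @export
pfba <- function(model, relative_slack = 0) {
  stopifnot(relative_slack >= 0, relative_slack < 1)
  base <- fba(model)
  if (base$status != "optimal") {
    return(new_flux_state(model, rep(NA_real_, length(model$reaction_ids)),
                          NA_real_, base$status))
  }
  p <- model_lp_parts(model)
  m <- nrow(p$A); n <- ncol(p$A)
  # variables [p; q], v = p - q
  A2 <- cbind(p$A, -p$A)
  lbp <- pmax(p$lb, 0); ubp <- pmax(p$ub, 0)
  lbq <- pmax(-p$ub, 0); ubq <- pmax(-p$lb, 0)
  opt <- base$objective_value
  if (relative_slack == 0) {
    A3 <- rbind(A2, c(p$obj, -p$obj))
    b3 <- c(p$b, opt)
    lb3 <- c(lbp, lbq); ub3 <- c(ubp, ubq)
  } else {
    floorv <- opt - relative_slack * abs(opt)
    A3 <- rbind(cbind(A2, numeric(m)), c(p$obj, -p$obj, -1))
    b3 <- c(p$b, 0)
    lb3 <- c(lbp, lbq, floorv); ub3 <- c(ubp, ubq, Inf)
  }
  cost <- c(rep(1, 2L * n), numeric(ncol(A3) - 2L * n))
  sol <- solve_lp(cost, A3, b3, lb3, ub3, maximize = FALSE)
  if (sol$status != "optimal") {
    return(new_flux_state(model, rep(NA_real_, n), NA_real_, sol$status))
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  fs <- new_flux_state(model, v, sum(p$obj * v), "optimal")
  attr(fs, "total_flux") <- sum(abs(v))
  fs
}
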