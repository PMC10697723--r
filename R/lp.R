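## Dense bounded-variable two-phase primal simplex.
##
## Solves    maximize  c'x
##           subject to A x = b,  lb <= x <= ub
##
## Written for the flux-balance problems in this package (tens of variables,
## tens of equality rows, mostly finite bounds). No sparse machinery; the
## basis matrix is re-factorised at every iteration, which at this scale is
## cheaper than maintaining an LU update and avoids drift.

#' Solve a bounded linear program
#'
#' Maximizes \code{t(c) %*% x} subject to \code{A x = b} and \code{lb <= x <= ub}
#' with a two-phase primal simplex supporting general (possibly negative or
#' infinite) variable bounds. Dantzig pricing with an automatic switch to
#' Bland's rule guards against cycling on degenerate vertices.
#'
#' @param c objective coefficients (length n).
#' @param A dense constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds (length n; \code{-Inf}/\code{Inf} allowed).
#' @param maximize if \code{FALSE}, minimizes instead.
#' @param tol pivot/optimality tolerance.
#' @param feas_tol feasibility tolerance on the phase-1 objective.
#' @param maxit iteration cap across both phases.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded" or
#'   "maxit"), \code{objective}, \code{x} (length n, NA unless optimal) and
#'   \code{iterations}.
#' @examples
#' # max x1 + x2 s.t. x1 + x2 <= 1 written with a slack: x1 + x2 + s = 1
#' lp_solve(c(1, 1, 0), matrix(c(1, 1, 1), 1), 1,
#'          lb = c(0, 0, 0), ub = c(Inf, Inf, Inf))$objective
#' @export
lp_solve <- function(c, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, feas_tol = 1e-7, maxit = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(c) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), iterations = 0L))
  obj <- if (maximize) as.numeric(c) else -as.numeric(c)
  lb <- as.numeric(lb); ub <- as.numeric(ub)

  ## scale rows of A to unit max-norm for pivot stability
  rs <- apply(abs(A), 1, max); rs[rs == 0] <- 1
  A <- A / rs; b <- as.numeric(b) / rs

  ## start structural variables at the finite bound nearest zero
  x0 <- numeric(n)
  fl <- is.finite(lb); fu <- is.finite(ub)
  x0[fl & fu] <- ifelse(abs(lb[fl & fu]) <= abs(ub[fl & fu]),
                        lb[fl & fu], ub[fl & fu])
  x0[fl & !fu] <- lb[fl & !fu]
  x0[!fl & fu] <- ub[!fl & fu]
  r <- b - as.vector(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)

  ## augment with one artificial per row
  Afull <- cbind(A, diag(sgn, m))
  N <- n + m
  LB <- c(lb, rep(0, m))
  UB <- c(ub, rep(Inf, m))
  xval <- c(x0, abs(r))          # current value of every variable
  basis <- (n + 1L):N            # artificials basic
  at_upper <- logical(N)
  at_upper[seq_len(n)] <- fu & x0 == ub & !(fl & x0 == lb)
  frozen_all <- LB >= UB - 1e-30

  phase <- 1L
  cost <- c(rep(0, n), rep(-1, m))   # maximize -sum(artificials)
  it <- 0L; bland <- FALSE; stall <- 0L; last_obj <- -Inf
  refresh <- 0L

  repeat {
    it <- it + 1L
    if (it > maxit)
      return(list(status = "maxit", objective = NA_real_,
                  x = rep(NA_real_, n), iterations = it))

    B <- Afull[, basis, drop = FALSE]
    Binv <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv))
      return(list(status = "maxit", objective = NA_real_,
                  x = rep(NA_real_, n), iterations = it))
    refresh <- refresh + 1L
    if (refresh >= 40L || refresh == 1L) {
      ## periodic refresh of the basic values against accumulated drift
      nonb <- setdiff(seq_len(N), basis)
      xval[basis] <- Binv %*% (b - Afull[, nonb, drop = FALSE] %*% xval[nonb])
      if (refresh >= 40L) refresh <- 2L
    }

    y <- as.vector(crossprod(Binv, cost[basis]))
    nonbasic <- setdiff(seq_len(N), basis)
    d <- cost[nonbasic] - as.vector(y %*% Afull[, nonbasic, drop = FALSE])

    up_ok <- d > tol & !at_upper[nonbasic]
    dn_ok <- d < -tol & (at_upper[nonbasic] |
                           (!is.finite(LB[nonbasic]) & !is.finite(UB[nonbasic])))
    elig <- which((up_ok | dn_ok) & !frozen_all[nonbasic])

    cur_obj <- sum(cost[basis] * xval[basis]) +
      sum(cost[nonbasic] * xval[nonbasic])
    if (cur_obj <= last_obj + 1e-12) stall <- stall + 1L else stall <- 0L
    last_obj <- cur_obj
    if (stall > 2L * N) bland <- TRUE

    if (!length(elig)) {
      if (phase == 1L) {
        if (-cur_obj > feas_tol)
          return(list(status = "infeasible", objective = NA_real_,
                      x = rep(NA_real_, n), iterations = it))
        UB[(n + 1L):N] <- 0
        frozen_all[(n + 1L):N] <- TRUE
        xval[(n + 1L):N][xval[(n + 1L):N] < 0] <- 0
        cost <- c(obj, rep(0, m))
        phase <- 2L; bland <- FALSE; stall <- 0L; last_obj <- -Inf
        refresh <- 0L
        next
      }
      ## final refresh of basic values for a clean residual
      nonb <- setdiff(seq_len(N), basis)
      xval[basis] <- Binv %*% (b - Afull[, nonb, drop = FALSE] %*% xval[nonb])
      xs <- xval[seq_len(n)]
      val <- sum(obj * xs)
      return(list(status = "optimal",
                  objective = if (maximize) val else -val,
                  x = xs, iterations = it))
    }

    j_rel <- if (bland) elig[which.min(nonbasic[elig])] else
      elig[which.max(abs(d[elig]))]
    jj <- nonbasic[j_rel]
    s <- if (up_ok[j_rel]) 1 else -1          # direction of movement of x_jj

    w <- as.vector(Binv %*% Afull[, jj])      # xB changes by -s*t*w
    sw <- s * w
    ## vectorized ratio test
    xB <- xval[basis]
    tk <- rep(Inf, m)
    dec <- sw > tol & is.finite(LB[basis])
    inc <- sw < -tol & is.finite(UB[basis])
    tk[dec] <- (xB[dec] - LB[basis][dec]) / sw[dec]
    tk[inc] <- (xB[inc] - UB[basis][inc]) / sw[inc]
    leave <- if (any(is.finite(tk))) which.min(tk) else 0L
    tmax <- if (leave > 0L) tk[leave] else Inf
    t_own <- if (s > 0) UB[jj] - xval[jj] else xval[jj] - LB[jj]
    if (is.finite(t_own) && t_own < tmax - 1e-15) { tmax <- t_own; leave <- -1L }

    if (!is.finite(tmax)) {
      if (phase == 1L)
        return(list(status = "maxit", objective = NA_real_,
                    x = rep(NA_real_, n), iterations = it))
      return(list(status = "unbounded",
                  objective = if (maximize) Inf else -Inf,
                  x = rep(NA_real_, n), iterations = it))
    }
    tmax <- max(tmax, 0)

    xval[jj] <- xval[jj] + s * tmax
    xval[basis] <- xval[basis] - sw * tmax
    if (leave == -1L) {
      at_upper[jj] <- s > 0                   # bound flip, basis unchanged
    } else {
      lv <- basis[leave]
      to_lower <- sw[leave] > 0
      xval[lv] <- if (to_lower) LB[lv] else UB[lv]
      at_upper[lv] <- !to_lower
      basis[leave] <- jj
      at_upper[jj] <- FALSE
    }
  }
}

#' Brute-force LP optimum by vertex enumeration
#'
#' Independent reference for [lp_solve()] on small problems: enumerates every
#' basic solution of \code{A x = b, lb <= x <= ub} (all choices of
#' \code{rank(A)} basic columns with the remaining variables fixed at either
#' bound), keeps the feasible ones and returns the best objective. All bounds
#' must be finite. Cost grows combinatorially; intended for problems with at
#' most ~10 variables.
#'
#' @inheritParams lp_solve
#' @param tol feasibility tolerance for enumerated vertices.
#' @return list with \code{objective} (NA if infeasible) and \code{x}.
#' @export
lp_enumerate <- function(c, A, b, lb, ub, maximize = TRUE, tol = 1e-8) {
  A <- as.matrix(A); m <- nrow(A); n <- ncol(A)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  qrA <- qr(A)
  r <- qrA$rank
  if (r == 0L) {                      # no effective constraints: box optimum
    if (max(abs(b)) > tol) return(list(objective = NA_real_, x = rep(NA_real_, n)))
    x <- ifelse((maximize & c > 0) | (!maximize & c < 0), ub, lb)
    return(list(objective = sum(c * x), x = x))
  }
  ## use r independent rows
  rows <- qr(t(A))$pivot[seq_len(r)]
  Ar <- A[rows, , drop = FALSE]; br <- b[rows]
  best <- NULL; best_val <- if (maximize) -Inf else Inf
  basis_sets <- utils::combn(n, r, simplify = FALSE)
  nb_n <- n - r
  bound_grid <- if (nb_n > 0)
    as.matrix(expand.grid(rep(list(c(0, 1)), nb_n))) else matrix(0, 1, 0)
  for (Bset in basis_sets) {
    Bm <- Ar[, Bset, drop = FALSE]
    if (abs(det(Bm)) < 1e-12) next
    Nset <- setdiff(seq_len(n), Bset)
    for (g in seq_len(nrow(bound_grid))) {
      xN <- ifelse(bound_grid[g, ] > 0, ub[Nset], lb[Nset])
      rhs <- br - if (nb_n > 0) as.vector(Ar[, Nset, drop = FALSE] %*% xN) else 0
      xB <- solve(Bm, rhs)
      x <- numeric(n); x[Bset] <- xB
      if (nb_n > 0) x[Nset] <- xN
      if (any(x < lb - tol) || any(x > ub + tol)) next
      if (max(abs(A %*% x - b)) > 1e-7) next
      val <- sum(c * x)
      if ((maximize && val > best_val) || (!maximize && val < best_val)) {
        best_val <- val; best <- x
      }
    }
  }
  if (is.null(best)) list(objective = NA_real_, x = rep(NA_real_, n))
  else list(objective = best_val, x = best)
}
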