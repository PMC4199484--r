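#' Built-in linear programming solver
#'
#' A dense two-phase primal simplex for the small LPs arising from
#' toy-scale flux balance analysis and gap filling:
#'
#' \deqn{\min / \max\; c^T x \quad s.t.\; A x = b,\; lb \le x \le ub}
#'
#' Variables are shifted to be non-negative and finite upper bounds are
#' carried as explicit slack rows, giving the standard form solved by a
#' tableau simplex (Dantzig pricing with a Bland's-rule fallback for
#' anti-cycling).  All bounds must be finite -- metabolic models in this
#' package always have finite flux bounds -- so unboundedness cannot
#' occur by construction and is reported as an error if detected.
#'
#' This exists because no LP solver package is assumed available at run
#' time; it is validated in the test suite against hand-solved LPs and
#' an external reference solver on random instances.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n) of equality rows.
#' @param b right-hand side (length m).
#' @param lb,ub finite variable bounds.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol feasibility/pivot tolerance.
#' @return list with `status` (`"optimal"` or `"infeasible"`),
#'   `objective`, and `x` (primal solution, length n).
#' @export
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  stopifnot(ncol(A) == n, length(b) == nrow(A), length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite bounds")
  if (any(lb > ub + tol))
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  # shift: y = x - lb in [0, u]
  u <- ub - lb
  b2 <- b - as.vector(A %*% lb)
  m1 <- nrow(A)
  ub_rows <- which(u > tol)         # variables with room need a cap row
  fixed <- which(u <= tol)          # fixed variables: y = 0
  m2 <- length(ub_rows)
  # columns: n structural + m2 slacks + artificials (added per row below)
  Aall <- cbind(A, matrix(0, m1, m2))
  if (m2) {
    cap <- matrix(0, m2, n + m2)
    cap[cbind(seq_len(m2), ub_rows)] <- 1
    cap[cbind(seq_len(m2), n + seq_len(m2))] <- 1
    Aall <- rbind(Aall, cap)
  }
  rhs <- c(b2, u[ub_rows])
  m <- m1 + m2
  neg <- rhs < 0
  Aall[neg, ] <- -Aall[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]
  # basis: slack if its coefficient is +1 and row rhs >= 0, else artificial
  basis <- integer(m)
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    sl <- if (i > m1) n + (i - m1) else 0L
    if (sl > 0L && Aall[i, sl] > 0.5) {
      basis[i] <- sl
    } else {
      Aall <- cbind(Aall, 0)
      Aall[i, ncol(Aall)] <- 1
      basis[i] <- ncol(Aall)
      art_cols <- c(art_cols, ncol(Aall))
    }
  }
  ncols <- ncol(Aall)
  T <- cbind(Aall, rhs)
  # --- phase 1: minimize sum of artificials ---
  if (length(art_cols)) {
    crow <- numeric(ncols + 1)
    crow[art_cols] <- 1
    # reduce cost row against initial basis (artificials are basic)
    for (i in which(basis %in% art_cols)) crow <- crow - T[i, ]
    res <- simplex_iterate(T, crow, basis, banned = fixed, tol = tol)
    T <- res$T; basis <- res$basis; crow <- res$crow
    if (-crow[ncols + 1] > 1e-7)
      return(list(status = "infeasible", objective = NA_real_,
                  x = rep(NA_real_, n)))
    # drive artificials out of the basis (they are at value ~0)
    for (i in which(basis %in% art_cols)) {
      piv <- which(abs(T[i, seq_len(n + m2)]) > tol &
                     !(seq_len(n + m2) %in% c(basis, fixed)))
      if (length(piv)) {
        j <- piv[1]
        T[i, ] <- T[i, ] / T[i, j]
        for (r in seq_len(nrow(T))) if (r != i && abs(T[r, j]) > 0)
          T[r, ] <- T[r, ] - T[r, j] * T[i, ]
        basis[i] <- j
      }                       # else: redundant row; artificial stays at 0
    }
  }
  # --- phase 2 ---
  cvec <- c(if (maximize) -(obj) else obj)   # minimize internal objective
  crow <- numeric(ncols + 1)
  crow[seq_len(n)] <- cvec
  for (i in seq_len(m)) if (abs(crow[basis[i]]) > 0)
    crow <- crow - crow[basis[i]] * T[i, ]
  banned <- c(art_cols, fixed)
  res <- simplex_iterate(T, crow, basis, banned = banned, tol = tol)
  T <- res$T; basis <- res$basis
  if (res$unbounded)
    stop("solve_lp: unbounded objective (check flux bounds)")
  y <- numeric(ncols)
  y[basis] <- T[, ncols + 1]
  x <- y[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * x), x = x)
}

# tableau pivoting loop; returns updated tableau, basis and cost row.
# Dantzig pricing, switching to Bland's rule after a burn-in to guarantee
# termination on degenerate problems.
simplex_iterate <- function(T, crow, basis, banned, tol) {
  m <- nrow(T); ncols <- ncol(T) - 1L
  eligible <- setdiff(seq_len(ncols), banned)
  maxit <- 200L + 40L * (m + ncols)
  bland_after <- 20L + 4L * (m + ncols)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) stop("simplex: iteration limit exceeded")
    red <- crow[eligible]
    cand <- eligible[red < -tol]
    if (!length(cand)) return(list(T = T, basis = basis, crow = crow,
                                   unbounded = FALSE))
    j <- if (it <= bland_after) cand[which.min(crow[cand])] else min(cand)
    col <- T[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(T = T, basis = basis, crow = crow,
                                  unbounded = TRUE))
    ratios <- T[pos, ncols + 1L] / col[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + tol]
    i <- ties[which.min(basis[ties])]      # deterministic tie-break
    T[i, ] <- T[i, ] / T[i, j]
    piv <- T[i, ]
    upd <- which(abs(T[, j]) > 0)
    upd <- upd[upd != i]
    if (length(upd)) T[upd, ] <- T[upd, ] - outer(T[upd, j], piv)
    crow <- crow - crow[j] * piv
    basis[i] <- j
  }
}

# convenience: feasibility of Ax = b, lb <= x <= ub
lp_feasible <- function(A, b, lb, ub, tol = 1e-9) {
  res <- solve_lp(numeric(ncol(A)), A, b, lb, ub, maximize = FALSE, tol = tol)
  res$status == "optimal"
}
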