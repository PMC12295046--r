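# Internal linear and mixed-integer programming layer.
#
# All constraint-based stages (FBA, GrowMatch, OptKnock) reduce to LPs or
# MILPs over bounded variables:
#
#   max / min  c'x   s.t.  A x {<=,=,>=} b,   lb <= x <= ub
#
# lp_solve() translates to standard form (variables shifted by their lower
# bounds, finite upper bounds as rows, fixed variables eliminated) and hands
# the result to simplex_core(), a dense two-phase primal simplex. Pivoting
# uses the Dantzig rule with an automatic switch to Bland's rule when the
# objective stalls, which guarantees termination on the degenerate LPs that
# FBA produces (every mass-balance right-hand side is zero). MILPs are
# solved by depth-first branch-and-bound on binary variables with
# LP-relaxation bound pruning (milp_solve). Problem sizes in this package
# are small (toy networks, <= 25 reactions, <= 8 binaries), for which a
# dense tableau simplex is entirely adequate.

# Two-phase primal simplex for:  min c'z  s.t.  A z {<=,=,>=} b,  z >= 0.
# Returns list(status = "optimal"|"infeasible"|"unbounded", objective, z).
simplex_core <- function(obj, A, dir, rhs, tol = 1e-9, max_iter = NULL) {
  m <- nrow(A); n <- ncol(A)
  # normalize rhs >= 0
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- vapply(dir[neg], function(d)
      switch(d, "<=" = ">=", ">=" = "<=", "=" = "="), character(1))
  }
  # append slack (+1) / surplus (-1) columns for inequalities
  n_ineq <- sum(dir != "=")
  A_std <- cbind(A, matrix(0, m, n_ineq))
  k <- n
  for (i in which(dir != "=")) {
    k <- k + 1L
    A_std[i, k] <- if (dir[i] == "<=") 1 else -1
  }
  n_std <- n + n_ineq
  n_tot <- n_std + m  # plus one artificial per row
  Tb <- cbind(A_std, diag(m), rhs)
  basis <- n_std + seq_len(m)
  if (is.null(max_iter)) max_iter <- 2000L + 60L * (n_tot + m)

  # One simplex phase on tableau `Tb` (m x (n_tot + 1)) with basis `basis`,
  # minimizing `cost` over columns `active`. Dantzig entering rule, switching
  # to Bland's rule after the objective stalls; Bland tie-break on leaving.
  piv_tol <- 1e-7
  phase <- function(cost, active, bland_from_start = FALSE) {
    # Numerical safeguards learned the hard way on degenerate FBA tableaus:
    # reduced costs are recomputed from the tableau every iteration (the
    # incremental update drifts over long degenerate runs), the pivot element
    # must exceed piv_tol, and among ratio-test ties the largest pivot
    # element is taken (smallest basis index, i.e. Bland, once the objective
    # stalls, which guarantees termination).
    stall <- if (bland_from_start) .Machine$integer.max %/% 2L else 0L
    best_obj <- Inf
    for (it in seq_len(max_iter)) {
      cb <- cost[basis]
      nzb <- which(cb != 0)
      red <- cost[seq_len(n_tot)]
      if (length(nzb)) {
        red <- red - drop(cb[nzb] %*% Tb[nzb, seq_len(n_tot), drop = FALSE])
      }
      objv <- sum(cb * Tb[, n_tot + 1L])
      cand <- active[red[active] < -tol]
      if (!length(cand)) return(list(status = "optimal", objective = objv))
      blandish <- stall > 2L * (m + 5L)
      pc <- if (blandish) min(cand) else cand[which.min(red[cand])]
      col <- Tb[, pc]
      pos <- which(col > piv_tol)
      if (!length(pos)) return(list(status = "unbounded", objective = NA_real_))
      ratios <- Tb[pos, n_tot + 1L] / col[pos]
      rmin <- min(ratios)
      ties <- which(ratios <= rmin + tol)
      pr <- if (blandish) pos[ties][which.min(basis[pos[ties]])]
            else pos[ties][which.max(col[pos[ties]])]
      piv_row <- Tb[pr, ] / Tb[pr, pc]
      Tb <<- Tb - outer(col, piv_row)
      Tb[pr, ] <<- piv_row
      basis[pr] <<- pc
      if (objv < best_obj - tol) {
        stall <- 0L; best_obj <- objv
      } else if (!bland_from_start) {
        stall <- stall + 1L
      }
    }
    list(status = "maxiter", objective = NA_real_)
  }

  # phase 1: minimize the sum of artificials
  Tb0 <- Tb; basis0 <- basis
  ph1 <- phase(c(rep(0, n_std), rep(1, m)), seq_len(n_tot))
  if (ph1$status == "optimal" && ph1$objective > 1e-7 && ph1$objective < 1e-2) {
    # ambiguous near-zero residual: retry on a fresh tableau with Bland's
    # rule throughout before declaring infeasibility
    Tb <- Tb0; basis <- basis0
    ph1 <- phase(c(rep(0, n_std), rep(1, m)), seq_len(n_tot),
                 bland_from_start = TRUE)
  }
  if (ph1$status != "optimal") {
    return(list(status = "error", objective = NA_real_, z = NULL))
  }
  if (ph1$objective > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, z = NULL))
  }
  # drive remaining zero-valued artificials out of the basis
  drop_rows <- integer(0)
  for (i in which(basis > n_std)) {
    row <- Tb[i, seq_len(n_std)]
    j <- which(abs(row) > 1e-8)
    if (length(j)) {
      pc <- j[1L]
      piv_row <- Tb[i, ] / Tb[i, pc]
      Tb <- Tb - outer(Tb[, pc], piv_row)
      Tb[i, ] <- piv_row
      basis[i] <- pc
    } else {
      drop_rows <- c(drop_rows, i)  # redundant constraint
    }
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(m), drop_rows)
    Tb <- Tb[keep, , drop = FALSE]
    basis <- basis[keep]
    m <- length(keep)
  }

  # phase 2: original objective; artificial columns may not re-enter
  ph2 <- phase(c(obj, rep(0, n_tot - n)), seq_len(n_std))
  if (ph2$status != "optimal") {
    return(list(status = if (ph2$status == "unbounded") "unbounded" else "error",
                objective = NA_real_, z = NULL))
  }
  z <- numeric(n_tot)
  z[basis] <- Tb[, n_tot + 1L]
  list(status = "optimal", objective = ph2$objective, z = z[seq_len(n)])
}

# Solve a bounded-variable LP. Returns list(status, objective, x).
# status: "optimal", "infeasible", or "error" (simplex failed to converge).
# All bounds must be finite.
lp_solve <- function(obj, A, dir, rhs, lb, ub, maximize = TRUE,
                     n_iter = NULL) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n,
            is.null(A) || ncol(A) == n, all(is.finite(lb)), all(is.finite(ub)))
  if (any(ub < lb - 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  if (is.null(A)) {
    A <- matrix(0, 0, n)
    dir <- character(0)
    rhs <- numeric(0)
  }
  A <- as.matrix(A)

  # Eliminate fixed variables (common after knockouts set bounds to 0, 0).
  fixed <- (ub - lb) < 1e-12
  x_out <- rep(NA_real_, n)
  x_out[fixed] <- lb[fixed]
  const_obj <- sum(obj[fixed] * lb[fixed])
  if (all(fixed)) {
    resid <- if (nrow(A)) drop(A %*% lb) else numeric(0)
    ok <- all(vapply(seq_along(dir), function(i) {
      switch(dir[i],
             "<=" = resid[i] <= rhs[i] + 1e-7,
             ">=" = resid[i] >= rhs[i] - 1e-7,
             "="  = abs(resid[i] - rhs[i]) <= 1e-7)
    }, logical(1)))
    if (!ok) return(list(status = "infeasible", objective = NA_real_, x = x_out))
    return(list(status = "optimal", objective = const_obj, x = x_out))
  }
  free <- which(!fixed)
  if (any(fixed) && nrow(A)) {
    rhs <- rhs - drop(A[, fixed, drop = FALSE] %*% lb[fixed])
    A <- A[, free, drop = FALSE]
  } else if (any(fixed)) {
    A <- A[, free, drop = FALSE]
  }
  objf <- obj[free]; lbf <- lb[free]; ubf <- ub[free]

  # Shift: x = lb + z, z >= 0.
  if (nrow(A)) rhs <- rhs - drop(A %*% lbf)
  const_obj <- const_obj + sum(objf * lbf)

  # Finite upper bounds as <= rows (skip where slack is huge but finite: they
  # are still rows; problems here are small enough not to care).
  span <- ubf - lbf
  Aub <- diag(length(objf))
  A_all <- rbind(A, Aub)
  dir_all <- c(dir, rep("<=", length(objf)))
  rhs_all <- c(rhs, span)

  res <- simplex_core(if (maximize) -objf else objf, A_all, dir_all, rhs_all,
                      max_iter = n_iter)
  if (res$status == "infeasible") {
    return(list(status = "infeasible", objective = NA_real_, x = x_out))
  }
  if (res$status != "optimal") {
    return(list(status = "error", objective = NA_real_, x = x_out,
                message = paste("simplex:", res$status)))
  }
  z <- res$z
  x_out[free] <- lbf + z
  list(status = "optimal", objective = const_obj + sum(objf * z), x = x_out)
}

# Branch-and-bound MILP over binary variables `binary_idx`.
# Returns list(status, objective, x). Depth-first, most-fractional branching,
# LP-relaxation bound pruning against the incumbent.
milp_solve <- function(obj, A, dir, rhs, lb, ub, binary_idx,
                       maximize = TRUE, int_tol = 1e-6, gap_tol = 1e-7,
                       verbose = FALSE) {
  sense <- if (maximize) 1 else -1
  best <- list(objective = -sense * Inf, x = NULL)  # worst value in sense scale
  n_nodes <- 0L

  recurse <- function(lb, ub) {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > 100000L) stop("branch-and-bound node limit exceeded")
    rel <- lp_solve(obj, A, dir, rhs, lb, ub, maximize = maximize)
    if (verbose) {
      cat("node", n_nodes, "fix:",
          paste0(ifelse(lb[binary_idx] == ub[binary_idx], lb[binary_idx], "."),
                 collapse = ""),
          "status:", rel$status, "bound:", rel$objective,
          "incumbent:", sense * best$objective, "\n")
    }
    if (rel$status == "infeasible") return(invisible(NULL))
    if (rel$status != "optimal") stop("LP relaxation failed: ",
                                      rel$message %||% rel$status)
    if (sense * rel$objective <= sense * best$objective + gap_tol &&
        !is.null(best$x)) {
      return(invisible(NULL))  # bound cannot beat incumbent
    }
    frac <- abs(rel$x[binary_idx] - round(rel$x[binary_idx]))
    if (!length(binary_idx) || all(frac <= int_tol)) {
      xi <- rel$x
      xi[binary_idx] <- round(xi[binary_idx])
      if (sense * rel$objective > sense * best$objective) {
        best <<- list(objective = rel$objective, x = xi)
      }
      return(invisible(NULL))
    }
    j <- binary_idx[which.max(frac)]
    first <- if (rel$x[j] >= 0.5) 1 else 0
    for (val in c(first, 1 - first)) {
      lb2 <- lb; ub2 <- ub
      lb2[j] <- val; ub2[j] <- val
      recurse(lb2, ub2)
    }
    invisible(NULL)
  }

  recurse(lb, ub)
  if (is.null(best$x)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, length(obj))))
  }
  list(status = "optimal", objective = best$objective, x = best$x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small helper used by MILP builders: accumulate sparse triplets then emit a
# dense constraint matrix (problems are small; dense is what the LP layer
# wants anyway).
constraint_builder <- function(n_vars) {
  rows <- list(); dirs <- character(0); rhss <- numeric(0)
  add <- function(idx, val, dir, rhs) {
    r <- numeric(n_vars)
    r[idx] <- val
    rows[[length(rows) + 1L]] <<- r
    dirs[length(dirs) + 1L] <<- dir
    rhss[length(rhss) + 1L] <<- rhs
  }
  emit <- function() {
    list(A = do.call(rbind, rows), dir = dirs, rhs = rhss)
  }
  list(add = add, emit = emit)
}
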