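#' Minimum-norm static muscle redundancy
#'
#' Solves the static muscle redundancy problem at one instant: find
#' activations minimizing `sum(a^2)` subject to the joint moment balance
#' `G %*% a = moment` and box bounds `0 <= a <= 1`, where `G[j, i]` is the
#' moment-generating gain of muscle `i` at degree of freedom `j`
#' (moment arm times maximal achievable muscle force at the current state).
#' Solved with an active-set method on the KKT conditions; in the interior
#' case this reduces to the closed-form Lagrange solution
#' `a = t(G) %*% solve(G %*% t(G), moment)`.
#'
#' @param G Gains matrix, dofs x muscles (N*m per unit activation).
#' @param moment Moment demand per dof, N*m.
#' @param tol Feasibility/optimality tolerance.
#' @param max_iter Active-set iteration cap.
#' @return List with `activation`, `moment_residual`, `objective`,
#'   `iterations`, `converged`.
#' @export
solve_static_redundancy <- function(G, moment, tol = 1e-10, max_iter = 100) {
  G <- rbind(G)
  d <- nrow(G); m <- ncol(G)
  stopifnot(length(moment) == d)
  at_lo <- rep(FALSE, m); at_hi <- rep(FALSE, m)
  a <- rep(0, m)
  solve_free <- function(free, fixed_hi) {
    rhs <- moment - if (any(fixed_hi)) rowSums(G[, fixed_hi, drop = FALSE]) else 0
    Gf <- G[, free, drop = FALSE]
    M <- Gf %*% t(Gf)
    # KKT: 2 a = t(G) lambda on free variables, G a = rhs; a rank-deficient
    # free block (fewer free muscles than dofs, collinear rows) falls back
    # to the SVD pseudo-inverse, i.e. the least-squares multiplier
    lambda <- tryCatch(2 * solve(M, rhs), error = function(e) {
      sv <- svd(M)
      keep <- sv$d > max(sv$d[1], 1e-12) * 1e-10
      2 * sv$v[, keep, drop = FALSE] %*%
        ((t(sv$u[, keep, drop = FALSE]) %*% rhs) / sv$d[keep])
    })
    list(a = as.numeric(t(Gf) %*% lambda) / 2, lambda = as.numeric(lambda))
  }
  lambda <- rep(0, d)
  for (it in seq_len(max_iter)) {
    free <- !(at_lo | at_hi)
    if (!any(free)) {
      a[at_lo] <- 0; a[at_hi] <- 1
      lambda <- rep(0, d)
    } else {
      sol <- solve_free(free, at_hi)
      a[free] <- sol$a; a[at_lo] <- 0; a[at_hi] <- 1
      lambda <- sol$lambda
    }
    # primal violations among free variables
    viol_lo <- which(free & a < -tol)
    viol_hi <- which(free & a > 1 + tol)
    if (length(viol_lo) + length(viol_hi) > 0) {
      if (length(viol_lo) > 0) {
        i <- viol_lo[which.min(a[viol_lo])]
        at_lo[i] <- TRUE
      } else {
        i <- viol_hi[which.max(a[viol_hi])]
        at_hi[i] <- TRUE
      }
      next
    }
    # dual feasibility: gradient 2 a_i - g_i' lambda; at lower bound need >= 0,
    # at upper bound need <= 0
    grad <- 2 * a - as.numeric(t(G) %*% lambda)
    rel_lo <- which(at_lo & grad < -tol)
    rel_hi <- which(at_hi & grad > tol)
    if (length(rel_lo) + length(rel_hi) > 0) {
      if (length(rel_lo) > 0) {
        i <- rel_lo[which.min(grad[rel_lo])]
        at_lo[i] <- FALSE
      } else {
        i <- rel_hi[which.max(grad[rel_hi])]
        at_hi[i] <- FALSE
      }
      next
    }
    res <- as.numeric(moment - G %*% a)
    feas <- max(abs(res)) < tol * max(1, max(abs(moment)))
    if (!feas) {
      # equality constraints unmet (rank-deficient free block): release the
      # bound variable that can reduce the residual, if any
      gain <- as.numeric(t(G) %*% res)
      cand_lo <- which(at_lo & gain > tol)
      cand_hi <- which(at_hi & gain < -tol)
      if (length(cand_lo) + length(cand_hi) > 0) {
        if (length(cand_lo) > 0 &&
            (length(cand_hi) == 0 || max(gain[cand_lo]) >= max(-gain[cand_hi]))) {
          at_lo[cand_lo[which.max(gain[cand_lo])]] <- FALSE
        } else {
          at_hi[cand_hi[which.max(-gain[cand_hi])]] <- FALSE
        }
        next
      }
    }
    return(list(activation = pmin(pmax(a, 0), 1), moment_residual = res,
                objective = sum(a^2), iterations = it, converged = feas))
  }
  out <- static_enumeration(G, moment, tol)
  if (!is.null(out)) return(out)
  res <- as.numeric(moment - G %*% a)
  list(activation = pmin(pmax(a, 0), 1), moment_residual = res,
       objective = sum(a^2), iterations = max_iter, converged = FALSE)
}

# exhaustive bound-configuration fallback for small problems, used when the
# active-set iteration stalls on a degenerate instance
static_enumeration <- function(G, moment, tol = 1e-10) {
  m <- ncol(G); d <- nrow(G)
  if (m > 10) return(NULL)
  best <- NULL; best_obj <- Inf
  for (code in 0:(3^m - 1)) {
    state <- (code %/% 3^(seq_len(m) - 1)) %% 3   # 0 free, 1 at 0, 2 at 1
    a <- rep(0, m)
    a[state == 2] <- 1
    free <- state == 0
    rhs <- moment - if (any(state == 2)) {
      rowSums(G[, state == 2, drop = FALSE])
    } else rep(0, d)
    if (any(free)) {
      Gf <- G[, free, drop = FALSE]
      K <- Gf %*% t(Gf)
      if (rcond(K) < 1e-12) next
      a[free] <- as.numeric(t(Gf) %*% solve(K, rhs))
    }
    if (any(a < -tol) || any(a > 1 + tol)) next
    if (max(abs(G %*% a - moment)) > 1e-8 * max(1, max(abs(moment)))) next
    obj <- sum(a^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- a
    }
  }
  if (is.null(best)) return(NULL)
  res <- as.numeric(moment - G %*% best)
  list(activation = pmin(pmax(best, 0), 1), moment_residual = res,
       objective = sum(best^2), iterations = NA_integer_, converged = TRUE)
}

# soft warm-start variant used to initialize the dynamic solver: ridge
# least squares toward the demand, clipped to the box
static_redundancy_ridge <- function(G, moment, w = 1e4) {
  d <- nrow(G)
  M <- G %*% t(G) + diag(1 / w, d)
  a <- as.numeric(t(G) %*% solve(M, moment))
  pmin(pmax(a, 0), 1)
}
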