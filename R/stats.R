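#' Repeated-measures correlation
#'
#' Common within-subject linear association between two repeatedly measured
#' variables, computed from the analysis-of-covariance model
#' `y ~ subject + x` (parallel regression lines with subject-specific
#' intercepts). The correlation coefficient carries the sign of the common
#' slope; degrees of freedom are `N - k - 1` for `N` observations and `k`
#' subjects.
#'
#' @param subject Subject identifiers (repeated).
#' @param x,y Paired observations.
#' @return A tibble of class `gaitmet_rmcorr` with `slope`, `r`, `df`,
#'   `p_value`, `n_subjects`, `n_obs`.
#' @export
rmcorr <- function(subject, x, y) {
  keep <- stats::complete.cases(subject, x, y)
  subject <- factor(subject[keep]); x <- x[keep]; y <- y[keep]
  counts <- table(subject)
  few <- names(counts)[counts < 2]
  if (length(few) > 0) {
    warning("dropping subjects with a single observation: ",
            paste(few, collapse = ", "))
    keep <- !(as.character(subject) %in% few)
    subject <- droplevels(subject[keep]); x <- x[keep]; y <- y[keep]
  }
  k <- nlevels(subject)
  if (k < 2) stop("need at least two subjects with >= 2 observations", call. = FALSE)
  fit <- stats::lm(y ~ subject + x)
  an <- suppressWarnings(stats::anova(fit))
  ss_x <- an["x", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df <- length(y) - k - 1
  slope <- unname(stats::coef(fit)["x"])
  r2 <- ss_x / (ss_x + ss_err)
  r <- sign(slope) * sqrt(r2)
  # exact fit: residual SS ~ 0 and p degenerates to 0
  if (ss_err <= .Machine$double.eps * max(1, ss_x)) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  out <- tibble::tibble(
    slope = slope, r = r, df = df, p_value = p,
    n_subjects = k, n_obs = length(y)
  )
  class(out) <- c("gaitmet_rmcorr", class(out))
  out
}

#' One-dimensional permutation (sign-flip) paired test on gait curves
#'
#' Pointwise paired t statistics over time-normalized curves, with
#' family-wise inference by permutation of the signs of the subject
#' difference curves. The critical threshold is the `1 - alpha` quantile of
#' the permutation distribution of the maximum (absolute, if two-tailed)
#' t statistic; suprathreshold clusters are reported with a permutation
#' p-value from the distribution of the maximum cluster extent.
#'
#' Sign assignments are fully enumerated when `2^n <= max_exhaustive`,
#' otherwise `n_perm` seeded Monte-Carlo flips are drawn.
#'
#' @param a,b Matrices, subjects x time points, matched rows.
#' @param alpha Family-wise error level (default 0.05).
#' @param two_tailed Two-tailed test (default `TRUE`).
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param max_exhaustive Largest enumeration size (default 4096).
#' @param seed Optional seed for the Monte-Carlo branch.
#' @return List of class `gaitmet_snpm` with `t` (pointwise curve),
#'   `threshold`, `alpha`, `clusters` (tibble `start_pct`, `end_pct`,
#'   `extent`, `p_value`), and `n_perm_used`.
#' @export
snpm_paired_1d <- function(a, b, alpha = 0.05, two_tailed = TRUE,
                           n_perm = 10000, max_exhaustive = 4096,
                           seed = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("curve matrices must match in shape", call. = FALSE)
  n <- nrow(a); K <- ncol(a)
  if (n < 4) warning("fewer than 4 subjects: the permutation set is very small")
  d <- a - b

  tcurve <- function(dm) {
    m <- colMeans(dm)
    s <- apply(dm, 2, stats::sd)
    s[s == 0] <- .Machine$double.eps
    m / (s / sqrt(n))
  }
  stat <- function(tv) if (two_tailed) abs(tv) else tv

  t_obs <- tcurve(d)
  if (2^n <= max_exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    n_used <- nrow(signs)
  } else {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    signs <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), ncol = n)
    signs[1, ] <- 1  # include the identity assignment
    n_used <- n_perm
  }
  max_stat <- numeric(n_used)
  perm_t <- matrix(NA_real_, n_used, K)
  for (i in seq_len(n_used)) {
    perm_t[i, ] <- tcurve(d * signs[i, ])
    max_stat[i] <- max(stat(perm_t[i, ]))
  }
  threshold <- sort(max_stat)[ceiling((1 - alpha) * n_used)]

  cluster_extents <- function(tv) {
    above <- stat(tv) > threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    tibble::tibble(start = starts[r$values], end = ends[r$values])
  }
  max_extent <- vapply(seq_len(n_used), function(i) {
    cl <- cluster_extents(perm_t[i, ])
    if (nrow(cl) == 0) 0 else max(cl$end - cl$start + 1)
  }, numeric(1))

  obs <- cluster_extents(t_obs)
  pct <- function(idx) 100 * (idx - 1) / (K - 1)
  clusters <- if (nrow(obs) == 0) {
    tibble::tibble(start_pct = numeric(), end_pct = numeric(),
                   extent = integer(), p_value = numeric())
  } else {
    tibble::tibble(
      start_pct = pct(obs$start), end_pct = pct(obs$end),
      extent = as.integer(obs$end - obs$start + 1),
      p_value = vapply(as.numeric(obs$end - obs$start + 1),
                       function(e) mean(max_extent >= e), numeric(1))
    )
  }
  structure(
    list(t = t_obs, threshold = threshold, alpha = alpha,
         two_tailed = two_tailed, clusters = clusters, n_perm_used = n_used),
    class = "gaitmet_snpm"
  )
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Wraps the exact signed-rank distribution for small samples (`n <= 12`
#' after dropping zero differences, provided there are no rank ties) and
#' the normal approximation otherwise. Zero differences are dropped with a
#' warning; if all differences are zero the p-value is 1.
#'
#' @param x,y Paired samples.
#' @param two_tailed Two-tailed test (default `TRUE`).
#' @return Tibble with `statistic` (V), `p_value`, `n_effective`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y, two_tailed = TRUE) {
  stopifnot(length(x) == length(y))
  d <- x - y
  nz <- d != 0
  if (!any(nz)) {
    warning("all paired differences are zero")
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          n_effective = 0L, exact = TRUE))
  }
  if (any(!nz)) warning(sum(!nz), " zero difference(s) dropped")
  d <- d[nz]
  n <- length(d)
  ties <- any(duplicated(abs(d)))
  use_exact <- n <= 12 && !ties
  alt <- if (two_tailed) "two.sided" else "greater"
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = alt, exact = use_exact,
                       correct = !use_exact)
  )
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_effective = n, exact = use_exact)
}

#' Agreement between a computed and a reference curve
#'
#' Pearson correlation and root-mean-square error between two curves on a
#' common grid.
#'
#' @param computed,reference Numeric vectors on the same grid.
#' @return Tibble with `r` and `rmse` (in the curves' units). `r` is `NA`
#'   (with a warning) for a constant reference.
#' @export
agreement_metrics <- function(computed, reference) {
  stopifnot(length(computed) == length(reference))
  rmse <- sqrt(mean((computed - reference)^2))
  if (stats::sd(reference) == 0 || stats::sd(computed) == 0) {
    warning("constant curve: correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(computed, reference)
  }
  tibble::tibble(r = r, rmse = rmse)
}

#' On/off timing of an excitation curve
#'
#' Intervals (in percent of the gait cycle) where the curve, normalized to
#' its own maximum, exceeds a threshold (default 50% excitation).
#'
#' @param excitation Excitation curve over one cycle.
#' @param threshold Fraction of the curve's maximum (default 0.5).
#' @return Tibble with `on_pct`, `off_pct` per interval (possibly empty).
#' @export
onoff_timing <- function(excitation, threshold = 0.5) {
  K <- length(excitation)
  mx <- max(excitation)
  empty <- tibble::tibble(on_pct = numeric(), off_pct = numeric())
  if (mx <= 0) return(empty)
  above <- (excitation / mx) > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  pct <- function(idx) 100 * (idx - 1) / (K - 1)
  if (!any(r$values)) return(empty)
  tibble::tibble(on_pct = pct(starts[r$values]), off_pct = pct(ends[r$values]))
}
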