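#' AUROC with DeLong variance
#'
#' Area under the ROC curve computed as the Mann-Whitney estimator (ties
#' counted one half): the probability that a randomly chosen event subject is
#' scored above a randomly chosen non-event subject. The variance is the
#' DeLong nonparametric estimate from the structural components (pseudovalues)
#' of the positives and negatives, computed with the midrank algorithm so
#' tied scores are handled exactly. The 95% confidence interval is the normal
#' approximation, clipped to `[0, 1]`.
#'
#' @param scores Numeric vector of risk scores (any monotone transform of a
#'   model's linear predictor gives the same AUC).
#' @param outcomes Binary vector (0/1 or logical) of the same length; both
#'   classes must be present.
#' @return Object of class `roc_result`: list with `auc`, `variance`,
#'   `ci95_low`, `ci95_high`, `n_pos`, `n_neg`.
#' @examples
#' auroc(c(.8, .6, .4, .2), c(1, 0, 1, 0))  # auc 0.75
#' @export
auroc <- function(scores, outcomes) {
  cmp <- delong_components(scores, outcomes)
  v <- stats::var(cmp$v_pos) / cmp$m + stats::var(cmp$v_neg) / cmp$n
  half <- 1.96 * sqrt(v)
  structure(list(auc = cmp$auc, variance = v,
                 ci95_low = max(0, cmp$auc - half),
                 ci95_high = min(1, cmp$auc + half),
                 n_pos = cmp$m, n_neg = cmp$n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, digits = 3, ...) {
  cat(sprintf("AUROC %.*f [95%% CI %.*f to %.*f]  (%d events, %d non-events)\n",
              digits, x$auc, digits, x$ci95_low, digits, x$ci95_high,
              x$n_pos, x$n_neg))
  invisible(x)
}

# DeLong structural components via the midrank identity:
# for positive i, V10_i = P(score_neg < s_i) + P(score_neg = s_i)/2
#               = (midrank_all(s_i) - midrank_pos(s_i)) / n_neg
# and symmetrically for negatives. AUC = mean(V10) = mean over positives.
delong_components <- function(scores, outcomes) {
  outcomes <- as.integer(as.logical(outcomes))
  stopifnot(length(scores) == length(outcomes), !anyNA(scores),
            !anyNA(outcomes))
  pos <- scores[outcomes == 1L]
  neg <- scores[outcomes == 0L]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) {
    stop("AUROC requires both classes present (", m, " events, ", n,
         " non-events)", call. = FALSE)
  }
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v_pos <- (r_all[seq_len(m)] - r_pos) / n
  v_neg <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = mean(v_pos), v_pos = v_pos, v_neg = v_neg, m = m, n = n)
}

#' Test equality of correlated ROC curves
#'
#' DeLong's nonparametric test for k ROC curves computed on the *same*
#' subjects (the test behind Stata's `roccomp`): the k-vector of AUCs has its
#' covariance estimated from the paired structural components; a contrast of
#' successive differences against the first curve yields a chi-square
#' statistic with k - 1 degrees of freedom under the null of equal areas.
#' With k = 2 the statistic is exactly the square of the usual paired
#' z-statistic. A singular contrast covariance (e.g. two identical score
#' vectors) is handled by the Moore-Penrose pseudoinverse with the degrees of
#' freedom reduced to the covariance rank; identical curves return statistic
#' 0 and p 1.
#'
#' @param score_sets List of k numeric score vectors, all aligned to the same
#'   subjects (same length and order).
#' @param outcomes Binary outcome vector shared by all curves.
#' @return Object of class `roc_comparison`: list with `statistic`, `df`,
#'   `p_value`, `aucs`.
#' @export
compare_roc <- function(score_sets, outcomes) {
  stopifnot(is.list(score_sets), length(score_sets) >= 2L)
  k <- length(score_sets)
  len <- vapply(score_sets, length, 1L)
  if (length(unique(len)) != 1L || len[1] != length(outcomes)) {
    stop("all score vectors must be aligned to the same subjects",
         call. = FALSE)
  }
  cmp <- lapply(score_sets, delong_components, outcomes = outcomes)
  m <- cmp[[1]]$m; n <- cmp[[1]]$n
  v10 <- sapply(cmp, `[[`, "v_pos")   # m x k
  v01 <- sapply(cmp, `[[`, "v_neg")   # n x k
  aucs <- vapply(cmp, `[[`, 0, "auc")
  s <- stats::cov(v10) / m + stats::cov(v01) / n
  contrast <- cbind(-1, diag(k - 1))   # curve j vs curve 1
  d <- as.vector(contrast %*% aucs)
  vd <- contrast %*% s %*% t(contrast)
  pi_vd <- pseudo_solve(vd)
  stat <- max(0, as.numeric(t(d) %*% pi_vd$inv %*% d))
  df <- max(1L, pi_vd$rank)
  p <- if (pi_vd$rank == 0L) 1 else stats::pchisq(stat, df,
                                                  lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 aucs = aucs), class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("ROC equality test: chi2(%d) = %.3f, p = %.4g\n",
              x$df, x$statistic, x$p_value))
  cat("  AUCs:", paste(sprintf("%.4f", x$aucs), collapse = ", "), "\n")
  invisible(x)
}

# pseudoinverse via SVD; returns rank so callers can adjust df
pseudo_solve <- function(a, tol = 1e-10) {
  sv <- svd(a)
  keep <- sv$d > tol * max(sv$d, 0)
  rank <- sum(keep)
  inv <- if (rank == 0L) matrix(0, nrow(a), ncol(a)) else
    sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(inv = inv, rank = rank)
}

#' Paired bootstrap test of two correlated AUCs
#'
#' Cross-check for [compare_roc()]: resamples subjects with replacement,
#' stratified by outcome, and refers the observed AUC difference to its
#' bootstrap standard error on the normal scale. Not the default test --
#' provided to corroborate the DeLong p-value.
#'
#' @param scores1,scores2 Score vectors on the same subjects.
#' @param outcomes Shared binary outcome.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Seed for the resampling stream.
#' @return List with `p_value`, `delta` (observed AUC difference) and `se`.
#' @export
bootstrap_roc_test <- function(scores1, scores2, outcomes, n_boot = 2000,
                               seed = 1L) {
  outcomes <- as.integer(as.logical(outcomes))
  ip <- which(outcomes == 1L); im <- which(outcomes == 0L)
  delta <- auroc(scores1, outcomes)$auc - auroc(scores2, outcomes)$auc
  with_seed(stage_seed(seed, "bootstrap_roc"), {
    ds <- vapply(seq_len(n_boot), function(b) {
      i <- c(sample(ip, replace = TRUE), sample(im, replace = TRUE))
      o <- outcomes[i]
      delong_components(scores1[i], o)$auc -
        delong_components(scores2[i], o)$auc
    }, 0)
    se <- stats::sd(ds)
    z <- delta / se
    list(p_value = 2 * stats::pnorm(-abs(z)), delta = delta, se = se)
  })
}
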