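#' Anderson-Darling test of normality
#'
#' Case-3 composite test (mean and variance estimated from the sample),
#' computed via [nortest::ad.test()]. The pipeline reports this check but
#' always proceeds nonparametrically; it gates nothing.
#'
#' @param x numeric sample, n >= 8, non-degenerate.
#' @return a `feit_test` with the A-squared statistic and p-value.
#' @export
anderson_darling <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 8L) stop("Anderson-Darling test needs at least 8 observations")
  if (sd(x) == 0) stop("sample has zero variance")
  at <- nortest::ad.test(x)
  test_result(unname(at$statistic), at$p.value,
              "Anderson-Darling normality test", n = length(x))
}

# within-block midranks and the tie-corrected Friedman chi-square pieces
friedman_parts <- function(y) {
  n <- nrow(y); k <- ncol(y)
  r <- t(apply(y, 1L, rank))
  Rj <- colSums(r)
  A1 <- sum(r^2)
  C1 <- n * k * (k + 1)^2 / 4
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  stat <- if (A1 == C1) 0 else num / (A1 - C1)
  list(n = n, k = k, ranks = r, rank_sums = Rj, A1 = A1, C1 = C1,
       statistic = stat)
}

#' Friedman repeated-measures rank test
#'
#' Blocks are subjects, columns are treatments (body positions). Within
#' each block the values are converted to midranks; the tie-corrected
#' chi-square statistic has `k - 1` degrees of freedom. For small,
#' tie-free tables (`k!^n <= 50000`) the p-value is computed exactly by
#' enumerating all within-block rank orderings; otherwise the chi-square
#' approximation is used.
#'
#' @param table numeric matrix, blocks x treatments, complete (no `NA`),
#'   with at least 3 blocks and 3 treatments.
#' @param exact `"auto"` (default), `"never"` or `"always"` (errors when
#'   enumeration is infeasible).
#' @return a `feit_test` with `statistic` (chi-square), `p_value`, `df`,
#'   `rank_sums`.
#' @export
friedman_test <- function(table, exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  y <- as.matrix(table)
  if (anyNA(y)) stop("block table has missing cells; the design must be complete")
  if (nrow(y) < 3L || ncol(y) < 3L)
    stop("need at least 3 blocks and 3 treatments")
  fp <- friedman_parts(y)
  n <- fp$n; k <- fp$k
  has_ties <- any(apply(y, 1L, function(row) anyDuplicated(row) > 0L))
  n_orderings <- factorial(k)^n
  use_exact <- switch(exact,
                      never = FALSE,
                      always = TRUE,
                      auto = !has_ties && n_orderings <= 5e4)
  if (use_exact && (has_ties || n_orderings > 5e6))
    stop("exact enumeration infeasible for this table")
  if (use_exact) {
    perms <- perm_matrix(k)
    combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(perms))), n)))
    Rj <- matrix(0, nrow(combos), k)
    for (b in seq_len(n)) Rj <- Rj + perms[combos[, b], , drop = FALSE]
    stats <- 12 / (n * k * (k + 1)) * rowSums((Rj - n * (k + 1) / 2)^2)
    p <- mean(stats >= fp$statistic - 1e-9)
    method <- "Friedman rank sum test (exact permutation p)"
  } else {
    p <- pchisq(fp$statistic, k - 1L, lower.tail = FALSE)
    method <- "Friedman rank sum test (chi-square approximation)"
  }
  test_result(fp$statistic, p, method, df = k - 1L, rank_sums = fp$rank_sums,
              n_blocks = n, n_treatments = k)
}

# all k! permutations of 1..k as rows
perm_matrix <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_matrix(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Conover post-hoc test after Friedman
#'
#' All-pairs comparisons based on within-block rank sums: the statistic
#' for treatments i, j is `(R_i - R_j)` divided by
#' `sqrt(2 (n A1 - sum R^2) / ((n-1)(k-1)))`, referred to a t
#' distribution on `(n-1)(k-1)` degrees of freedom, where `A1` is the sum
#' of squared ranks. Pairwise p-values are corrected with Holm's
#' step-down procedure by default (Bonferroni available). Intended to be
#' run after a significant Friedman omnibus; calling it otherwise raises
#' a warning but still computes.
#'
#' @param table numeric matrix, blocks x treatments, complete.
#' @param friedman optional `feit_test` from [friedman_test()] on the same
#'   table (computed if missing).
#' @param correction `"holm"` (default) or `"bonferroni"`.
#' @param alpha omnibus significance level used for the warning.
#' @return a `feit_test` whose `pairwise` element is the symmetric matrix
#'   of corrected p-values (unit diagonal); the raw t statistics are in
#'   `t_statistics`.
#' @export
conover_posthoc <- function(table, friedman = NULL,
                            correction = c("holm", "bonferroni"),
                            alpha = 0.05) {
  correction <- match.arg(correction)
  y <- as.matrix(table)
  if (anyNA(y)) stop("block table has missing cells; the design must be complete")
  if (is.null(friedman)) friedman <- friedman_test(y)
  if (friedman$p_value >= alpha)
    warning(sprintf("Friedman omnibus p = %.3g is not significant at %g; post-hoc comparisons are exploratory",
                    friedman$p_value, alpha))
  fp <- friedman_parts(y)
  n <- fp$n; k <- fp$k; Rj <- fp$rank_sums
  denom2 <- 2 * (n * fp$A1 - sum(Rj^2)) / ((n - 1) * (k - 1))
  df <- (n - 1) * (k - 1)
  tmat <- matrix(0, k, k, dimnames = list(colnames(y), colnames(y)))
  pmat <- matrix(1, k, k, dimnames = list(colnames(y), colnames(y)))
  pairs <- which(upper.tri(tmat), arr.ind = TRUE)
  tt <- numeric(nrow(pairs)); pr <- numeric(nrow(pairs))
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, 1L]; j <- pairs[q, 2L]
    dRj <- Rj[i] - Rj[j]
    tq <- if (denom2 > 0) dRj / sqrt(denom2)
    else if (dRj == 0) 0 else sign(dRj) * Inf
    tt[q] <- tq
    pr[q] <- 2 * pt(-abs(tq), df)
  }
  pc <- p.adjust(pr, method = correction)
  for (q in seq_len(nrow(pairs))) {
    i <- pairs[q, 1L]; j <- pairs[q, 2L]
    tmat[i, j] <- tt[q]; tmat[j, i] <- -tt[q]
    pmat[i, j] <- pc[q]; pmat[j, i] <- pc[q]
  }
  test_result(friedman$statistic, friedman$p_value,
              sprintf("Conover all-pairs post-hoc (Friedman), %s-corrected",
                      correction),
              pairwise = pmat, t_statistics = tmat, df = df,
              rank_sums = Rj)
}

#' Wilcoxon signed rank test for paired samples
#'
#' Differences equal to zero are dropped; at least 6 informative pairs
#' are required. The p-value is exact for n <= 25 without ties and uses
#' the normal approximation with tie correction otherwise (via
#' [stats::wilcox.test()]).
#'
#' @param x,y paired numeric vectors of equal length.
#' @return a `feit_test` with the signed-rank statistic `V` and p-value.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) stop("all paired differences are zero")
  if (length(d) < 6L)
    stop("fewer than 6 non-zero paired differences; test not meaningful")
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))
  test_result(unname(wt$statistic), wt$p.value,
              sprintf("Wilcoxon signed rank test (%s)",
                      if (exact) "exact" else "normal approximation"),
              n = length(d))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return a `feit_test`; the correlation coefficient is both the
#'   `statistic` and the `estimate`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ct$estimate), ct$p.value, "Pearson correlation",
              estimate = unname(ct$estimate), n = length(x))
}
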