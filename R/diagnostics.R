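# Statistical battery: normality, instrument agreement, group comparison
# with LSD contrasts, Pearson correlation.

#' Normality test (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample K-S statistic of the sample against a normal distribution
#' with the sample's own mean and SD; because the parameters are
#' estimated, the p-value uses the Lilliefors correction
#' (Dallal-Wilkinson approximation, via [nortest::lillie.test()]).
#'
#' @param x numeric sample, `n >= 5`, non-degenerate.
#' @return list with `statistic` and `p`.
#' @export
ks_normality <- function(x) {
  stop_if_not_number(x, "x")
  if (length(x) < 5) stop("need n >= 5", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance",
                              call. = FALSE)
  res <- nortest::lillie.test(x)
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

# ICC(A,1): two-way random effects, absolute agreement, single measure,
# from the two-way mean squares (n subjects x k raters, no replication).
icc_a1 <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  MSR <- k * sum((row_m - grand)^2) / (n - 1)
  MSC <- n * sum((col_m - grand)^2) / (k - 1)
  SSE <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (denom == 0) return(1)
  (MSR - MSE) / denom
}

# Concordance correlation coefficient with population (1/n) moments.
ccc_coef <- function(x, y) {
  n <- length(x)
  sx2 <- stats::var(x) * (n - 1) / n
  sy2 <- stats::var(y) * (n - 1) / n
  sxy <- stats::cov(x, y) * (n - 1) / n
  2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
}

#' Instrument agreement suite
#'
#' Given paired readings of the same quantity from two instruments,
#' computes the Bland-Altman bias and 95% limits of agreement
#' (`bias +/- 1.96 SD` of the differences), the paired t-test, the
#' intraclass correlation coefficient ICC(A,1) (two-way random effects,
#' absolute agreement, single measure -- the standard form for two-device
#' agreement) and the concordance correlation coefficient.
#'
#' @param x,y paired numeric vectors (instrument 1 and 2), `n >= 3`.
#' @return object of class `agreement_result`: list with `bias`,
#'   `loa_low`, `loa_high`, `paired_t_p`, `icc`, `ccc`, `n` and `icc_form`.
#' @export
agreement_suite <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3 pairs", call. = FALSE)
  d <- y - x
  bias <- mean(d)
  sdd <- stats::sd(d)
  pt <- if (sdd == 0) 1 else stats::t.test(y, x, paired = TRUE)$p.value
  structure(
    list(bias = bias, loa_low = bias - 1.96 * sdd,
         loa_high = bias + 1.96 * sdd, paired_t_p = pt,
         icc = icc_a1(cbind(x, y)), ccc = ccc_coef(x, y),
         n = length(x), icc_form = "ICC(A,1) two-way random, absolute agreement, single measure"),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Agreement (n=%d): bias %.4g, LoA [%.4g, %.4g], paired-t p %.3g, ICC %.3f, CCC %.3f\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$paired_t_p, x$icc, x$ccc))
  invisible(x)
}

#' One-way ANOVA with Fisher LSD pairwise contrasts
#'
#' Standard one-way analysis of variance followed by least-significant-
#' difference pairwise t-tests using the pooled within-group mean square
#' and its degrees of freedom.  Raw (unadjusted) p-values are reported, as
#' is conventional for the LSD procedure; the number of comparisons is
#' recorded so a reader can judge multiplicity.
#'
#' @param groups named list of numeric vectors (one per group, each
#'   `n >= 2`), or a data frame with columns `value` and `group`.
#' @return object of class `group_comparison`: list with `summary`
#'   (per-group n/mean/SD), `F`, `p`, `df`, `pairwise` (data frame of LSD
#'   contrasts), `SSB`, `SSW`, `SST` and `n_comparisons`.
#' @export
anova_lsd <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("every group needs n >= 2", call. = FALSE)
  }
  labs <- names(groups) %||% as.character(seq_along(groups))
  n_i <- vapply(groups, length, 1L)
  m_i <- vapply(groups, mean, 1)
  s_i <- vapply(groups, stats::sd, 1)
  N <- sum(n_i)
  kg <- length(groups)
  grand <- sum(n_i * m_i) / N
  SSB <- sum(n_i * (m_i - grand)^2)
  SSW <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  SST <- SSB + SSW
  df1 <- kg - 1
  df2 <- N - kg
  MSW <- SSW / df2
  flag <- NULL
  if (MSW == 0) {
    Fstat <- if (SSB == 0) 0 else Inf
    p <- if (SSB == 0) 1 else 0
    if (SSB > 0) flag <- "zero within-group variance"
  } else {
    Fstat <- (SSB / df1) / MSW
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  pair <- utils::combn(seq_len(kg), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pair)), function(j) {
    a <- pair[1, j]; b <- pair[2, j]
    se <- sqrt(MSW * (1 / n_i[a] + 1 / n_i[b]))
    tval <- if (se == 0) {
      if (m_i[a] == m_i[b]) 0 else Inf
    } else {
      (m_i[a] - m_i[b]) / se
    }
    data.frame(groupA = labs[a], groupB = labs[b],
               diff = m_i[a] - m_i[b], t = tval,
               p = if (is.infinite(tval)) 0 else
                 2 * stats::pt(abs(tval), df2, lower.tail = FALSE))
  }))
  structure(
    list(summary = data.frame(group = labs, n = n_i, mean = m_i, sd = s_i,
                              row.names = NULL),
         F = Fstat, p = p, df = c(df1, df2), pairwise = pairwise,
         SSB = SSB, SSW = SSW, SST = SST,
         n_comparisons = ncol(pair), flag = flag),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(x$summary, row.names = FALSE)
  cat("LSD contrasts:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors, `n >= 3`, both non-degenerate.
#' @return list with `r`, `p` and `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
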