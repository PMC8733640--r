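# ROC analysis: empirical curve, trapezoidal AUC, Youden cutoff, and the
# DeLong placement-value test for paired AUC comparison.

coerce_cases <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  lv <- levels(droplevels(f))
  if (length(lv) != 2) stop("labels must have exactly two classes",
                            call. = FALSE)
  pos <- positive %||% lv[2]
  if (!pos %in% lv) stop("`positive` is not a label level", call. = FALSE)
  as.character(f) == pos
}

#' Empirical ROC curve with Youden cutoff
#'
#' Computes the empirical ROC over all score thresholds, the trapezoidal
#' AUC (identical to the Mann-Whitney pair-counting probability with ties
#' scored 1/2), and an operating cutoff chosen by the Youden index
#' `J = sensitivity + specificity - 1` (ties broken toward higher
#' specificity).  The score orientation is chosen automatically so that
#' `AUC >= 0.5` and recorded in `direction` (`"cases_high"` means cases
#' tend to score higher; a positive call is `score >= cutoff` for
#' `cases_high` and `score <= cutoff` for `cases_low`).
#'
#' @param scores numeric marker values.
#' @param labels two-class labels (logical with `TRUE` = case, or any
#'   two-level vector with `positive` naming the case level).
#' @param positive case level when `labels` is not logical.
#' @param direction `"auto"` (default), `"cases_high"` or `"cases_low"`.
#' @return object of class `roc_result`: list with `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden`, `direction`, `curve` (data
#'   frame `threshold`, `fpr`, `tpr`) and class counts.
#' @export
roc_curve <- function(scores, labels, positive = NULL,
                      direction = c("auto", "cases_high", "cases_low")) {
  direction <- match.arg(direction)
  cases <- coerce_cases(labels, positive)
  if (length(scores) != length(cases)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(scores) & !is.na(cases)
  scores <- scores[ok]; cases <- cases[ok]
  if (!any(cases) || all(cases)) {
    stop("both classes must be present", call. = FALSE)
  }
  build <- function(s) {
    thr <- sort(unique(s))
    tpr <- vapply(thr, function(th) mean(s[cases] >= th), 1)
    fpr <- vapply(thr, function(th) mean(s[!cases] >= th), 1)
    curve <- data.frame(threshold = c(-Inf, thr, Inf),
                        fpr = c(1, fpr, 0), tpr = c(1, tpr, 0))
    o <- order(curve$fpr, curve$tpr)
    cu <- curve[o, ]
    auc <- sum(diff(cu$fpr) * (utils::head(cu$tpr, -1) +
                                 utils::tail(cu$tpr, -1)) / 2)
    list(curve = curve, auc = auc)
  }
  hi <- build(scores)
  dir_use <- direction
  if (direction == "auto") {
    dir_use <- if (hi$auc >= 0.5) "cases_high" else "cases_low"
  }
  if (dir_use == "cases_high") {
    res <- hi
    s_eff <- scores
  } else {
    res <- build(-scores)
    s_eff <- -scores
  }
  # Youden cutoff over the attainable operating points
  cv <- res$curve
  J <- cv$tpr - cv$fpr
  spec <- 1 - cv$fpr
  best <- which(J == max(J))
  best <- best[which.max(spec[best])]
  thr_eff <- cv$threshold[best]
  # report the cutoff as a midpoint between adjacent observed scores where
  # possible, on the original score scale
  lower_scores <- s_eff[s_eff < thr_eff]
  cut_eff <- if (is.finite(thr_eff) && length(lower_scores)) {
    (thr_eff + max(lower_scores)) / 2
  } else {
    thr_eff
  }
  cutoff <- if (dir_use == "cases_high") cut_eff else -cut_eff
  sens <- mean(s_eff[cases] >= cut_eff)
  specat <- mean(s_eff[!cases] < cut_eff)
  structure(
    list(auc = res$auc, cutoff = unname(cutoff), sensitivity = sens,
         specificity = specat, youden = sens + specat - 1,
         direction = dir_use, curve = res$curve,
         n_cases = sum(cases), n_controls = sum(!cases)),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC (%d cases / %d controls, %s): AUC %.3f; cutoff %.4g -> sens %.3f, spec %.3f\n",
    x$n_cases, x$n_controls, x$direction, x$auc, x$cutoff,
    x$sensitivity, x$specificity))
  invisible(x)
}

# DeLong placement values: V10 (per case) and V01 (per control) for one
# marker under the cases-high convention.
delong_placements <- function(scores, cases) {
  xs <- scores[cases]
  ys <- scores[!cases]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(xs, function(xi) mean(psi(xi, ys)), 1)
  v01 <- vapply(ys, function(yj) mean(psi(xs, yj)), 1)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired comparison of two correlated AUCs (DeLong test)
#'
#' Both markers must be scored on the same subjects.  The test statistic
#' is the AUC difference divided by its standard error from the DeLong
#' placement-value covariance construction; the p-value is two-sided
#' normal.  Marker orientation follows each marker's own `auto` direction
#' so the comparison is between the discriminative abilities.
#'
#' @param scores1,scores2 numeric marker values on identical subjects.
#' @param labels shared two-class labels.
#' @param positive case level when `labels` is not logical.
#' @return list with `auc1`, `auc2`, `delta`, `var_delta`, `z` and `p`.
#' @export
roc_compare <- function(scores1, scores2, labels, positive = NULL) {
  cases <- coerce_cases(labels, positive)
  if (length(scores1) != length(cases) || length(scores2) != length(cases)) {
    stop("length mismatch", call. = FALSE)
  }
  if (!any(cases) || all(cases)) {
    stop("both classes must be present", call. = FALSE)
  }
  orient <- function(s) {
    if (delong_placements(s, cases)$auc >= 0.5) s else -s
  }
  s1 <- orient(scores1)
  s2 <- orient(scores2)
  p1 <- delong_placements(s1, cases)
  p2 <- delong_placements(s2, cases)
  m <- sum(cases)
  n <- sum(!cases)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- p1$auc - p2$auc
  if (var_delta <= 0 || delta == 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc1 = p1$auc, auc2 = p2$auc, delta = delta,
       var_delta = var_delta, z = z, p = p)
}
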