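#' @include AllClasses.R kinematics.R
NULL

#' Comparison result container
#'
#' Plain-list result of a two-group comparison: effect estimate (mm or
#' degrees), test statistic, degrees of freedom, p-value and the
#' significance flag at `alpha`.
#'
#' @param estimate,statistic,df,p numeric scalars.
#' @param alpha significance level.
#' @param test label of the test performed.
#' @return list with class `comparisonResult`.
#' @keywords internal
comparisonResult <- function(estimate, statistic, df, p, alpha = 0.05,
                             test = "t") {
  stopifnot(p >= 0, p <= 1)
  structure(list(estimate = estimate, statistic = statistic, df = df,
                 p = p, alpha = alpha, significant = p < alpha,
                 test = test),
            class = "comparisonResult")
}

#' @export
print.comparisonResult <- function(x, ...) {
  cat(sprintf("%s: estimate %.4g, t = %.4g, df = %.3g, p = %.4g %s\n",
              x$test, x$estimate, x$statistic, x$df, x$p,
              if (x$significant) sprintf("(significant at %.2g)", x$alpha)
              else ""))
  invisible(x)
}

#' Paired t test
#'
#' Classical paired t on the within-pair differences `x - y`.
#'
#' @param x,y paired numeric vectors of equal length, n >= 2.
#' @param alpha significance level (default 0.05).
#' @return A `comparisonResult` list (estimate = mean difference).
#' @export
pairedT <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("paired t test needs n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) < 1e-12)
    stop("degenerate paired t test: zero variance of the differences")
  ht <- stats::t.test(x, y, paired = TRUE)
  comparisonResult(unname(ht$estimate), unname(ht$statistic),
                   unname(ht$parameter), ht$p.value, alpha, "paired t")
}

#' Welch's t test
#'
#' Unequal-variance two-sample t with Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param x,y numeric vectors, each n >= 2.
#' @param alpha significance level (default 0.05).
#' @return A `comparisonResult` list (estimate = mean(x) - mean(y)).
#' @export
welchT <- function(x, y, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) stop("Welch t test needs n >= 2")
  if (stats::var(x) + stats::var(y) < 1e-24)
    stop("degenerate Welch t test: both samples have zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE)
  comparisonResult(unname(ht$estimate[1] - ht$estimate[2]),
                   unname(ht$statistic), unname(ht$parameter), ht$p.value,
                   alpha, "Welch t")
}

#' Repeated-measures comparison of condition curves
#'
#' Post hoc pairwise condition contrasts from a mixed linear model with
#' repeated measures over flexion bins: for each requested condition pair
#' the model `value ~ condition + flexionBin + (1 | subject)` is fit on
#' that pair's data (REML via \pkg{lmerTest}) and the condition
#' coefficient is reported with its Satterthwaite degrees of freedom.
#' Contrasts are reported unadjusted; set `adjust = "holm"` for a Holm
#' correction across the pairs.
#'
#' @param curves list of [KinematicCurve-class] objects, or a long
#'   data.frame as from [curvesToTable()].
#' @param channel `"ap"` (mm) or `"rotation"` (degrees).
#' @param pairs list of length-2 character vectors of condition names;
#'   default: all pairs present.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default, raw p-values) or `"holm"`.
#' @return data.frame with one row per pair: conditions, effect estimate
#'   (first minus second), t statistic, df, p, significance flag.
#' @export
repeatedMeasuresCompare <- function(curves, channel = c("ap", "rotation"),
                                    pairs = NULL, alpha = 0.05,
                                    adjust = c("none", "holm")) {
  channel <- match.arg(channel)
  adjust <- match.arg(adjust)
  tab <- if (is.data.frame(curves)) curves else curvesToTable(curves)
  tab$value <- if (channel == "ap") tab$ap_mm else tab$rot_deg
  missingBins <- is.na(tab$value)
  if (any(missingBins)) {
    warning("dropping ", sum(missingBins), " missing flexion-bin values")
    tab <- tab[!missingBins, , drop = FALSE]
  }
  conds <- unique(tab$condition)
  if (is.null(pairs)) {
    cmb <- utils::combn(conds, 2, simplify = FALSE)
    pairs <- cmb
  }
  rows <- lapply(pairs, function(pr) {
    sub <- tab[tab$condition %in% pr, , drop = FALSE]
    if (length(unique(sub$subject)) < 2L)
      stop("repeated-measures comparison needs at least 2 subjects")
    sub$condition <- factor(sub$condition, levels = pr)
    sub$flexionBin <- factor(sub$flexion)
    fit <- suppressMessages(lmerTest::lmer(
      value ~ condition + flexionBin + (1 | subject), data = sub,
      REML = TRUE))
    co <- stats::coef(summary(fit))
    row <- co[grep("^condition", rownames(co))[1], ]
    data.frame(condition1 = pr[2], condition2 = pr[1],
               effect = unname(row["Estimate"]),
               statistic = unname(row["t value"]),
               df = unname(row["df"]),
               p = unname(row["Pr(>|t|)"]))
  })
  out <- do.call(rbind, rows)
  if (adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  out$significant <- out$p < alpha
  out
}
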