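# Group comparison: per-cell two-tailed tests with the Bonferroni
# threshold 0.05 / 68 regions / 5 bands = 0.000147.

#' Bonferroni significance threshold
#'
#' `alpha / (n_regions * n_bands)`; with the defaults,
#' 0.05 / 68 / 5 = 1.47e-4 (printed 0.000147). The divisor counts regions
#' and bands only — the threshold is applied within each value-type family.
#'
#' @param alpha Family-wise error target in (0, 1].
#' @param n_regions,n_bands Multiplicity counts (>= 1).
#' @return The per-cell threshold.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 68, 5)
bonferroni_threshold <- function(alpha = 0.05, n_regions = 68, n_bands = 5) {
  if (!(alpha > 0 && alpha <= 1)) {
    stop_megspect("alpha must be in (0, 1]", "megspect_invalid_alpha")
  }
  if (n_regions < 1 || n_bands < 1) {
    stop_megspect("counts must be positive", "megspect_invalid_counts")
  }
  alpha / (n_regions * n_bands)
}

# Vectorized two-sample tests over the columns of two matrices.
# Returns statistic, df, p (two-tailed).
column_welch <- function(xa, xb, pooled = FALSE) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  diff <- ma - mb
  stat <- diff / se
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  # degenerate cells: zero variance in both groups
  zero <- se == 0 | !is.finite(se)
  if (any(zero)) {
    eq <- zero & diff == 0
    stat[eq] <- 0; p[eq] <- 1; df[eq] <- NA_real_
    ne <- zero & diff != 0
    stat[ne] <- sign(diff[ne]) * Inf; p[ne] <- 0; df[ne] <- NA_real_
  }
  list(statistic = stat, df = df, p = p, mean_diff = diff)
}

#' Compare AD and NC groups per feature cell
#'
#' Runs a two-tailed two-sample test (Welch's unequal-variance t by
#' default) on every column of the feature matrix and flags cells against
#' the Bonferroni threshold. Direction is the sign of `mean(AD) - mean(NC)`.
#' Cells with zero variance in both groups and equal means get `p = 1` by
#' convention.
#'
#' @param features A `meg_features` object, or a plain matrix together with
#'   `group`.
#' @param group Factor/character of `"AD"`/`"NC"` per row (ignored when
#'   `features` is a `meg_features`).
#' @param threshold Significance threshold (default
#'   [bonferroni_threshold()]).
#' @param method `"welch"` (default), `"student"`, or `"wilcoxon"`.
#' @return Data frame of class `meg_group_comparison`: one row per cell with
#'   `name`, `value_type`, `band`, `region`, `statistic`, `p`, `direction`
#'   (`"AD>NC"`/`"NC>AD"`), `significant`; the threshold is carried as an
#'   attribute.
#' @export
compare_groups <- function(features, group = NULL,
                           threshold = bonferroni_threshold(),
                           method = c("welch", "student", "wilcoxon")) {
  method <- match.arg(method)
  if (inherits(features, "meg_features")) {
    x <- features$x
    group <- features$group
    idx <- features$index
  } else {
    x <- features
    stopifnot(!is.null(group))
    idx <- NULL
  }
  group <- factor(as.character(group), levels = c("NC", "AD"))
  if (min(table(group)) < 2) {
    stop_megspect("need at least 2 subjects per group",
                  "megspect_too_few_subjects")
  }
  xa <- x[group == "AD", , drop = FALSE]
  xb <- x[group == "NC", , drop = FALSE]
  if (method == "wilcoxon") {
    p <- numeric(ncol(x)); stat <- numeric(ncol(x))
    for (j in seq_len(ncol(x))) {
      wt <- suppressWarnings(stats::wilcox.test(xa[, j], xb[, j],
                                                exact = FALSE))
      p[j] <- wt$p.value; stat[j] <- unname(wt$statistic)
    }
    diff <- colMeans(xa) - colMeans(xb)
    res <- list(statistic = stat, p = p, mean_diff = diff)
  } else {
    res <- column_welch(xa, xb, pooled = (method == "student"))
  }
  out <- data.frame(
    name = colnames(x) %||% sprintf("cell_%04d", seq_len(ncol(x))),
    statistic = res$statistic,
    p = res$p,
    direction = ifelse(res$mean_diff >= 0, "AD>NC", "NC>AD"),
    significant = res$p < threshold,
    stringsAsFactors = FALSE
  )
  if (!is.null(idx)) {
    out <- cbind(idx[, c("value_type", "band", "region")], out)
  }
  attr(out, "threshold") <- threshold
  attr(out, "method") <- method
  class(out) <- c("meg_group_comparison", "data.frame")
  out
}
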