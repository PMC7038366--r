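#' One-way repeated-measures ANOVA
#'
#' Classical within-subject one-way ANOVA on a complete subjects x
#' conditions matrix of feature means.  The total sum of squares is split
#' into condition, subject and error components:
#' SS_condition = n sum((condition mean - grand)^2),
#' SS_subject = k sum((subject mean - grand)^2),
#' SS_error = SS_total - SS_condition - SS_subject, and
#' F = (SS_condition / (k-1)) / (SS_error / ((k-1)(n-1))) with the upper-tail
#' F probability as p-value.  No sphericity correction is applied by
#' default; `gg_correction = TRUE` applies the Greenhouse-Geisser epsilon to
#' the degrees of freedom as a sensitivity analysis.
#'
#' @param mat numeric matrix, subjects in rows, conditions in columns,
#'   no missing cells.
#' @param gg_correction apply the Greenhouse-Geisser correction.
#' @param feature optional feature label carried in the result.
#' @return An `anova_result` list: `feature`, `F`, `p`, `df_condition`,
#'   `df_error`, `ss_condition`, `ss_subject`, `ss_error`, and `epsilon`
#'   when corrected.
#' @export
rm_anova_oneway <- function(mat, gg_correction = FALSE, feature = NA) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells in the subject x condition matrix; no imputation is performed",
                       call. = FALSE)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  grand <- mean(mat)
  cm <- colMeans(mat); rm_ <- rowMeans(mat)
  ss_cond <- n * sum((cm - grand)^2)
  ss_subj <- k * sum((rm_ - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df_c <- k - 1L; df_e <- (k - 1L) * (n - 1L)
  ms_c <- ss_cond / df_c; ms_e <- ss_err / df_e
  F <- if (ms_e > 0) ms_c / ms_e else if (ms_c == 0) 0 else Inf
  eps <- 1
  if (gg_correction && k > 2L) {
    S <- stats::cov(mat)
    mS <- mean(S); rowm <- rowMeans(S)
    num <- (k * (mean(diag(S)) - mS))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * mS^2)
    eps <- max(min(num / den, 1), 1 / (k - 1))
  }
  p <- stats::pf(F, df_c * eps, df_e * eps, lower.tail = FALSE)
  structure(list(feature = feature, F = F, p = p,
                 df_condition = df_c, df_error = df_e,
                 ss_condition = ss_cond, ss_subject = ss_subj,
                 ss_error = ss_err, epsilon = eps),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA%s: F(%g, %g) = %.3f, p = %.4g\n",
              if (is.na(x$feature)) "" else paste0(" [", x$feature, "]"),
              x$df_condition * x$epsilon, x$df_error * x$epsilon, x$F, x$p))
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Paired two-sided t tests on subject-wise differences for every condition
#' pair, with Bonferroni adjustment (raw p times the number of pairs, capped
#' at 1) and significance flags at `alpha`.  A zero-variance difference
#' vector is flagged degenerate and never significant.
#'
#' @param mat subjects x conditions matrix as in [rm_anova_oneway()].
#' @param alpha significance level (default 0.05).
#' @param feature optional label.
#' @return data.frame: `feature`, `condition_a`, `condition_b`,
#'   `mean_diff`, `p_raw`, `p_adj`, `significant`, `degenerate`.
#' @export
bonferroni_pairwise <- function(mat, alpha = 0.05, feature = NA) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells", call. = FALSE)
  k <- ncol(mat)
  if (k < 2L) stop("need at least 2 conditions", call. = FALSE)
  conds <- colnames(mat)
  if (is.null(conds)) conds <- paste0("c", seq_len(k))
  pairs <- utils::combn(k, 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(q) {
    a <- pairs[1L, q]; b <- pairs[2L, q]
    d <- mat[, a] - mat[, b]
    degen <- stats::sd(d) == 0
    p_raw <- if (degen) NA_real_ else stats::t.test(d)$p.value
    data.frame(feature = feature, condition_a = conds[a],
               condition_b = conds[b], mean_diff = mean(d),
               p_raw = p_raw, stringsAsFactors = FALSE, degenerate = degen)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(out$p_raw * m, 1)
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out[, c("feature", "condition_a", "condition_b", "mean_diff",
          "p_raw", "p_adj", "significant", "degenerate")]
}

#' Normalize condition means to the control condition
#'
#' Divides every (condition, feature, source) mean by the control mean of
#' the same feature and source, reproducing the normalized-to-control
#' comparison layout.  Ratios with a zero control mean are `NA` and flagged.
#'
#' @param summary a [condition_summary()] result.
#' @param control control condition name (default "control").
#' @return data.frame `condition`, `feature`, `source`, `ratio`,
#'   `undefined`.
#' @export
normalize_to_control <- function(summary, control = "control") {
  if (!control %in% summary$condition)
    stop(sprintf("control condition '%s' not in summary", control), call. = FALSE)
  ctl <- summary[summary$condition == control, c("feature", "source", "mean")]
  names(ctl)[3L] <- "control_mean"
  out <- merge(summary, ctl, by = c("feature", "source"))
  out$undefined <- out$control_mean == 0
  out$ratio <- ifelse(out$undefined, NA_real_, out$mean / out$control_mean)
  out[order(out$condition, out$feature),
      c("condition", "feature", "source", "ratio", "undefined")]
}

#' Condition-comparison report table
#'
#' One row per feature: the ANOVA (F, p) pair and per-condition
#' "(mean +/- sd)" cells, annotated with `*` when the condition differs
#' significantly from control and `**` when the two non-control conditions
#' differ from each other (Bonferroni-corrected pairwise comparisons).
#'
#' @param summary a [condition_summary()] result (cane source).
#' @param anovas named list of [rm_anova_oneway()] results per feature.
#' @param pairwise named list of [bonferroni_pairwise()] tables per feature.
#' @param control control condition name.
#' @return data.frame, one row per feature.
#' @export
make_report <- function(summary, anovas = NULL, pairwise = NULL,
                        control = "control") {
  summary <- summary[summary$source == "cane", , drop = FALSE]
  feats <- intersect(FEATURE_NAMES, unique(summary$feature))
  conds <- unique(summary$condition)
  conds <- c(intersect(control, conds), setdiff(conds, control))
  rows <- lapply(feats, function(f) {
    r <- data.frame(feature = f, stringsAsFactors = FALSE)
    a <- anovas[[f]]
    r$anova_F_p <- if (is.null(a)) "" else sprintf("(%.1f, %s)", a$F,
      if (a$p < 0.001) "<0.001" else sprintf("%.3f", a$p))
    pw <- pairwise[[f]]
    for (cn in conds) {
      s <- summary[summary$feature == f & summary$condition == cn, ]
      star <- ""
      if (!is.null(pw) && cn != control) {
        vs_ctl <- pw[(pw$condition_a == control & pw$condition_b == cn) |
                       (pw$condition_b == control & pw$condition_a == cn), ]
        if (nrow(vs_ctl) && any(vs_ctl$significant)) star <- " *"
        others <- pw[pw$condition_a != control & pw$condition_b != control &
                       (pw$condition_a == cn | pw$condition_b == cn), ]
        if (nrow(others) && any(others$significant))
          star <- paste0(star, if (nzchar(star)) ", **" else " **")
      }
      r[[cn]] <- if (nrow(s)) sprintf("(%.1f ± %.1f)%s", s$mean, s$sd, star)
                 else ""
    }
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
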