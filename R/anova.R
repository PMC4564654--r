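#' Two-way repeated-measures ANOVA on trajectory records
#'
#' Analyses a condition x epoch fully within-subjects design with runs as
#' subjects: omnibus main effects and interaction (via [stats::aov()] with
#' the appropriate error strata, uncorrected degrees of freedom), simple
#' main effects of condition at every epoch, and Bonferroni-protected
#' pairwise comparisons between conditions at every epoch.
#'
#' Simple main effects use the pooled within-subject error convention: the
#' subject x condition and subject x condition x epoch error sums of
#' squares are pooled, so with `s` subjects, `k` conditions and `m` epochs
#' the error degrees of freedom are `(s-1)(k-1)m`.
#'
#' Pairwise comparisons are paired t tests across runs at each epoch,
#' declared significant below the Bonferroni-adjusted level
#' `alpha / (k * (k - 1) / 2)`. A degenerate zero-variance difference is
#' declared significant when its mean is non-zero and non-significant when
#' the two conditions are identical.
#'
#' @param records trajectory records data.frame (or a `tonal_experiment`)
#'   with columns `run_id`, `epoch`, `condition` and the dependent
#'   variable. The design must be balanced: every run must have every
#'   condition x epoch cell exactly once.
#' @param dv dependent variable: `"percent_correct"` or `"activation"`.
#' @param alpha familywise significance level (default 0.05).
#' @return An object of class `rm_anova_report`: list with `omnibus`
#'   (effect, df1, df2, F, p), `simple` (per-epoch condition F tests on the
#'   pooled error), `pairwise` (per-epoch paired comparisons with
#'   `mean_diff`, `t`, `p`, `significant`), `pooled_error` (SS, df), and
#'   the design dimensions.
#' @export
rm_anova <- function(records, dv = c("percent_correct", "activation"),
                     alpha = 0.05) {
  dv <- match.arg(dv)
  if (inherits(records, "tonal_experiment")) records <- records$trajectories
  cond_chr <- as.character(records$condition)
  cond_levels <- if (is.factor(records$condition)) {
    levels(records$condition)
  } else {
    unique(cond_chr)  # order of first appearance, not alphabetical
  }
  d <- data.frame(run = factor(records$run_id),
                  cond = factor(cond_chr, levels = cond_levels),
                  ep = factor(records$epoch),
                  y = records[[dv]])
  s <- nlevels(d$run); k <- nlevels(d$cond); m <- nlevels(d$ep)

  tab <- table(d$run, d$cond, d$ep)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    stop(sprintf(
      "unbalanced design: %d run x condition x epoch cells missing or duplicated (first: run %s, condition %s, epoch %s)",
      nrow(bad), dimnames(tab)[[1]][bad[1, 1]],
      dimnames(tab)[[2]][bad[1, 2]], dimnames(tab)[[3]][bad[1, 3]]),
      call. = FALSE)
  }

  fit <- stats::aov(y ~ cond * ep + Error(run / (cond * ep)), data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tb <- sm[[paste0("Error: ", stratum)]][[1]]
    i <- match(term, trimws(rownames(tb)))
    r <- match("Residuals", trimws(rownames(tb)))
    c(df1 = tb[i, "Df"], df2 = tb[r, "Df"],
      F = tb[i, "F value"], p = tb[i, "Pr(>F)"],
      ss_err = tb[r, "Sum Sq"])
  }
  e_cond <- pull("run:cond", "cond")
  e_ep <- pull("run:ep", "ep")
  e_int <- pull("run:cond:ep", "cond:ep")

  omnibus <- data.frame(
    effect = c("condition", "epoch", "condition:epoch"),
    df1 = c(e_cond["df1"], e_ep["df1"], e_int["df1"]),
    df2 = c(e_cond["df2"], e_ep["df2"], e_int["df2"]),
    F = c(e_cond["F"], e_ep["F"], e_int["F"]),
    p = c(e_cond["p"], e_ep["p"], e_int["p"]),
    row.names = NULL)

  # pooled error for simple main effects of condition at each epoch
  ss_pooled <- e_cond["ss_err"] + e_int["ss_err"]
  df_pooled <- e_cond["df2"] + e_int["df2"]
  ms_pooled <- ss_pooled / df_pooled

  cell <- aggregate(y ~ cond + ep, data = d, FUN = mean)
  simple <- do.call(rbind, lapply(levels(d$ep), function(j) {
    mj <- cell$y[cell$ep == j]
    ss <- s * sum((mj - mean(mj))^2)
    Fj <- (ss / (k - 1)) / ms_pooled
    data.frame(epoch = as.numeric(j), df1 = k - 1, df2 = unname(df_pooled),
               F = unname(Fj),
               p = unname(pf(Fj, k - 1, df_pooled, lower.tail = FALSE)))
  }))

  pairs <- utils::combn(levels(d$cond), 2, simplify = FALSE)
  alpha_adj <- alpha / length(pairs)
  pairwise <- do.call(rbind, lapply(levels(d$ep), function(j) {
    do.call(rbind, lapply(pairs, function(pr) {
      ya <- d$y[d$cond == pr[1] & d$ep == j][order(d$run[d$cond == pr[1] & d$ep == j])]
      yb <- d$y[d$cond == pr[2] & d$ep == j][order(d$run[d$cond == pr[2] & d$ep == j])]
      diffs <- ya - yb
      if (sd(diffs) == 0) {
        tstat <- if (mean(diffs) == 0) 0 else Inf * sign(mean(diffs))
        pval <- if (mean(diffs) == 0) 1 else 0
      } else {
        tstat <- mean(diffs) / (sd(diffs) / sqrt(length(diffs)))
        pval <- 2 * pt(abs(tstat), df = length(diffs) - 1, lower.tail = FALSE)
      }
      data.frame(epoch = as.numeric(j),
                 pair = paste(pr[1], "vs", pr[2]),
                 mean_diff = mean(diffs), t = tstat, p = pval,
                 significant = pval < alpha_adj,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(simple) <- rownames(pairwise) <- NULL

  structure(
    list(dv = dv, omnibus = omnibus, simple = simple, pairwise = pairwise,
         pooled_error = c(ss = unname(ss_pooled), df = unname(df_pooled)),
         n_subjects = s, n_conditions = k, n_epochs = m,
         alpha = alpha, alpha_adjusted = alpha_adj),
    class = "rm_anova_report")
}

#' @export
print.rm_anova_report <- function(x, ...) {
  cat(sprintf("<rm_anova_report> dv = %s, %d subjects x %d conditions x %d epochs\n",
              x$dv, x$n_subjects, x$n_conditions, x$n_epochs))
  o <- x$omnibus
  for (i in seq_len(nrow(o))) {
    cat(sprintf("  %-16s F(%d,%d) = %.2f, p = %.3g\n",
                o$effect[i], o$df1[i], o$df2[i], o$F[i], o$p[i]))
  }
  cat(sprintf("  pairwise alpha (Bonferroni): %.4f\n", x$alpha_adjusted))
  invisible(x)
}

#' First checkpoints of scale and of harmony sensitivity
#'
#' Operationalises the ordering question "is scale sensitivity acquired
#' before harmony sensitivity?" on a trajectory analysis:
#' *scale onset* is the first epoch at which both in-scale conditions
#' significantly exceed the out-of-scale condition in the pairwise
#' comparisons; *harmony onset* is the first epoch at which the
#' regular-harmony condition significantly exceeds the irregular in-scale
#' condition. Significance comes from the report's Bonferroni-protected
#' pairwise tests; direction from the sign of the mean difference.
#'
#' @param report an [rm_anova()] report.
#' @return List with `scale_onset` and `harmony_onset` (epoch numbers;
#'   `Inf` if the sensitivity never becomes significant).
#' @export
sensitivity_onsets <- function(report) {
  stopifnot(inherits(report, "rm_anova_report"))
  pw <- report$pairwise
  sig_pos <- function(pair_name) {
    rows <- pw[pw$pair == pair_name & pw$significant & pw$mean_diff > 0, ]
    if (nrow(rows) == 0L) Inf else min(rows$epoch)
  }
  reg_oos <- sig_pos("in_scale_regular vs out_of_scale_irregular")
  irr_oos <- sig_pos("in_scale_irregular vs out_of_scale_irregular")
  reg_irr <- sig_pos("in_scale_regular vs in_scale_irregular")
  # scale sensitivity requires both in-scale conditions to beat out-of-scale
  # from the same checkpoint onwards
  both <- function(p1, p2) {
    eps <- sort(unique(pw$epoch))
    ok <- vapply(eps, function(e) {
      r1 <- pw[pw$pair == p1 & pw$epoch == e, ]
      r2 <- pw[pw$pair == p2 & pw$epoch == e, ]
      nrow(r1) == 1L && nrow(r2) == 1L &&
        r1$significant && r1$mean_diff > 0 &&
        r2$significant && r2$mean_diff > 0
    }, logical(1))
    if (any(ok)) eps[which(ok)[1L]] else Inf
  }
  list(scale_onset = both("in_scale_regular vs out_of_scale_irregular",
                          "in_scale_irregular vs out_of_scale_irregular"),
       harmony_onset = reg_irr,
       first_regular_vs_out_of_scale = reg_oos,
       first_irregular_vs_out_of_scale = irr_oos)
}
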