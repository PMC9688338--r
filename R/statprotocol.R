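#' Assemble a metric table
#'
#' Long-format container for per-subject, per-frequency, per-state network
#' metrics (characteristic path length, clustering, SWP components, ...).
#'
#' @param subject,frequency,state,value equal-length vectors.
#' @return Data frame of class `metric_table`.
#' @export
metric_table <- function(subject, frequency, state, value) {
  df <- data.frame(subject = subject, frequency = frequency,
                   state = state, value = value)
  if (!all(df$state %in% c("GSW", "RS")))
    stop("state must be GSW or RS")
  class(df) <- c("metric_table", "data.frame")
  df
}

#' Paired GSW vs RS comparison at one frequency
#'
#' Normality of the per-subject differences (GSW - RS) is assessed with the
#' Shapiro-Wilk test at alpha = 0.05; normal differences go to a two-sided
#' paired t-test, non-normal ones to the Wilcoxon signed-rank test (normal
#' approximation with continuity correction, zero differences dropped).
#' The p-value is Bonferroni-adjusted for the `n_comparisons` frequencies
#' analyzed in the protocol (12 by default).  All differences equal to zero
#' is degenerate: statistic 0, p = 1.
#'
#' @param values a `metric_table` (or data frame with subject, frequency,
#'   state, value).
#' @param frequency the frequency (Hz) to test.
#' @param n_comparisons Bonferroni family size.
#' @param shapiro_alpha gate level for the normality test.
#' @return List of class `stat_report`: test name, statistic, df (t branch),
#'   p, p_adjusted, effect direction, confidence interval (t branch),
#'   shapiro_p, mean_difference.
#' @export
paired_state_comparison <- function(values, frequency,
                                    n_comparisons = 12L,
                                    shapiro_alpha = 0.05) {
  df <- values[values$frequency == frequency, ]
  w <- stats::reshape(df[, c("subject", "state", "value")],
                      direction = "wide", idvar = "subject",
                      timevar = "state")
  if (!all(c("value.GSW", "value.RS") %in% names(w)) ||
      anyNA(w$value.GSW) || anyNA(w$value.RS))
    stop("both states required for every subject at frequency ", frequency)
  if (nrow(w) < 3L) stop("need at least 3 subjects")
  d <- w$value.GSW - w$value.RS
  direction <- sign(mean(d))
  if (all(d == 0)) {
    rep <- list(test = "degenerate", statistic = 0, df = NA_real_, p = 1,
                p_adjusted = 1, direction = 0, conf_int = c(NA_real_, NA_real_),
                shapiro_p = NA_real_, mean_difference = 0,
                frequency = frequency)
    class(rep) <- "stat_report"
    return(rep)
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= shapiro_alpha) {
    tt <- stats::t.test(d)
    rep <- list(test = "paired t", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                conf_int = as.numeric(tt$conf.int))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                              correct = TRUE))
    rep <- list(test = "wilcoxon signed-rank",
                statistic = unname(wt$statistic), df = NA_real_,
                p = wt$p.value, conf_int = c(NA_real_, NA_real_))
  }
  rep$p_adjusted <- min(1, n_comparisons * rep$p)
  rep$direction <- direction
  rep$shapiro_p <- sw$p.value
  rep$mean_difference <- mean(d)
  rep$frequency <- frequency
  class(rep) <- "stat_report"
  rep
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf("<stat_report> %s: statistic = %.4g, p = %.4g (adjusted %.4g)\n",
              x$test, x$statistic, x$p, x$p_adjusted))
  invisible(x)
}

#' Two-factor repeated-measures ANOVA (state x frequency)
#'
#' Fits the within-subject 2 (state) x k (frequency) design, reporting both
#' main effects and the interaction with partial eta squared.  Sphericity of
#' the frequency-involved effects is checked with Mauchly's test; when its p
#' falls below 0.05 the Greenhouse-Geisser-corrected p-value is the one
#' reported as `p_applied` for that effect.
#'
#' @param values a `metric_table` with a complete subject x frequency x
#'   state crossing.
#' @return List of class `rm_anova_report` with one row per effect in
#'   `$effects` (F, df, p, GG epsilon, Mauchly p, p_applied, partial eta2).
#' @export
rm_anova_state_frequency <- function(values) {
  freqs <- sort(unique(values$frequency))
  states <- c("GSW", "RS")
  subjects <- sort(unique(values$subject))
  key <- with(values, paste(subject, frequency, state))
  want <- expand.grid(subject = subjects, frequency = freqs, state = states)
  missing_cells <- with(want, paste(subject, frequency, state))
  missing_cells <- setdiff(missing_cells, key)
  if (length(missing_cells) > 0)
    stop("incomplete design; missing cells: ",
         paste(utils::head(missing_cells, 5L), collapse = ", "),
         if (length(missing_cells) > 5L) " ..." else "")
  cols <- expand.grid(state = states, frequency = freqs,
                      stringsAsFactors = FALSE)
  Y <- matrix(NA_real_, nrow = length(subjects), ncol = nrow(cols))
  for (j in seq_len(nrow(cols))) {
    sel <- values$frequency == cols$frequency[j] & values$state == cols$state[j]
    sub <- values[sel, ]
    Y[, j] <- sub$value[match(subjects, sub$subject)]
  }
  idata <- data.frame(state = factor(cols$state),
                      frequency = factor(cols$frequency))
  mlm <- stats::lm(Y ~ 1)
  av <- car::Anova(mlm, idata = idata, idesign = ~ state * frequency,
                   type = "III")
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  sph <- s$sphericity.tests
  adj <- s$pval.adjustments
  effects <- c("state", "frequency", "state:frequency")
  out <- data.frame(effect = effects, F = NA_real_, df1 = NA_real_,
                    df2 = NA_real_, p = NA_real_, gg_eps = NA_real_,
                    p_gg = NA_real_, mauchly_p = NA_real_,
                    p_applied = NA_real_, partial_eta2 = NA_real_)
  for (i in seq_along(effects)) {
    e <- effects[i]
    out$F[i] <- ut[e, "F value"]
    out$df1[i] <- ut[e, "num Df"]
    out$df2[i] <- ut[e, "den Df"]
    out$p[i] <- ut[e, "Pr(>F)"]
    out$partial_eta2[i] <- ut[e, "Sum Sq"] / (ut[e, "Sum Sq"] + ut[e, "Error SS"])
    if (!is.null(sph) && e %in% rownames(sph)) {
      out$mauchly_p[i] <- sph[e, "p-value"]
      out$gg_eps[i] <- adj[e, "GG eps"]
      out$p_gg[i] <- adj[e, "Pr(>F[GG])"]
      out$p_applied[i] <- if (out$mauchly_p[i] < 0.05) out$p_gg[i] else out$p[i]
    } else {
      out$p_applied[i] <- out$p[i]
    }
  }
  structure(list(effects = out, n_subjects = length(subjects),
                 n_frequencies = length(freqs)),
            class = "rm_anova_report")
}

#' @export
print.rm_anova_report <- function(x, ...) {
  cat(sprintf("<rm_anova_report> %d subjects, 2 states x %d frequencies\n",
              x$n_subjects, x$n_frequencies))
  print(x$effects, row.names = FALSE, digits = 4)
  invisible(x)
}
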