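## Cohort-level statistics: one-way linear models with estimated marginal
## means and pairwise contrasts, Welch t-tests, Pearson correlations of
## each parameter against log10 tumor count, and boxplot summaries.

#' One-way group model with estimated marginal means and contrasts
#'
#' Fits `parameter ~ group` by ordinary least squares, extracts estimated
#' marginal means with confidence intervals (which equal the group sample
#' means in this one-factor design), and performs post hoc pairwise
#' comparisons with a Tukey adjustment by default. Rows missing the
#' parameter are dropped for that parameter only.
#'
#' @param table data.frame with columns `group` and `parameter`.
#' @param parameter name of the response column.
#' @param adjust p-value adjustment for the pairwise contrasts:
#'   `"tukey"` (default), `"bonferroni"` or `"none"`.
#' @param conf_level confidence level for intervals.
#' @return List of class `group_comparison` with elements `parameter`,
#'   `emmeans` (group, emmean, ci_lo, ci_hi), `contrasts` (contrast,
#'   estimate, ci_lo, ci_hi, p_adj), `adjust` and `n_used`.
#' @export
fit_group_model <- function(table, parameter,
                            adjust = c("tukey", "bonferroni", "none"),
                            conf_level = 0.95) {
  adjust <- match.arg(adjust)
  if (!parameter %in% names(table)) stop("unknown parameter: ", parameter)
  d <- data.frame(group = factor(table$group), y = table[[parameter]])
  d <- d[!is.na(d$y) & !is.na(d$group), , drop = FALSE]
  counts <- table(d$group)
  empty <- names(counts)[counts == 0]
  if (length(empty))
    stop("group entirely missing for ", parameter, ": ",
         paste(empty, collapse = ", "))
  if (nlevels(droplevels(d$group)) < 2)
    stop("need at least 2 groups with observations")
  d$group <- droplevels(d$group)
  fit <- lm(y ~ group, data = d)

  if (stats::df.residual(fit) < 1) {
    gm <- tapply(d$y, d$group, mean)
    emm <- data.frame(group = names(gm), emmean = as.numeric(gm),
                      ci_lo = NA_real_, ci_hi = NA_real_)
    cn <- utils::combn(names(gm), 2)
    ctr <- data.frame(
      contrast = paste(cn[1, ], "-", cn[2, ]),
      estimate = gm[cn[1, ]] - gm[cn[2, ]],
      ci_lo = NA_real_, ci_hi = NA_real_, p_adj = NA_real_)
    rownames(ctr) <- NULL
  } else {
    # an all-identical response fits perfectly; the lm notice is expected
    em <- suppressWarnings(emmeans::emmeans(fit, "group"))
    es <- as.data.frame(stats::confint(em, level = conf_level))
    emm <- data.frame(group = as.character(es$group), emmean = es$emmean,
                      ci_lo = es$lower.CL, ci_hi = es$upper.CL)
    pr <- emmeans::contrast(em, "pairwise", adjust = adjust)
    ps <- as.data.frame(pr)
    ci <- as.data.frame(stats::confint(pr, level = conf_level))
    ctr <- data.frame(contrast = as.character(ps$contrast),
                      estimate = ps$estimate,
                      ci_lo = ci$lower.CL, ci_hi = ci$upper.CL,
                      p_adj = pmin(1, ps$p.value))
    if (suppressWarnings(summary(fit)$sigma) < 1e-12) {
      # zero residual variance: a zero contrast carries no evidence (p = 1),
      # a nonzero one is exact (p -> 0)
      ctr$p_adj <- ifelse(abs(ctr$estimate) <= 1e-12, 1, 0)
    }
  }
  structure(list(parameter = parameter, emmeans = emm, contrasts = ctr,
                 adjust = adjust, n_used = nrow(d)),
            class = "group_comparison")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test. Swapping the samples negates t and preserves p.
#' If both samples are (jointly) constant the statistic is undefined and an
#' error is raised.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 observations")
  res <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                  error = function(e)
                    stop("degenerate samples (zero variance): ",
                         conditionMessage(e), call. = FALSE))
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Pearson correlation of a parameter with log10 tumor count
#'
#' Correlates a study-table column against log10-transformed tumor counts,
#' with a two-sided p-value from the t-distribution on n - 2 degrees of
#' freedom. Rows with a missing parameter are dropped pairwise. Controls
#' with zero tumors are excluded by default (log10 of 0 is undefined); the
#' `"log1p"` policy instead uses `log10(count + 1)` and keeps them.
#'
#' @param table data.frame with columns `tumor_count` and `parameter`.
#' @param parameter name of the parameter column.
#' @param zero_count_policy `"exclude"` (default) or `"log1p"`.
#' @return List of class `correlation_result` with `parameter`,
#'   `pearson_r`, `p_value`, `n_pairs`.
#' @export
correlate_with_tumor_count <- function(table, parameter,
                                       zero_count_policy = c("exclude",
                                                             "log1p")) {
  zero_count_policy <- match.arg(zero_count_policy)
  if (!parameter %in% names(table)) stop("unknown parameter: ", parameter)
  cnt <- table$tumor_count
  y <- table[[parameter]]
  if (zero_count_policy == "exclude") {
    keep <- !is.na(cnt) & cnt > 0 & !is.na(y)
    lx <- log10(cnt[keep])
  } else {
    keep <- !is.na(cnt) & !is.na(y)
    lx <- log10(cnt[keep] + 1)
  }
  yy <- y[keep]
  if (length(yy) < 3) stop("need at least 3 complete pairs")
  if (sd(lx) == 0 || sd(yy) == 0) stop("undefined correlation: zero variance")
  ct <- stats::cor.test(lx, yy, method = "pearson")
  structure(list(parameter = parameter, pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n_pairs = length(yy)),
            class = "correlation_result")
}

#' Boxplot summary (median, IQR, 1.5*IQR whiskers, outliers)
#'
#' Quartiles use linearly interpolated quantiles (type 7), the same
#' convention as the ventilation-heterogeneity IQR. Whiskers sit at the
#' most extreme data points within 1.5 IQR of the box.
#'
#' @param values numeric vector, length >= 1.
#' @return List with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[inside]), whisker_hi = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Run the full statistics battery over a study table
#'
#' Per parameter: the one-way group model with marginal means and pairwise
#' contrasts, the boxplot summaries per group, and the Pearson correlation
#' against log10 tumor count.
#'
#' @param table a study table (one row per animal).
#' @param parameters columns to analyze; defaults to all XV and mechanics
#'   parameters present.
#' @param adjust contrast adjustment method.
#' @param zero_count_policy see [correlate_with_tumor_count()].
#' @return List with data.frames `comparisons`, `correlations`,
#'   `summaries`.
#' @export
run_cohort_stats <- function(table, parameters = NULL,
                             adjust = "tukey",
                             zero_count_policy = "exclude") {
  default_pars <- c("msv", "vt_ml", "vdp_pct", "nvdp_pct", "vh", "vh_ss",
                    "vh_ls", "mean_ct_gray", .mech_params)
  if (is.null(parameters))
    parameters <- intersect(default_pars, names(table))
  comp <- list(); corr <- list(); summ <- list()
  for (p in parameters) {
    gc <- tryCatch(fit_group_model(table, p, adjust = adjust),
                   error = function(e) NULL)
    if (!is.null(gc)) {
      ctr <- gc$contrasts
      comp[[p]] <- rbind(
        data.frame(parameter = p, group = gc$emmeans$group,
                   emmean = gc$emmeans$emmean, ci_lo = gc$emmeans$ci_lo,
                   ci_hi = gc$emmeans$ci_hi, contrast = NA_character_,
                   estimate = NA_real_, p_adj = NA_real_, method = gc$adjust),
        data.frame(parameter = p, group = NA_character_, emmean = NA_real_,
                   ci_lo = ctr$ci_lo, ci_hi = ctr$ci_hi,
                   contrast = ctr$contrast, estimate = ctr$estimate,
                   p_adj = ctr$p_adj, method = gc$adjust))
    }
    cr <- tryCatch(correlate_with_tumor_count(table, p, zero_count_policy),
                   error = function(e) NULL)
    if (!is.null(cr))
      corr[[p]] <- data.frame(parameter = p, r = cr$pearson_r,
                              p = cr$p_value, n = cr$n_pairs)
    for (g in unique(table$group)) {
      v <- table[[p]][table$group == g]
      if (all(is.na(v))) next
      bs <- boxplot_summary(v)
      summ[[paste(p, g)]] <- data.frame(
        parameter = p, group = g, median = bs$median, q1 = bs$q1,
        q3 = bs$q3, whisker_lo = bs$whisker_lo, whisker_hi = bs$whisker_hi,
        n_outliers = length(bs$outliers))
    }
  }
  list(comparisons = do.call(rbind, c(comp, list(make.row.names = FALSE))),
       correlations = do.call(rbind, c(corr, list(make.row.names = FALSE))),
       summaries = do.call(rbind, c(summ, list(make.row.names = FALSE))))
}
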