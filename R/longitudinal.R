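#' Fit the longitudinal linear mixed-effects model for one ROI
#'
#' Fits, by REML,
#' `value ~ group * timepoint_years + age + sex + icv + (1 | subject_id)`
#' on the rows of `table` belonging to one ROI and measure, with treatment
#' contrasts referenced to the `HC` group. The `group` main effect tests
#' baseline (timepoint 0) differences; the `group:timepoint_years`
#' interaction tests group differences in the rate of change. Omnibus F
#' tests are Type-III with Satterthwaite denominator degrees of freedom.
#' Rows with missing values in any model variable are dropped (with a
#' message); singular random-effect fits are flagged, not hidden.
#'
#' @param table Long-format cohort table with columns `subject_id`, `group`
#'   (levels HC, CHR-NP, CHR-P), `timepoint_years`, `roi`, `measure_name`,
#'   `value`, `age`, `sex`, `icv`.
#' @param roi ROI name to model.
#' @param measure Measure name to model (default `"ifw"`).
#' @param covariates Character vector of covariate columns to adjust for.
#' @return An `lme_fit`: list with `model` (the `lmerModLmerTest` object),
#'   `tests` (data.frame: effect, df_num, df_den, F, p for `group` and
#'   `group:time`), `roi`, `measure`, `n_obs`, `n_dropped`, `singular`.
#' @export
fit_lme <- function(table, roi, measure = "ifw",
                    covariates = c("age", "sex", "icv")) {
  need <- c("subject_id", "group", "timepoint_years", "roi", "measure_name",
            "value", covariates)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table lacks column(s): ", paste(miss, collapse = ", "))
  d <- table[table$roi == roi & table$measure_name == measure, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for roi '", roi, "' and measure '", measure, "'")

  used <- c("subject_id", "group", "timepoint_years", "value", covariates)
  cc <- stats::complete.cases(d[used])
  n_dropped <- sum(!cc)
  if (n_dropped > 0)
    message(sprintf("fit_lme: dropped %d row(s) with missing values", n_dropped))
  d <- d[cc, , drop = FALSE]

  d$group <- factor(d$group, levels = c("HC", "CHR-NP", "CHR-P"))
  if (any(is.na(d$group))) stop("group must be one of HC, CHR-NP, CHR-P")
  # z-score numeric covariates (e.g. ICV is ~1.5e6 mm^3): identical group and
  # time tests, better-conditioned model matrix
  for (cv in covariates)
    if (is.numeric(d[[cv]]) && stats::sd(d[[cv]]) > 0)
      d[[cv]] <- as.numeric(scale(d[[cv]]))
  cnt <- base::table(d$group[!duplicated(d$subject_id)])
  if (any(cnt < 3))
    stop("need at least 3 subjects per group; got ",
         paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "))
  if (length(unique(d$timepoint_years)) < 2)
    stop("only one distinct timepoint; time and interaction effects are inestimable")

  fml <- stats::as.formula(paste(
    "value ~ group * timepoint_years +",
    paste(covariates, collapse = " + "), "+ (1 | subject_id)"))
  model <- lmerTest::lmer(fml, data = d, REML = TRUE,
                          control = lme4::lmerControl(calc.derivs = FALSE))
  singular <- lme4::isSingular(model)
  if (singular)
    warning("singular random-effect fit for roi ", roi, "; results flagged")

  # lmerTest prints an advisory NOTE about main effects in the presence of
  # the interaction; here the main effect is the intended baseline contrast
  a <- suppressMessages(stats::anova(model, type = 3))
  pick <- c(group = "group", interaction = "group:timepoint_years")
  tests <- data.frame(
    effect = names(pick),
    df_num = a[pick, "NumDF"], df_den = a[pick, "DenDF"],
    F = a[pick, "F value"], p = a[pick, "Pr(>F)"],
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(model = model, tests = tests, roi = roi, measure = measure,
                 n_obs = nrow(d), n_dropped = n_dropped, singular = singular),
            class = "lme_fit")
}

#' Tukey-adjusted pairwise group contrasts
#'
#' For the `group` effect: pairwise differences of estimated marginal means
#' at `timepoint_years = 0` (baseline). For the `interaction` effect:
#' pairwise differences of the estimated marginal slopes over time. Both
#' use Satterthwaite degrees of freedom and adjust the 3-comparison family
#' by the studentized-range (Tukey) method. Contrasts are reported as
#' CHR-NP vs HC, CHR-P vs HC and CHR-P vs CHR-NP.
#'
#' @param fit An `lme_fit` from [fit_lme()].
#' @param effect `"group"` (baseline means) or `"interaction"` (slopes).
#' @return data.frame with `contrast`, `estimate`, `se`, `df`, `t`,
#'   `p_adjusted`.
#' @export
posthoc_pairwise <- function(fit, effect = c("group", "interaction")) {
  stopifnot(inherits(fit, "lme_fit"))
  effect <- match.arg(effect)
  if (effect == "group") {
    emm <- emmeans::emmeans(fit$model, "group",
                            at = list(timepoint_years = 0),
                            lmer.df = "satterthwaite")
  } else {
    emm <- emmeans::emtrends(fit$model, "group", var = "timepoint_years",
                             lmer.df = "satterthwaite")
  }
  prs <- as.data.frame(emmeans::contrast(emm, "revpairwise", adjust = "tukey"))
  data.frame(contrast = gsub("[()]", "", prs$contrast),
             estimate = prs$estimate, se = prs$SE, df = prs$df,
             t = prs$t.ratio, p_adjusted = prs$p.value,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment across a family of tests
#' (typically the eight cortical ROIs).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param alpha Rejection level applied to the adjusted values.
#' @return List with `p_adjusted` (same order as input) and `reject`
#'   (logical flags at `alpha`).
#' @export
fdr_adjust <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must be finite and within [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adjusted = adj, reject = adj <= alpha)
}

#' Run the full per-ROI longitudinal analysis
#'
#' Fits the mixed model in every ROI present in the table, collects the
#' omnibus group and interaction tests, adjusts each family of p-values
#' across ROIs by Benjamini-Hochberg FDR, and computes Tukey post hoc
#' contrasts for ROIs whose FDR-adjusted omnibus test is significant
#' (mirroring the convention of reporting post hoc tests only where the
#' omnibus effect survives correction).
#'
#' @param table Long-format cohort table (see [fit_lme()]).
#' @param measure Measure name (default `"ifw"`).
#' @param alpha Significance level for the FDR-adjusted omnibus tests.
#' @param posthoc_all Compute post hoc contrasts for every ROI regardless
#'   of omnibus significance (default `FALSE`).
#' @return A `longitudinal_result`: list with `effects` (data.frame: roi,
#'   effect, df_num, df_den, F, p, p_fdr, significant), `posthoc`
#'   (data.frame of contrasts, possibly empty), `fits` (named list of
#'   `lme_fit`s), `alpha`.
#' @export
longitudinal_analysis <- function(table, measure = "ifw", alpha = 0.05,
                                  posthoc_all = FALSE) {
  rois <- intersect(lobe_names(), unique(table$roi))
  if (length(rois) == 0) rois <- unique(table$roi)
  fits <- lapply(rois, function(r) fit_lme(table, r, measure))
  names(fits) <- rois

  eff <- do.call(rbind, lapply(rois, function(r)
    cbind(roi = r, fits[[r]]$tests, stringsAsFactors = FALSE)))
  eff$p_fdr <- NA_real_
  eff$significant <- FALSE
  for (e in unique(eff$effect)) {
    sel <- eff$effect == e
    adj <- fdr_adjust(eff$p[sel], alpha)
    eff$p_fdr[sel] <- adj$p_adjusted
    eff$significant[sel] <- adj$reject
  }

  ph <- list()
  for (k in seq_len(nrow(eff))) {
    if (!(eff$significant[k] || posthoc_all)) next
    pw <- posthoc_pairwise(fits[[eff$roi[k]]],
                           if (eff$effect[k] == "group") "group" else "interaction")
    ph[[length(ph) + 1]] <- cbind(roi = eff$roi[k], effect = eff$effect[k],
                                  pw, stringsAsFactors = FALSE)
  }
  posthoc <- if (length(ph)) do.call(rbind, ph)
             else data.frame(roi = character(0), effect = character(0),
                             contrast = character(0), estimate = numeric(0),
                             se = numeric(0), df = numeric(0), t = numeric(0),
                             p_adjusted = numeric(0))
  structure(list(effects = eff, posthoc = posthoc, fits = fits,
                 alpha = alpha, measure = measure),
            class = "longitudinal_result")
}

#' @exportS3Method base::print
print.longitudinal_result <- function(x, ...) {
  cat("Longitudinal LME analysis of '", x$measure, "' over ",
      length(x$fits), " ROIs (alpha = ", x$alpha, ", FDR-adjusted)\n\n", sep = "")
  print(x$effects, digits = 4)
  if (nrow(x$posthoc)) {
    cat("\nTukey post hoc contrasts (significant omnibus effects):\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Per-subject rates of change
#'
#' Ordinary least-squares slope of each subject's measurements against time,
#' for subjects with at least two distinct timepoints; others are excluded
#' with a message.
#'
#' @param table Long-format cohort table.
#' @param measure Measure name.
#' @param roi ROI name.
#' @return data.frame with `subject_id`, `roi`, `measure`, `slope`
#'   (units/year), `n_timepoints`.
#' @export
subject_slopes <- function(table, measure = "ifw", roi) {
  d <- table[table$roi == roi & table$measure_name == measure &
               is.finite(table$value), , drop = FALSE]
  out <- lapply(split(d, d$subject_id), function(s) {
    if (length(unique(s$timepoint_years)) < 2) return(NULL)
    fit <- stats::lm(value ~ timepoint_years, data = s)
    data.frame(subject_id = s$subject_id[1], roi = roi, measure = measure,
               slope = unname(stats::coef(fit)["timepoint_years"]),
               n_timepoints = nrow(s), stringsAsFactors = FALSE)
  })
  n_excl <- sum(vapply(out, is.null, logical(1)))
  if (n_excl > 0)
    message(sprintf("subject_slopes: excluded %d subject(s) with < 2 distinct timepoints",
                    n_excl))
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(subject_id = character(0), roi = character(0),
                      measure = character(0), slope = numeric(0),
                      n_timepoints = integer(0))
  rownames(res) <- NULL
  res
}

#' Spearman rank correlation
#'
#' Tie-corrected rank correlation with a two-sided p-value (large-sample t
#' approximation, which accommodates ties). Pairs with missing values are
#' dropped.
#'
#' @param x,y Numeric vectors of equal length; at least 4 complete pairs.
#' @return List with `rho`, `p` and `n` (complete pairs used).
#' @export
spearman_assoc <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Compare two independent correlations by Fisher's z
#'
#' Tests whether two correlation coefficients observed in independent
#' groups differ: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`
#' with a two-sided normal p-value.
#'
#' @param r1,r2 Correlations, strictly inside (-1, 1).
#' @param n1,n2 Group sizes, at least 4 each.
#' @return List with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 (Fisher transform undefined at +/-1)")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each group")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Write longitudinal results as TSV tables plus a JSON bundle
#'
#' @param result A `longitudinal_result`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_longitudinal <- function(result, out_dir) {
  stopifnot(inherits(result, "longitudinal_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(out_dir, "effects.tsv")
  utils::write.table(result$effects, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- file.path(out_dir, "posthoc.tsv")
  utils::write.table(result$posthoc, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p3 <- file.path(out_dir, "results.json")
  jsonlite::write_json(list(measure = result$measure, alpha = result$alpha,
                            effects = result$effects, posthoc = result$posthoc),
                       p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
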