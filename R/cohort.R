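#' Design of a synthetic three-group longitudinal cohort
#'
#' Describes a healthy-control (HC) group and two clinical-high-risk groups
#' (CHR-NP, non-converters; CHR-P, converters) followed over a common
#' timepoint schedule, with group-specific baseline offsets and annual
#' slopes, subject-level random intercepts, optional covariate effects and
#' Gaussian residual noise. Defaults emulate an iFW-like cortical measure:
#' both CHR groups start slightly above HC and the CHR-P group accumulates
#' free water faster over time.
#'
#' @param n_per_group Named counts for `HC`, `CHR-NP`, `CHR-P`
#'   (default 96/127/33).
#' @param baseline_mean Grand baseline mean of the measure (default 0.15).
#' @param baseline_offsets Named per-group additive offsets at baseline.
#' @param slope Named per-group slopes (measure units / year).
#' @param covariate_effects Named effects for `age` (per year), `sex`
#'   (male vs female) and `icv` (per mm^3); default all zero.
#' @param residual_sd Residual (within-subject) standard deviation.
#' @param ranef_sd Random-intercept standard deviation across subjects.
#' @param schedule Timepoints in years from baseline; must start at 0.
#' @param rois ROIs to simulate (independent realizations per ROI).
#' @param seed Integer seed.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_per_group = c("HC" = 96, "CHR-NP" = 127, "CHR-P" = 33),
                          baseline_mean = 0.15,
                          baseline_offsets = c("HC" = 0, "CHR-NP" = 0.01, "CHR-P" = 0.01),
                          slope = c("HC" = 0, "CHR-NP" = 0.001, "CHR-P" = 0.005),
                          covariate_effects = c(age = 0, sex = 0, icv = 0),
                          residual_sd = 0.02, ranef_sd = 0.03,
                          schedule = c(0, 1, 2), rois = lobe_names(),
                          seed = 1L) {
  grp <- c("HC", "CHR-NP", "CHR-P")
  stopifnot(all(grp %in% names(n_per_group)), all(n_per_group > 0),
            all(grp %in% names(baseline_offsets)), all(grp %in% names(slope)),
            residual_sd >= 0, ranef_sd >= 0,
            length(schedule) >= 1, schedule[1] == 0)
  structure(list(n_per_group = n_per_group[grp], baseline_mean = baseline_mean,
                 baseline_offsets = baseline_offsets[grp], slope = slope[grp],
                 covariate_effects = covariate_effects,
                 residual_sd = residual_sd, ranef_sd = ranef_sd,
                 schedule = schedule, rois = rois, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Simulate a longitudinal ROI cohort with known effects
#'
#' Generates a tidy long table (one row per subject x timepoint x ROI) of
#' the form consumed by [fit_lme()]: columns `subject_id`, `group`,
#' `timepoint_years`, `roi`, `measure_name`, `value`, `age`, `sex`, `icv`.
#' Ages are uniform on 12-35 years (the cohort's inclusion window), sex is
#' Bernoulli(0.5) coded F/M, intracranial volume is log-normal around
#' 1.5e6 mm^3. The generating parameters are returned alongside the table
#' so tests never re-derive truth.
#'
#' @param design A [cohort_design()].
#' @param measure_name Measure label (default `"ifw"`).
#' @return List with `table` (data.frame) and `truth` (the design).
#' @export
simulate_cohort <- function(design = cohort_design(), measure_name = "ifw") {
  stopifnot(inherits(design, "cohort_design"))
  rng <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(rng)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", rng, envir = globalenv())
  })
  set.seed(design$seed)

  groups <- rep(names(design$n_per_group), design$n_per_group)
  n <- length(groups)
  subj <- sprintf("S%03d", seq_len(n))
  age <- stats::runif(n, 12, 35)
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "M", "F")
  icv <- stats::rlnorm(n, log(1.5e6), 0.07)
  b_subj <- stats::rnorm(n, 0, design$ranef_sd)

  ce <- design$covariate_effects
  rows <- vector("list", length(design$rois))
  for (r in seq_along(design$rois)) {
    roi <- design$rois[r]
    tab <- expand.grid(i = seq_len(n), timepoint_years = design$schedule,
                       KEEP.OUT.ATTRS = FALSE)
    i <- tab$i
    mu <- design$baseline_mean +
      design$baseline_offsets[groups[i]] +
      design$slope[groups[i]] * tab$timepoint_years +
      ce[["age"]] * age[i] + ce[["sex"]] * (sex[i] == "M") +
      ce[["icv"]] * icv[i] + b_subj[i]
    rows[[r]] <- data.frame(
      subject_id = subj[i], group = groups[i],
      timepoint_years = tab$timepoint_years, roi = roi,
      measure_name = measure_name,
      value = mu + stats::rnorm(length(i), 0, design$residual_sd),
      age = age[i], sex = sex[i], icv = icv[i],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$roi, tab$subject_id, tab$timepoint_years), ]
  rownames(tab) <- NULL
  list(table = tab, truth = design)
}

#' Write a simulated cohort as TSV plus truth JSON
#'
#' @param cohort Result of [simulate_cohort()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>_truth.json`.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, prefix) {
  tsv <- paste0(prefix, ".tsv")
  utils::write.table(cohort$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- paste0(prefix, "_truth.json")
  jsonlite::write_json(unclass(cohort$truth), js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
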