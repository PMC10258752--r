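#' Standardize a metric to mean 0, SD 1
#'
#' Regression effects are reported per one standard deviation of the
#' metric, so metrics are standardized on the analysis subset (after the
#' diary-completeness filter) immediately before fitting.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return Vector with sample mean 0 and sample SD 1.
#' @export
standardize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || anyNA(values)) {
    stop("standardize needs >= 2 non-missing numeric values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("cannot standardize a constant vector (zero variance)",
         call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Assemble the per-subject cohort table
#'
#' Joins repertoire metrics, diary-derived infection counts and covariates
#' into the analysis table: one row per subject with the metric columns,
#' `older_siblings`, cumulative ARI counts `ari_y1`..`ari_y<k>` and diary
#' `completeness` over the full observation window. Subjects must appear in
#' all three inputs to be retained.
#'
#' @param metrics data.frame from [metrics_table()] (column `subject_id`).
#' @param diaries named list of [symptom_diary()] objects.
#' @param covariates data.frame with `subject_id`, logical
#'   `older_siblings`, and any further covariate columns (passed through).
#' @param gap_days,missing_policy forwarded to [call_episodes()].
#' @param years year boundaries for the cumulative counts.
#' @param episodes optional named list of precomputed episode tables (as
#'   returned by [call_episodes()]); when `NULL`, episodes are called from
#'   the diaries.
#' @return data.frame of class `cohort_table` (one row per subject).
#' @export
build_cohort_table <- function(metrics, diaries, covariates,
                               gap_days = 3L,
                               missing_policy = "asymptomatic",
                               years = 1:4,
                               episodes = NULL) {
  stopifnot(is.data.frame(metrics), "subject_id" %in% names(metrics),
            is.data.frame(covariates), "subject_id" %in% names(covariates))
  ends <- year_end_days(years)
  window <- c(0L, max(ends))
  ids <- intersect(intersect(metrics$subject_id, names(diaries)),
                   covariates$subject_id)
  rows <- lapply(ids, function(id) {
    epi <- if (!is.null(episodes)) episodes[[id]] else
      call_episodes(diaries[[id]], gap_days = gap_days,
                    missing_policy = missing_policy)
    counts <- cumulative_ari(epi, ends)
    ari <- as.data.frame(as.list(counts))
    names(ari) <- paste0("ari_y", years)
    cbind(metrics[metrics$subject_id == id, , drop = FALSE],
          covariates[covariates$subject_id == id,
                     setdiff(names(covariates), "subject_id"), drop = FALSE],
          ari,
          completeness = completeness(diaries[[id]], window))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Filter a cohort table by diary completeness
#'
#' @param table a [build_cohort_table()] result with a `completeness`
#'   column.
#' @param min_completeness retain subjects with completeness strictly above
#'   this value (default 0.8).
#' @return Filtered table, with the excluded subject ids in
#'   `attr(, "excluded")`.
#' @export
filter_completeness <- function(table, min_completeness = 0.8) {
  stopifnot("completeness" %in% names(table))
  keep <- table$completeness > min_completeness
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- table$subject_id[!keep]
  out
}

# Shared design-matrix preparation: standardizes the metric and handles a
# degenerate (constant) sibling covariate.
prepare_design <- function(table, metric) {
  if (!metric %in% names(table)) {
    stop(sprintf("metric '%s' is not a column of the cohort table", metric),
         call. = FALSE)
  }
  if (nrow(table) < 3L) {
    stop(sprintf("insufficient data: %d subject(s), need at least 3",
                 nrow(table)), call. = FALSE)
  }
  z <- standardize(table[[metric]])
  sib <- as.logical(table$older_siblings)
  drop_sib <- length(unique(sib)) < 2L
  if (drop_sib) {
    warning("older_siblings is constant; sibling term dropped from the model",
            call. = FALSE)
  }
  list(z = z, sib = sib, drop_sib = drop_sib)
}

effect_row <- function(term, estimate, ci, scale) {
  data.frame(term = term, estimate = estimate,
             ci_low = ci[1], ci_high = ci[2],
             scale = scale, stringsAsFactors = FALSE)
}

#' Adjusted linear model of cumulative ARI on one repertoire metric
#'
#' Ordinary least squares of the cumulative ARI count at `outcome_year`
#' years on the standardized metric plus an older-sibling indicator,
#' mirroring the convention of fitting each correlated repertoire index
#' separately while always adjusting for older siblings. Estimates are on
#' the "additional infections" scale: the metric coefficient is the change
#' in expected cumulative infections per 1 SD of the metric; the sibling
#' coefficient is the difference for children with older siblings.
#'
#' @param table cohort table (after the completeness filter).
#' @param metric name of the metric column, e.g. `"clonality"`.
#' @param outcome_year year whose cumulative count is the outcome
#'   (column `ari_y<outcome_year>`), default 4.
#' @param conf_level confidence level for the normal-theory Wald intervals.
#' @return data.frame of effect estimates (term, estimate, ci_low, ci_high,
#'   scale), with the fitted `lm` object in `attr(, "fit")`.
#' @export
fit_linear_ari <- function(table, metric, outcome_year = 4L,
                           conf_level = 0.95) {
  outcome <- paste0("ari_y", outcome_year)
  if (!outcome %in% names(table)) {
    stop(sprintf("cohort table lacks outcome column '%s'", outcome),
         call. = FALSE)
  }
  des <- prepare_design(table, metric)
  df <- data.frame(y = table[[outcome]], metric_z = des$z,
                   older_siblings = des$sib)
  fml <- if (des$drop_sib) y ~ metric_z else y ~ metric_z + older_siblings
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("collinear design: coefficients not estimable", call. = FALSE)
  }
  ci <- stats::confint.default(fit, level = conf_level)
  terms <- setdiff(names(stats::coef(fit)), "(Intercept)")
  out <- do.call(rbind, lapply(terms, function(tm) {
    effect_row(sub("TRUE$", "", tm), unname(stats::coef(fit)[tm]), ci[tm, ],
               scale = "additional_infections")
  }))
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Poisson regression of cumulative ARI across time intervals
#'
#' Log-link Poisson fit of the cumulative ARI count at each interval end on
#' the standardized metric and the older-sibling indicator; one model per
#' interval so the time course of the association can be compared on a
#' common relative-risk scale. The reported relative risk is the
#' exponentiated coefficient: the multiplicative change in expected
#' cumulative infections per 1 SD of the metric (or for having older
#' siblings), with exponentiated Wald confidence intervals.
#'
#' Overdispersion is not modelled; the Pearson dispersion statistic of
#' each fit is reported informationally in `attr(, "dispersion")`.
#'
#' @inheritParams fit_linear_ari
#' @param interval_years years whose cumulative counts are successive
#'   outcomes (default 1:4).
#' @return data.frame of effect estimates with an `interval_year` column;
#'   `scale` is `"relative_risk"`.
#' @export
fit_poisson_ari <- function(table, metric, interval_years = 1:4,
                            conf_level = 0.95) {
  des <- prepare_design(table, metric)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list()
  disp <- numeric(0)
  for (yr in interval_years) {
    outcome <- paste0("ari_y", yr)
    if (!outcome %in% names(table)) {
      stop(sprintf("cohort table lacks outcome column '%s'", outcome),
           call. = FALSE)
    }
    y <- table[[outcome]]
    if (all(y == 0)) {
      stop(sprintf("all counts are zero at interval year %d; Poisson fit is degenerate",
                   yr), call. = FALSE)
    }
    df <- data.frame(y = y, metric_z = des$z, older_siblings = des$sib)
    fml <- if (des$drop_sib) y ~ metric_z else y ~ metric_z + older_siblings
    fit <- stats::glm(fml, family = stats::poisson(), data = df)
    if (!fit$converged) {
      stop(sprintf("Poisson fit failed to converge at interval year %d", yr),
           call. = FALSE)
    }
    cf <- summary(fit)$coefficients
    terms <- setdiff(rownames(cf), "(Intercept)")
    rows <- do.call(rbind, lapply(terms, function(tm) {
      est <- cf[tm, "Estimate"]
      se <- cf[tm, "Std. Error"]
      r <- effect_row(sub("TRUE$", "", tm), exp(est),
                      exp(c(est - q * se, est + q * se)),
                      scale = "relative_risk")
      r$interval_year <- yr
      r
    }))
    out[[as.character(yr)]] <- rows
    disp[as.character(yr)] <-
      sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dispersion") <- disp
  res
}

#' Squared Pearson correlations between metrics and ARI counts
#'
#' Descriptive companion to the regression fits: R^2 between each metric
#' column and a cumulative ARI count.
#'
#' @param table cohort table.
#' @param metrics metric column names.
#' @param outcome_year year of the cumulative count.
#' @return Named numeric vector of R^2 values.
#' @export
metric_ari_r2 <- function(table,
                          metrics = c("clonality", "shannon_bits",
                                      "simpson_diversity", "richness"),
                          outcome_year = 4L) {
  y <- table[[paste0("ari_y", outcome_year)]]
  vapply(metrics, function(m) stats::cor(table[[m]], y)^2, numeric(1))
}
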