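test_that("standardize centers and scales to sample SD 1", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(rnorm(50, 10, 3))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(standardize(c(5, 5)), "constant")
  expect_error(standardize(5), "2")
})

test_that("fit_linear_ari recovers an exact linear signal", {
  set.seed(1)
  z <- rnorm(40)
  tab <- data.frame(subject_id = as.character(1:40),
                    metric = z,
                    older_siblings = rep(c(TRUE, FALSE), 20),
                    ari_y4 = 10 * standardize(z))
  # lm warns about the (intentionally) perfect fit
  est <- suppressWarnings(fit_linear_ari(tab, "metric"))
  row <- est[est$term == "metric_z", ]
  expect_equal(row$estimate, 10, tolerance = 1e-8)
  expect_equal(max(abs(resid(attr(est, "fit")))), 0, tolerance = 1e-8)
  expect_true(all(est$ci_low <= est$estimate & est$estimate <= est$ci_high))
})

test_that("a constant sibling covariate is dropped with a warning", {
  tab <- data.frame(subject_id = as.character(1:20), metric = rnorm(20),
                    older_siblings = FALSE, ari_y4 = rpois(20, 10))
  expect_warning(est <- fit_linear_ari(tab, "metric"), "constant")
  expect_equal(est$term, "metric_z")
  expect_error(fit_linear_ari(tab[1:2, ], "metric"), "insufficient")
  expect_error(fit_linear_ari(tab, "nope"), "not a column")
})

test_that("linear CIs achieve close to nominal coverage", {
  # generating model: ari = 30 - 3 * z + 5 * sib + N(0, 4)
  n <- 400
  covered_m <- covered_s <- 0
  for (r in 1:100) {
    set.seed(1000 + r)
    z <- rnorm(n)
    sib <- runif(n) < 0.4
    y <- 30 - 3 * z + 5 * sib + rnorm(n, 0, 4)
    tab <- data.frame(subject_id = as.character(1:n), metric = z,
                      older_siblings = sib, ari_y4 = y)
    est <- fit_linear_ari(tab, "metric")
    m <- est[est$term == "metric_z", ]
    s <- est[est$term == "older_siblings", ]
    # the metric is re-standardized, so the true slope is -3 * sd(z)
    truth_m <- -3 * sd(z)
    covered_m <- covered_m + (m$ci_low <= truth_m && truth_m <= m$ci_high)
    covered_s <- covered_s + (s$ci_low <= 5 && 5 <= s$ci_high)
  }
  expect_gte(covered_m, 93)
  expect_gte(covered_s, 93)
})

test_that("fit_poisson_ari recovers generating relative risks", {
  rrs <- vapply(1:50, function(r) {
    tab <- simulate_association_table(n = 500, beta0 = 3.4,
                                      beta_metric = -0.1, beta_sib = 0.15,
                                      seed = 5000 + r)
    est <- fit_poisson_ari(tab, "metric", interval_years = 4)
    est$estimate[est$term == "metric_z"]
  }, numeric(1))
  mc_se <- sd(rrs) / sqrt(length(rrs))
  expect_lt(abs(mean(rrs) - exp(-0.1)), 3 * mc_se + 0.03)

  # dispersion is reported informationally and is ~1 for Poisson data
  tab <- simulate_association_table(n = 1000, seed = 77)
  est <- fit_poisson_ari(tab, "metric", interval_years = 1:4)
  expect_equal(sort(unique(est$interval_year)), 1:4)
  expect_true(all(est$scale == "relative_risk"))
  disp <- attr(est, "dispersion")
  expect_true(all(disp > 0.7 & disp < 1.4))
})

test_that("null-metric Poisson CIs cover RR 1 at close to nominal rate", {
  cover <- vapply(1:100, function(r) {
    tab <- simulate_association_table(n = 300, beta_metric = 0,
                                      seed = 9000 + r)
    est <- fit_poisson_ari(tab, "metric", interval_years = 4)
    m <- est[est$term == "metric_z", ]
    m$ci_low <= 1 && 1 <= m$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("degenerate outcomes fail loudly, never silently", {
  tab <- data.frame(subject_id = as.character(1:10), metric = rnorm(10),
                    older_siblings = rep(c(TRUE, FALSE), 5), ari_y4 = 0L)
  expect_error(fit_poisson_ari(tab, "metric", interval_years = 4),
               "zero")
  expect_error(fit_poisson_ari(tab, "metric", interval_years = 2),
               "ari_y2")
})

test_that("linear and Poisson fits agree in sign and are order-invariant", {
  tab <- simulate_association_table(n = 400, beta_metric = -0.15, seed = 42)
  lin <- fit_linear_ari(tab, "metric")
  poi <- fit_poisson_ari(tab, "metric", interval_years = 4)
  b_lin <- lin$estimate[lin$term == "metric_z"]
  rr <- poi$estimate[poi$term == "metric_z"]
  expect_true(sign(b_lin) == sign(log(rr)))
  expect_lt(b_lin, 0)

  shuffled <- tab[sample(nrow(tab)), ]
  shuffled$subject_id <- paste0("X", shuffled$subject_id)
  lin2 <- fit_linear_ari(shuffled, "metric")
  expect_equal(lin2$estimate, lin$estimate, tolerance = 1e-9)
  poi2 <- fit_poisson_ari(shuffled, "metric", interval_years = 4)
  expect_equal(poi2$estimate, poi$estimate, tolerance = 1e-9)
})

test_that("build_cohort_table joins metrics, episodes and covariates", {
  sc <- cohort_scenario(n_subjects = 6, n_clones = 60,
                        reads_per_subject = 1200, diary_missing_prob = 0,
                        follow_up_days = 1460, seed = 21)
  sim <- simulate_cohort(sc)
  metrics <- metrics_table(lapply(sim$repertoires, filter_repertoire))
  tab <- build_cohort_table(metrics, sim$diaries, sim$covariates)
  expect_equal(nrow(tab), 6L)
  expect_true(all(c("ari_y1", "ari_y4", "completeness",
                    "older_siblings") %in% names(tab)))
  expect_true(all(tab$completeness == 1))
  # counts non-decreasing across years
  expect_true(all(tab$ari_y4 >= tab$ari_y1))
  # with no missingness the counts equal the planted episode totals
  truth_counts <- sim$truth$subjects$n_episodes[
    match(tab$subject_id, sim$truth$subjects$subject_id)]
  expect_equal(tab$ari_y4, truth_counts)

  filt <- filter_completeness(tab, 0.8)
  expect_equal(nrow(filt), 6L)
  expect_length(attr(filt, "excluded"), 0L)
})

test_that("metric_ari_r2 returns squared correlations", {
  tab <- simulate_association_table(n = 200, seed = 3)
  tab$clonality <- -tab$metric
  r2 <- metric_ari_r2(tab, metrics = "clonality")
  expect_equal(unname(r2), cor(tab$clonality, tab$ari_y4)^2)
})
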