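test_that("risk scores are the plain linear combination", {
  co <- toy_survival_cohort(n = 6, n_genes = 3)
  model <- structure(
    list(genes = c("s1", "s2"), coefficients = c(s1 = 1, s2 = -1),
         training_cohort = "x", ridge = FALSE, ridge_theta = 0,
         n = 6, n_events = 6, coef_table = tibble::tibble()),
    class = "risk_model"
  )
  sc <- risk_scores(model, co)
  expect_equal(sc$risk_score,
               unname(co$expression["s1", ] - co$expression["s2", ]))

  # cancellation and single-gene arithmetic
  x <- matrix(c(2, 2), 2, 1, dimnames = list(c("s1", "s2"), "pt001"))
  co1 <- survival_cohort(x, tibble::tibble(patient_id = "pt001",
                                           os_time = 10, os_event = 1L,
                                           stage = "III"))
  expect_equal(risk_scores(model, co1)$risk_score, 0)
  model1 <- model
  model1$genes <- "s1"
  model1$coefficients <- c(s1 = 0.5)
  x3 <- matrix(3, 1, 1, dimnames = list("s1", "pt001"))
  co3 <- survival_cohort(x3, co1$clinical)
  expect_equal(risk_scores(model1, co3)$risk_score, 1.5)

  model_missing <- model
  model_missing$genes <- c("s1", "absent")
  expect_error(risk_scores(model_missing, co), "absent")
})

test_that("risk scores are linear in the expression matrix", {
  co <- toy_survival_cohort(n = 10, n_genes = 3, seed = 2)
  model <- suppressWarnings(fit_risk_model(co, c("s1", "s2")))
  co2 <- co
  co2$expression <- co$expression * 2
  expect_equal(risk_scores(model, co2)$risk_score,
               2 * risk_scores(model, co)$risk_score)
})

test_that("fit_risk_model recovers a known coefficient and is order-invariant", {
  sim <- simulate_survival_cohorts("s1", 0.7, n_cohorts = 1,
                                   n_per_cohort = 300, censoring = 0.2,
                                   n_decoy_genes = 2, seed = 14)
  co <- sim$cohorts[[1]]
  model <- fit_risk_model(co, "s1")
  expect_equal(unname(model$coefficients["s1"]), 0.7, tolerance = 0.2)

  perm <- sample(ncol(co$expression))
  co_perm <- survival_cohort(co$expression[, perm],
                             co$clinical[perm, ], cohort_id = "perm")
  model_perm <- fit_risk_model(co_perm, "s1")
  expect_equal(model$coefficients, model_perm$coefficients,
               tolerance = 1e-8)
})

test_that("degenerate genes and event-free cohorts are handled", {
  co <- toy_survival_cohort(n = 40, n_genes = 3, seed = 3)
  co$expression["s3", ] <- 5
  expect_warning(model <- fit_risk_model(co, c("s1", "s3")),
                 "zero-variance")
  expect_identical(model$genes, "s1")

  dead <- co
  dead$clinical$os_event <- 0L
  expect_error(fit_risk_model(dead, "s1"), "zero events")
})

test_that("median split assigns ties to low risk and validates input", {
  co <- toy_survival_cohort(n = 8, n_genes = 2, seed = 4)
  scores <- tibble::tibble(patient_id = co$clinical$patient_id,
                           risk_score = c(1, 1, 1, 1, 2, 2, 3, 3))
  res <- median_split_logrank(scores, co)
  asg <- attr(res, "assignments")
  # median is 1.5; the four scores at 1 fall below, 2s and 3s above
  expect_equal(res$n_low, 4)
  expect_equal(res$n_high, 4)
  expect_setequal(asg$risk_group[asg$risk_score == 1], "low")

  flat <- dplyr::mutate(scores, risk_score = 7)
  expect_error(median_split_logrank(flat, co), "identical")
})

test_that("median split separates a strong signature in late-stage strata", {
  genes <- paste0("s", 1:5)
  sim <- simulate_survival_cohorts(genes, rep(c(0.8, -0.8), length.out = 5),
                                   n_cohorts = 2, n_per_cohort = c(250, 200),
                                   censoring = 0.2, seed = 15)
  model <- fit_risk_model(sim$cohorts[[1]], genes)
  sc <- risk_scores(model, sim$cohorts[[2]])
  late <- suppressWarnings(
    median_split_logrank(sc, sim$cohorts[[2]], stage_filter = c("III", "IV"))
  )
  expect_lt(late$logrank_p, 0.05)
  expect_gt(late$hr, 1)
  expect_equal(late$n, sum(sim$cohorts[[2]]$clinical$stage %in%
                             c("III", "IV")))
})

test_that("cross-validation is stratified, seeded and covers every patient", {
  co <- toy_survival_cohort(n = 30, n_genes = 3, seed = 5)
  cv1 <- suppressWarnings(cross_validate(co, c("s1", "s2"), k = 5, seed = 9))
  cv2 <- suppressWarnings(cross_validate(co, c("s1", "s2"), k = 5, seed = 9))
  expect_identical(cv1, cv2)
  expect_setequal(cv1$patient_id, co$clinical$patient_id)
  expect_equal(sort(unique(cv1$fold)), 1:5)

  loo <- suppressWarnings(cross_validate(co, "s1", k = 30, seed = 9))
  expect_equal(nrow(loo), 30)
})

test_that("null signatures give non-significant splits in most replicates", {
  genes <- paste0("s", 1:3)
  hits <- vapply(1:30, function(i) {
    sim <- simulate_survival_cohorts(genes, rep(0, 3), n_cohorts = 1,
                                     n_per_cohort = 80, censoring = 0.2,
                                     n_decoy_genes = 0, seed = 200 + i)
    co <- sim$cohorts[[1]]
    set.seed(300 + i)
    fake_scores <- tibble::tibble(patient_id = co$clinical$patient_id,
                                  risk_score = rnorm(80))
    suppressWarnings(median_split_logrank(fake_scores, co)$logrank_p) < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("meta-analysis pooling matches hand computation and metafor", {
  effects <- tibble::tibble(
    cohort_id = c("a", "b", "c"),
    log_hr = c(0.8, 0.5, 1.1),
    se_log_hr = c(0.2, 0.3, 0.25)
  )
  fixed <- meta_analyze(effects, "fixed")
  w <- 1 / effects$se_log_hr^2
  expect_equal(fixed$pooled_log_hr, sum(w * effects$log_hr) / sum(w),
               tolerance = 1e-12)
  expect_equal(fixed$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  expect_equal(fixed$tau2, 0)

  random <- meta_analyze(effects, "random")
  skip_if_not_installed("metafor")
  fe <- metafor::rma(yi = effects$log_hr, sei = effects$se_log_hr,
                     method = "FE")
  expect_equal(fixed$pooled_log_hr, as.numeric(fe$beta), tolerance = 1e-8)
  dl <- metafor::rma(yi = effects$log_hr, sei = effects$se_log_hr,
                     method = "DL")
  expect_equal(random$pooled_log_hr, as.numeric(dl$beta), tolerance = 1e-8)
  expect_equal(random$tau2, dl$tau2, tolerance = 1e-8)
})

test_that("degenerate pooling cases behave exactly", {
  same <- tibble::tibble(cohort_id = c("a", "b"), log_hr = 0.6,
                         se_log_hr = 0.2)
  for (m in c("fixed", "random")) {
    res <- meta_analyze(same, m)
    expect_equal(res$pooled_log_hr, 0.6, tolerance = 1e-12)
    expect_equal(res$tau2, 0)
    expect_true(res$ci_lower <= res$pooled_hr &
                  res$pooled_hr <= res$ci_upper)
  }
  bad <- dplyr::mutate(same, se_log_hr = c(0.2, 0))
  expect_error(meta_analyze(bad), "positive")
  expect_error(meta_analyze(same[1, ]), "at least 2")
})

test_that("the concordance index is exact on ordered data and rank-invariant", {
  n <- 20
  pid <- sprintf("pt%03d", 1:n)
  x <- matrix(0, 1, n, dimnames = list("s1", pid))
  co <- survival_cohort(
    x, tibble::tibble(patient_id = pid, os_time = n:1, os_event = 1L,
                      stage = "III"))
  # highest score fails first, no censoring: C = 1
  sc <- tibble::tibble(patient_id = pid, risk_score = 1:n)
  expect_equal(concordance_index(sc, co)$c_index, 1)
  # reversed scores: C = 0
  expect_equal(concordance_index(dplyr::mutate(sc, risk_score = -risk_score),
                                 co)$c_index, 0)
  # strictly monotone transforms leave C unchanged
  co2 <- toy_survival_cohort(n = 50, seed = 6)
  sc2 <- tibble::tibble(patient_id = co2$clinical$patient_id,
                        risk_score = rnorm(50))
  c_raw <- concordance_index(sc2, co2)$c_index
  c_exp <- concordance_index(dplyr::mutate(sc2, risk_score = exp(risk_score)),
                             co2)$c_index
  expect_equal(c_raw, c_exp)
})

test_that("the concordance index agrees with the survival package", {
  co <- toy_survival_cohort(n = 60, seed = 7)
  cl <- co$clinical
  cl$os_event[seq(1, 60, by = 3)] <- 0L # add censoring
  co_c <- survival_cohort(co$expression, cl)
  sc <- tibble::tibble(patient_id = cl$patient_id,
                       risk_score = unname(co$expression["s1", ]))
  ours <- concordance_index(sc, co_c)$c_index
  ref <- survival::concordance(
    survival::Surv(cl$os_time, cl$os_event) ~ sc$risk_score, reverse = TRUE
  )$concordance
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("survival simulation honours cohort sizes and censoring bounds", {
  sim <- simulate_survival_cohorts(paste0("s", 1:3), c(0.5, -0.5, 0.2),
                                   seed = 16)
  expect_equal(vapply(sim$cohorts, function(co) ncol(co$expression),
                      numeric(1)),
               c(62, 177, 566, 65, 70), ignore_attr = TRUE)
  expect_error(
    simulate_survival_cohorts("s1", 1, censoring = 1),
    "censoring"
  )
  expect_error(simulate_survival_cohorts(c("a", "b"), 1), "equal length")
})

test_that("the factor screen reports univariate and multivariate rows", {
  sim <- simulate_survival_cohorts(paste0("s", 1:3), c(0.8, -0.8, 0.5),
                                   n_cohorts = 1, n_per_cohort = 200,
                                   censoring = 0.2, seed = 17)
  co <- sim$cohorts[[1]]
  model <- fit_risk_model(co, paste0("s", 1:3))
  clin <- dplyr::inner_join(co$clinical, risk_scores(model, co),
                            by = "patient_id")
  clin$late_stage <- as.integer(clin$stage %in% c("III", "IV"))
  tbl <- cox_factor_table(clin, c("risk_score", "late_stage"))
  expect_equal(nrow(tbl), 4)
  expect_setequal(unique(tbl$analysis), c("univariate", "multivariate"))
  rs <- tbl[tbl$analysis == "univariate" & grepl("risk_score", tbl$factor), ]
  expect_gt(rs$hr, 1)
  expect_lt(rs$p_value, 0.01)
})
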