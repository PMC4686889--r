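#' Survival cohort container
#'
#' @param expression Genes-by-patients numeric matrix with gene ids as row
#'   names and patient ids as column names.
#' @param clinical Data frame with `patient_id`, `os_time` (> 0),
#'   `os_event` (0/1) and `stage` (`"I"`..`"IV"`), one row per patient, in
#'   any order (matched to expression columns by `patient_id`).
#' @param cohort_id Label for the cohort.
#' @return An object of class `survival_cohort`.
#' @export
survival_cohort <- function(expression, clinical, cohort_id = "cohort") {
  if (!is.matrix(expression) || is.null(rownames(expression)) ||
      is.null(colnames(expression))) {
    abort("`expression` must be a matrix with gene and patient dimnames.")
  }
  need <- c("patient_id", "os_time", "os_event", "stage")
  if (!all(need %in% names(clinical))) {
    abort(paste0("`clinical` needs columns: ", paste(need, collapse = ", ")))
  }
  clinical <- as_tibble(clinical)
  if (!setequal(clinical$patient_id, colnames(expression))) {
    abort("clinical patient_ids must match expression columns.")
  }
  if (!all(clinical$os_event %in% c(0, 1))) abort("os_event must be 0/1.")
  if (any(clinical$os_event == 1 & (is.na(clinical$os_time) |
                                      clinical$os_time <= 0))) {
    abort("evented patients must have positive os_time.")
  }
  if (!all(clinical$stage %in% c("I", "II", "III", "IV"))) {
    abort("stage must be one of I, II, III, IV.")
  }
  clinical <- clinical[match(colnames(expression), clinical$patient_id), ]
  structure(list(expression = expression, clinical = clinical,
                 cohort_id = cohort_id),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("<survival_cohort> %s: %d genes x %d patients, %d events\n",
              x$cohort_id, nrow(x$expression), ncol(x$expression),
              sum(x$clinical$os_event)))
  invisible(x)
}

#' Simulate survival cohorts driven by a known gene signature
#'
#' Expression values are standard normal per gene and patient. Event times
#' follow a proportional-hazards model with exponential baseline: the
#' linear predictor is the signature risk score `sum(beta_i * x_ij)`, and
#' times are drawn by inverse-CDF sampling. Censoring times are independent
#' exponentials calibrated so roughly the requested fraction of baseline
#' patients is censored. Tumor stage is assigned from the quantile of the
#' absolute centred predictor plus noise, so late-stage patients carry
#' larger predictor spread - early-stage strata are signal-poor, late-stage
#' strata signal-rich.
#'
#' @param signature_genes Character vector of signature gene ids.
#' @param true_coefficients Numeric log-hazard coefficients, one per gene.
#' @param n_cohorts Number of cohorts (default 5).
#' @param n_per_cohort Patients per cohort; a single value or one per
#'   cohort (default the Clinicinfo-style sizes 62, 177, 566, 65, 70).
#' @param censoring Target censoring fraction in `[0, 1)` (default 0.3).
#' @param baseline_hazard Exponential baseline hazard per day (default
#'   1/1000).
#' @param n_decoy_genes Non-signature genes included in each expression
#'   matrix (default 20).
#' @param seed RNG seed.
#' @return List with `cohorts` (list of [survival_cohort()]) and `truth`
#'   (signature genes and coefficients).
#' @export
simulate_survival_cohorts <- function(signature_genes, true_coefficients,
                                      n_cohorts = 5,
                                      n_per_cohort = c(62, 177, 566, 65, 70),
                                      censoring = 0.3,
                                      baseline_hazard = 1e-3,
                                      n_decoy_genes = 20,
                                      seed = NULL) {
  if (length(signature_genes) != length(true_coefficients)) {
    abort("`signature_genes` and `true_coefficients` must have equal length.")
  }
  if (!all(is.finite(true_coefficients))) abort("coefficients must be finite.")
  check_scalar_number(n_cohorts, "n_cohorts", 1)
  check_scalar_number(censoring, "censoring", 0, 1, strict_upper = TRUE)
  check_scalar_number(baseline_hazard, "baseline_hazard", 0,
                      strict_lower = TRUE)
  n_per_cohort <- rep_len(n_per_cohort, n_cohorts)
  use_seed(seed)
  genes <- c(signature_genes,
             if (n_decoy_genes > 0) sprintf("decoy%03d", seq_len(n_decoy_genes)))
  cohorts <- purrr::map(seq_len(n_cohorts), function(ci) {
    n <- n_per_cohort[ci]
    pid <- sprintf("c%d_pt%04d", ci, seq_len(n))
    x <- matrix(rnorm(length(genes) * n), length(genes), n,
                dimnames = list(genes, pid))
    eta <- as.numeric(crossprod(x[signature_genes, , drop = FALSE],
                                true_coefficients))
    t_event <- -log(runif(n)) / (baseline_hazard * exp(eta))
    if (censoring > 0) {
      lam_c <- baseline_hazard * censoring / (1 - censoring)
      t_cens <- -log(runif(n)) / lam_c
    } else {
      t_cens <- rep(Inf, n)
    }
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
    # late stage tracks predictor spread: quantile of |centred eta| + noise
    u <- rank(abs(eta - median(eta)), ties.method = "average") / n +
      rnorm(n, sd = 0.15)
    stage <- cut(u, breaks = c(-Inf, 0.25, 0.55, 0.85, Inf),
                 labels = c("I", "II", "III", "IV"))
    survival_cohort(
      x,
      tibble(patient_id = pid, os_time = os_time, os_event = os_event,
             stage = as.character(stage)),
      cohort_id = sprintf("cohort_%d", ci)
    )
  })
  list(cohorts = cohorts,
       truth = list(signature_genes = signature_genes,
                    true_coefficients = true_coefficients))
}
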