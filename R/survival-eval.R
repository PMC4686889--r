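#' Fit a multivariable Cox risk model over a gene signature
#'
#' Fits a proportional-hazards regression of overall survival on the
#' expression of the signature genes in a training cohort. Genes with zero
#' expression variance are dropped with a warning. If the unpenalized fit
#' fails to converge or produces non-finite coefficients, the model is
#' refit with a small ridge penalty (reported in the result).
#'
#' @param cohort A [survival_cohort()].
#' @param genes Signature gene ids; must all be rows of the cohort's
#'   expression matrix.
#' @param ridge_theta Ridge penalty used by the fallback fit (default 1).
#' @return An object of class `risk_model`: list with `genes`,
#'   `coefficients` (named, log-hazard scale), `training_cohort`, `ridge`
#'   (logical), `ridge_theta`, `n`, `n_events` and the coefficient table.
#' @export
fit_risk_model <- function(cohort, genes, ridge_theta = 1) {
  stopifnot(inherits(cohort, "survival_cohort"))
  missing_genes <- setdiff(genes, rownames(cohort$expression))
  if (length(missing_genes)) {
    abort(paste0("gene(s) absent from the cohort: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  cl <- cohort$clinical
  n_events <- sum(cl$os_event)
  if (n_events == 0) abort("training cohort has zero events.")
  if (n_events < 10) {
    warn(sprintf("only %d events in the training cohort; estimates may be unstable.",
                 n_events))
  }
  x <- t(cohort$expression[genes, , drop = FALSE])
  keep <- apply(x, 2, sd) > 0
  if (any(!keep)) {
    warn(paste0("dropping zero-variance gene(s): ",
                paste(genes[!keep], collapse = ", ")))
  }
  genes <- genes[keep]
  if (!length(genes)) abort("no gene with non-zero variance remains.")
  df <- data.frame(x[, keep, drop = FALSE], check.names = FALSE)
  df$.time <- cl$os_time
  df$.event <- cl$os_event
  terms <- paste0("`", genes, "`")
  plain_formula <- stats::as.formula(
    paste("survival::Surv(.time, .event) ~", paste(terms, collapse = " + "))
  )
  used_ridge <- FALSE
  fit_warned <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph(plain_formula, data = df),
      # coxph signals unstable/infinite coefficients as warnings
      warning = function(w) {
        fit_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) NULL
  )
  bad <- is.null(fit) || fit_warned || any(!is.finite(stats::coef(fit)))
  if (bad) {
    inform(sprintf("unpenalized Cox fit unstable; refitting with ridge penalty theta = %g.",
                   ridge_theta))
    ridge_formula <- stats::as.formula(paste0(
      "survival::Surv(.time, .event) ~ survival::ridge(",
      paste(terms, collapse = ", "), ", theta = ", ridge_theta, ")"
    ))
    fit <- survival::coxph(ridge_formula, data = df)
    used_ridge <- TRUE
  }
  coefs <- stats::coef(fit)
  names(coefs) <- genes
  se <- sqrt(diag(stats::vcov(fit)))[seq_along(genes)]
  structure(
    list(genes = genes, coefficients = coefs,
         training_cohort = cohort$cohort_id,
         ridge = used_ridge, ridge_theta = if (used_ridge) ridge_theta else 0,
         n = nrow(df), n_events = n_events,
         coef_table = tibble(term = genes, estimate = unname(coefs),
                             std.error = unname(se),
                             p.value = 2 * stats::pnorm(-abs(unname(coefs) / unname(se))))),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %d genes trained on %s (%d patients, %d events)%s\n",
              length(x$genes), x$training_cohort, x$n, x$n_events,
              if (x$ridge) sprintf(" [ridge theta=%g]", x$ridge_theta) else ""))
  invisible(x)
}

#' @describeIn fit_risk_model Coefficient table (`term`, `estimate`,
#'   `std.error`, `p.value`).
#' @param x A `risk_model`.
#' @param ... Unused.
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) x$coef_table

#' @describeIn fit_risk_model One-row model summary.
#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, n_genes = length(x$genes),
         ridge = x$ridge, ridge_theta = x$ridge_theta,
         training_cohort = x$training_cohort)
}

#' Linear risk scores for a cohort
#'
#' The per-patient risk score is the linear combination of signature-gene
#' expression weighted by the training-cohort Cox coefficients:
#' `r_j = sum_i beta_i * x_ij`. Coefficients are never refit on test
#' cohorts.
#'
#' @param model A `risk_model` from [fit_risk_model()].
#' @param cohort A [survival_cohort()] containing all model genes.
#' @return A tibble `patient_id`, `risk_score`.
#' @export
risk_scores <- function(model, cohort) {
  stopifnot(inherits(model, "risk_model"), inherits(cohort, "survival_cohort"))
  missing_genes <- setdiff(model$genes, rownames(cohort$expression))
  if (length(missing_genes)) {
    abort(paste0("cohort lacks model gene(s): ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  scores <- as.numeric(crossprod(
    cohort$expression[model$genes, , drop = FALSE], model$coefficients
  ))
  tibble(patient_id = colnames(cohort$expression), risk_score = scores)
}

#' Median-split survival comparison with log-rank test
#'
#' Splits patients at the median risk score (strictly above the median is
#' high-risk; scores at or below it are low-risk unless `ties_high`),
#' optionally within a stage stratum, and compares the two groups with a
#' two-sided log-rank test plus a univariable Cox hazard ratio (high vs
#' low).
#'
#' @param scores Tibble `patient_id`, `risk_score` (e.g. from
#'   [risk_scores()] or [cross_validate()]).
#' @param cohort A [survival_cohort()].
#' @param stage_filter Optional character vector of stages to keep, e.g.
#'   `c("III", "IV")`.
#' @param ties_high If `TRUE`, scores equal to the median go to the
#'   high-risk group (default `FALSE`).
#' @return A one-row tibble: `cohort_id`, `n`, `n_high`, `n_low`,
#'   `logrank_p`, `hr`, `log_hr`, `se_log_hr`; the per-patient group
#'   assignment tibble is attached as attribute `"assignments"`.
#' @export
median_split_logrank <- function(scores, cohort, stage_filter = NULL,
                                 ties_high = FALSE) {
  stopifnot(inherits(cohort, "survival_cohort"))
  df <- dplyr::inner_join(cohort$clinical, scores, by = "patient_id")
  if (!is.null(stage_filter)) df <- filter(df, .data$stage %in% stage_filter)
  if (nrow(df) < 4) abort("fewer than 4 patients after filtering.")
  if (length(unique(df$risk_score)) == 1L) {
    abort("all risk scores identical; median split undefined.")
  }
  med <- median(df$risk_score)
  high <- if (ties_high) df$risk_score >= med else df$risk_score > med
  if (sum(high) < 2 || sum(!high) < 2) {
    abort("median split leaves fewer than 2 patients on one side.")
  }
  df$risk_group <- ifelse(high, "high", "low")
  surv <- survival::Surv(df$os_time, df$os_event)
  sd_fit <- survival::survdiff(surv ~ risk_group, data = df)
  p <- 1 - pchisq(sd_fit$chisq, df = 1)
  cx <- survival::coxph(surv ~ I(risk_group == "high"), data = df)
  log_hr <- unname(stats::coef(cx)[1])
  se <- sqrt(diag(stats::vcov(cx)))[1]
  out <- tibble(
    cohort_id = cohort$cohort_id, n = nrow(df),
    n_high = sum(high), n_low = sum(!high),
    logrank_p = p, hr = exp(log_hr), log_hr = log_hr,
    se_log_hr = unname(se)
  )
  attr(out, "assignments") <-
    select(df, "patient_id", "risk_score", "risk_group")
  out
}

#' Out-of-fold risk scores by stratified k-fold cross-validation
#'
#' Folds are stratified by event status so every training set retains
#' events; each patient is scored by the model fit with their fold held
#' out. If a fold assignment leaves a training set without events, folds
#' are re-drawn (up to 100 attempts).
#'
#' @param cohort A [survival_cohort()].
#' @param genes Signature gene ids.
#' @param k Number of folds (default 5; `k = n` gives leave-one-out).
#' @param seed RNG seed controlling fold assignment.
#' @param ridge_theta Passed to [fit_risk_model()].
#' @return A tibble `patient_id`, `fold`, `risk_score`.
#' @export
cross_validate <- function(cohort, genes, k = 5, seed = NULL,
                           ridge_theta = 1) {
  stopifnot(inherits(cohort, "survival_cohort"))
  n <- ncol(cohort$expression)
  check_scalar_number(k, "k", 2, n)
  use_seed(seed)
  ev <- cohort$clinical$os_event
  assign_folds <- function() {
    fold <- integer(n)
    for (grp in list(which(ev == 1), which(ev == 0))) {
      fold[grp] <- sample(rep_len(seq_len(k), length(grp)))
    }
    fold
  }
  for (attempt in seq_len(100)) {
    fold <- assign_folds()
    ok <- all(vapply(seq_len(k), function(f) sum(ev[fold != f]) > 0,
                     logical(1)))
    if (ok) break
    if (attempt == 100) abort("could not build folds with events in every training set.")
  }
  purrr::map_dfr(seq_len(k), function(f) {
    test_ids <- colnames(cohort$expression)[fold == f]
    if (!length(test_ids)) return(tibble())
    train <- survival_cohort(
      cohort$expression[, fold != f, drop = FALSE],
      filter(cohort$clinical, !(.data$patient_id %in% test_ids)),
      cohort_id = paste0(cohort$cohort_id, "_minus_fold", f)
    )
    model <- suppressWarnings(
      fit_risk_model(train, genes, ridge_theta = ridge_theta)
    )
    test <- survival_cohort(
      cohort$expression[, fold == f, drop = FALSE],
      filter(cohort$clinical, .data$patient_id %in% test_ids),
      cohort_id = cohort$cohort_id
    )
    mutate(risk_scores(model, test), fold = f, .after = "patient_id")
  }) |>
    arrange(.data$patient_id)
}
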