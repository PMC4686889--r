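#' Pool per-cohort log hazard ratios by fixed- or random-effect model
#'
#' Fixed effect: inverse-variance weighted mean of the cohort log hazard
#' ratios. Random effect: DerSimonian-Laird, with the between-cohort
#' variance `tau^2 = max(0, (Q - (k-1)) / C)` added to every cohort's
#' sampling variance before re-weighting (`Q` the fixed-effect
#' heterogeneity statistic, `C = sum(w) - sum(w^2)/sum(w)`). Homogeneous
#' cohorts give `tau^2 = 0` and the two models coincide.
#'
#' @param effects Data frame with columns `cohort_id`, `log_hr`,
#'   `se_log_hr` (e.g. rows from [median_split_logrank()]).
#' @param model `"fixed"` or `"random"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `meta_result`: list with `model`, `k`,
#'   `pooled_log_hr`, `pooled_hr`, `se`, `ci_lower`, `ci_upper` (HR
#'   scale), `p_value`, `Q`, `tau2` and the per-cohort tibble with
#'   weights.
#' @export
meta_analyze <- function(effects, model = c("fixed", "random"),
                         conf_level = 0.95) {
  model <- match.arg(model)
  need <- c("cohort_id", "log_hr", "se_log_hr")
  if (!all(need %in% names(effects))) {
    abort(paste0("`effects` needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(effects) < 2) abort("pooling needs at least 2 cohorts.")
  if (any(!is.finite(effects$se_log_hr) | effects$se_log_hr <= 0)) {
    abort("all standard errors must be positive and finite.")
  }
  y <- effects$log_hr
  w <- 1 / effects$se_log_hr^2
  k <- length(y)
  mu_fixed <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fixed)^2)
  tau2 <- 0
  if (model == "random") {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
    w <- 1 / (effects$se_log_hr^2 + tau2)
  }
  mu <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      model = model, k = k, pooled_log_hr = mu, pooled_hr = exp(mu),
      se = se, ci_lower = exp(mu - z * se), ci_upper = exp(mu + z * se),
      p_value = 2 * stats::pnorm(-abs(mu / se)), Q = Q, tau2 = tau2,
      per_cohort = mutate(as_tibble(effects), weight = w / sum(w))
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> %s-effect pooling of %d cohorts: HR %.3f (%.3f-%.3f), p = %.3g, tau^2 = %.3g\n",
    x$model, x$k, x$pooled_hr, x$ci_lower, x$ci_upper, x$p_value, x$tau2
  ))
  invisible(x)
}

#' @describeIn meta_analyze Per-cohort effects with pooling weights.
#' @param x A `meta_result`.
#' @param ... Unused.
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) x$per_cohort

#' @describeIn meta_analyze One-row pooled summary.
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble(model = x$model, k = x$k, pooled_hr = x$pooled_hr,
         pooled_log_hr = x$pooled_log_hr, se = x$se,
         ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         p_value = x$p_value, Q = x$Q, tau2 = x$tau2)
}

#' Forest plot of a pooled hazard-ratio meta-analysis
#'
#' @param object A `meta_result`.
#' @param ... Unused.
#' @return A ggplot: per-cohort hazard ratios with 95% intervals and the
#'   pooled estimate.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  z <- stats::qnorm(0.975)
  per <- object$per_cohort |>
    mutate(hr = exp(.data$log_hr),
           lo = exp(.data$log_hr - z * .data$se_log_hr),
           hi = exp(.data$log_hr + z * .data$se_log_hr))
  pooled <- tibble(cohort_id = sprintf("pooled (%s)", object$model),
                   hr = object$pooled_hr, lo = object$ci_lower,
                   hi = object$ci_upper)
  df <- bind_rows(select(per, "cohort_id", "hr", "lo", "hi"), pooled) |>
    mutate(cohort_id = factor(.data$cohort_id, levels = rev(.data$cohort_id)),
           pooled = .data$cohort_id == pooled$cohort_id)
  ggplot(df, aes(x = .data$hr, y = .data$cohort_id, colour = .data$pooled)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$lo, xmax = .data$hi), height = 0.2) +
    geom_vline(xintercept = 1, linetype = 2) +
    scale_x_log10() +
    guides(colour = "none") +
    labs(x = "hazard ratio (high vs low risk)", y = NULL) +
    theme_minimal()
}

#' Harrell's concordance index of risk scores against survival
#'
#' The fraction of comparable patient pairs ordered correctly by the risk
#' score: a pair is comparable when the earlier time is an observed event;
#' it is concordant when the earlier-failing patient has the higher score,
#' and score ties count one half.
#'
#' @param scores Tibble `patient_id`, `risk_score`.
#' @param cohort A [survival_cohort()].
#' @return One-row tibble: `cohort_id`, `c_index`, `concordant`, `tied`,
#'   `comparable`.
#' @export
concordance_index <- function(scores, cohort) {
  stopifnot(inherits(cohort, "survival_cohort"))
  df <- dplyr::inner_join(cohort$clinical, scores, by = "patient_id")
  n <- nrow(df)
  if (n < 2) abort("need at least 2 patients.")
  tm <- df$os_time
  ev <- df$os_event
  sc <- df$risk_score
  # pair (i, j) comparable when t_i < t_j and patient i had the event
  lt <- outer(tm, tm, "<")
  comparable <- lt & matrix(ev == 1, n, n)
  sg <- outer(sc, sc, ">")
  se <- outer(sc, sc, "==")
  concordant <- sum(comparable & sg)
  tied <- sum(comparable & se)
  total <- sum(comparable)
  if (total == 0) abort("no comparable pairs (all times censored or tied).")
  tibble(cohort_id = cohort$cohort_id,
         c_index = (concordant + 0.5 * tied) / total,
         concordant = concordant, tied = tied, comparable = total)
}

#' Univariate and multivariate Cox factor screen
#'
#' Standard prognostic-factor report: each clinical factor (e.g. stage,
#' age, risk score) is screened in a univariable Cox model, then all are
#' entered jointly in one multivariable model.
#'
#' @param clinical Data frame with `os_time`, `os_event` and the factor
#'   columns.
#' @param factors Character vector of column names to screen.
#' @return A tibble: `factor`, `analysis` (`univariate`/`multivariate`),
#'   `hr`, `ci_lower`, `ci_upper`, `p_value`.
#' @export
cox_factor_table <- function(clinical, factors) {
  missing_cols <- setdiff(c("os_time", "os_event", factors), names(clinical))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  surv <- survival::Surv(clinical$os_time, clinical$os_event)
  row_of <- function(fit, analysis) {
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    tibble(factor = names(cf), analysis = analysis,
           hr = exp(unname(cf)),
           ci_lower = exp(unname(cf) - 1.96 * unname(se)),
           ci_upper = exp(unname(cf) + 1.96 * unname(se)),
           p_value = 2 * stats::pnorm(-abs(unname(cf) / unname(se))))
  }
  uni <- purrr::map_dfr(factors, function(f) {
    fit <- survival::coxph(
      stats::as.formula(paste("surv ~ `", f, "`", sep = "")),
      data = clinical
    )
    row_of(fit, "univariate")
  })
  multi_fit <- survival::coxph(
    stats::as.formula(paste("surv ~", paste0("`", factors, "`", collapse = " + "))),
    data = clinical
  )
  bind_rows(uni, row_of(multi_fit, "multivariate"))
}
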