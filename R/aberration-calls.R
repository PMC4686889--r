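#' Library-size normalize paired counts to log2(CPM + 1)
#'
#' Scales every column (sample arm) to counts per million before the log.
#' The paired differential-expression caller works on these values.
#'
#' @param x A [paired_matrix()] of raw counts (`layer = "expression"`).
#' @return A [paired_matrix()] of log2(CPM + 1) values, same layer tag.
#' @examples
#' counts <- matrix(rpois(6, 50), 3, 2,
#'                  dimnames = list(paste0("g", 1:3), c("p1", "p2")))
#' normalize_counts(paired_matrix(counts, counts))
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "paired_matrix"))
  if (x$layer != "expression") abort("normalize_counts expects the expression layer.")
  for (arm in c("tumor", "normal")) {
    cs <- colSums(x[[arm]])
    bad <- which(cs == 0)
    if (length(bad)) {
      abort(sprintf("all-zero %s column(s): %s", arm,
                    paste(x$pair_ids[bad], collapse = ", ")))
    }
  }
  cpm <- function(m) log2(sweep(m, 2, colSums(m), "/") * 1e6 + 1)
  paired_matrix(cpm(x$tumor), cpm(x$normal), layer = "expression")
}

# per-gene paired t-test on the row-wise differences of two matrices;
# zero-variance rows get p = 1 (reported in the `degenerate` attribute)
paired_t_rows <- function(tumor, normal) {
  n <- ncol(tumor)
  if (n < 3L) abort("paired testing needs at least 3 pairs.")
  d <- tumor - normal
  mu <- rowMeans(d)
  s <- row_sds(d)
  degen <- s == 0
  tstat <- ifelse(degen, 0, mu / (s / sqrt(n)))
  p <- 2 * pt(-abs(tstat), df = n - 1)
  p[degen] <- 1
  structure(tibble(gene_id = rownames(tumor), mean_diff = unname(mu),
                   statistic = unname(tstat), p_value = unname(p)),
            degenerate = sum(degen))
}

# shared caller skeleton: paired t on `test_values`, fold change from
# `fc_fun`, BH FDR, two-sided direction gate
call_layer <- function(layer, test_tumor, test_normal, fc,
                       dir_up, dir_down, fdr_max, fc_min) {
  check_scalar_number(fdr_max, "fdr_max", 0, 1)
  check_scalar_number(fc_min, "fc_min", 1)
  tt <- paired_t_rows(test_tumor, test_normal)
  if (attr(tt, "degenerate") > 0) {
    inform(sprintf("%d gene(s) with zero-variance paired differences in the %s layer; p set to 1.",
                   attr(tt, "degenerate"), layer))
  }
  res <- tt |>
    mutate(
      layer = layer,
      fold_change = unname(fc),
      fdr = p.adjust(.data$p_value, method = "BH"),
      direction = dplyr::case_when(
        .data$fdr < fdr_max & .data$fold_change >= fc_min ~ dir_up,
        .data$fdr < fdr_max & .data$fold_change <= 1 / fc_min ~ dir_down,
        TRUE ~ NA_character_
      ),
      passed = !is.na(.data$direction)
    ) |>
    select("gene_id", "layer", "direction", "fold_change",
           "p_value", "fdr", "passed")
  class(res) <- c("aberration_calls", class(res))
  res
}

#' Call differentially expressed genes between paired tumor/normal counts
#'
#' Per gene, a paired t-test on the log2(CPM + 1) tumor-minus-normal
#' differences with Benjamini-Hochberg FDR. The fold change is the ratio of
#' mean tumor CPM + 1 to mean normal CPM + 1. A gene passes as `up` when
#' `fdr < fdr_max` and fold change >= `fc_min`, as `down` when
#' `fdr < fdr_max` and fold change <= `1/fc_min`.
#'
#' @param x A [paired_matrix()] of raw counts.
#' @param fdr_max FDR gate (default 0.01).
#' @param fc_min Fold-change gate (default 2).
#' @return A tibble of class `aberration_calls`: `gene_id`, `layer`,
#'   `direction` (`up`/`down`/`NA`), `fold_change`, `p_value`, `fdr`,
#'   `passed`.
#' @export
call_deg <- function(x, fdr_max = 0.01, fc_min = 2) {
  stopifnot(inherits(x, "paired_matrix"))
  if (x$layer != "expression") abort("call_deg expects the expression layer.")
  logcpm <- normalize_counts(x)
  cpm <- function(m) sweep(m, 2, colSums(m), "/") * 1e6
  fc <- (rowMeans(cpm(x$tumor)) + 1) / (rowMeans(cpm(x$normal)) + 1)
  call_layer("expression", logcpm$tumor, logcpm$normal, fc,
             "up", "down", fdr_max, fc_min)
}

#' Call copy-number amplified and deleted genes
#'
#' Per gene, a paired t-test on the linear copy ratio `2^segmean` and a fold
#' change defined as the ratio of mean tumor to mean normal linear copy
#' ratio. `amp` requires `fdr < fdr_max` and fold change >= `fc_min`; `del`
#' the reciprocal gate.
#'
#' @param x A [paired_matrix()] of gene-level log2 segment means
#'   (`layer = "cnv_segmean"`), e.g. from [gene_level_cnv()].
#' @param fdr_max FDR gate (default 0.001).
#' @param fc_min Fold-change gate on the linear copy ratio (default 1.2).
#' @return An `aberration_calls` tibble with directions `amp`/`del`.
#' @export
call_cnv <- function(x, fdr_max = 0.001, fc_min = 1.2) {
  stopifnot(inherits(x, "paired_matrix"))
  if (x$layer != "cnv_segmean") abort("call_cnv expects the cnv_segmean layer.")
  lt <- 2^x$tumor
  ln <- 2^x$normal
  fc <- rowMeans(lt) / rowMeans(ln)
  call_layer("cnv", lt, ln, fc, "amp", "del", fdr_max, fc_min)
}

#' Call promoter hyper- and hypomethylated genes
#'
#' Per gene, a paired t-test on promoter beta values and a fold change
#' defined as the ratio of mean tumor beta to mean normal beta.
#'
#' @param x A [paired_matrix()] of promoter beta values
#'   (`layer = "methylation_beta"`), e.g. from [promoter_methylation()].
#' @param fdr_max FDR gate (default 0.001).
#' @param fc_min Fold-change gate on the beta ratio (default 1.5).
#' @return An `aberration_calls` tibble with directions `hyper`/`hypo`.
#' @export
call_methylation <- function(x, fdr_max = 0.001, fc_min = 1.5) {
  stopifnot(inherits(x, "paired_matrix"))
  if (x$layer != "methylation_beta") {
    abort("call_methylation expects the methylation_beta layer.")
  }
  fc <- rowMeans(x$tumor) / rowMeans(x$normal)
  call_layer("methylation", x$tumor, x$normal, fc,
             "hyper", "hypo", fdr_max, fc_min)
}

#' Call recurrently mutated genes by patient-level mutation rate
#'
#' A gene is kept when the fraction of distinct patients carrying at least
#' one mutation in it exceeds `rate_min` (strictly greater; 5% by default,
#' so 15/300 patients is not enough but 16/300 is). Duplicate rows for the
#' same gene and patient count once.
#'
#' @param mutations Data frame with columns `gene_id` and `sample_id`, one
#'   row per mutation call.
#' @param n_patients Cohort size used as the rate denominator.
#' @param rate_min Strict lower bound on the mutation rate (default 0.05).
#' @param roster Optional character vector of valid patient ids; a
#'   `sample_id` outside it is an error.
#' @return A tibble `gene_id`, `n_mutated`, `rate`, `passed`, sorted by
#'   decreasing rate, containing all genes seen in `mutations`.
#' @export
call_mutated <- function(mutations, n_patients, rate_min = 0.05,
                         roster = NULL) {
  if (!all(c("gene_id", "sample_id") %in% names(mutations))) {
    abort("`mutations` needs columns gene_id and sample_id.")
  }
  check_scalar_number(n_patients, "n_patients", 1)
  check_scalar_number(rate_min, "rate_min", 0, 1)
  if (!is.null(roster)) {
    alien <- setdiff(unique(mutations$sample_id), roster)
    if (length(alien)) {
      abort(paste0("sample id(s) not in roster: ",
                   paste(head(alien, 5), collapse = ", ")))
    }
  }
  mutations |>
    distinct(.data$gene_id, .data$sample_id) |>
    count(.data$gene_id, name = "n_mutated") |>
    mutate(rate = .data$n_mutated / n_patients,
           passed = .data$rate > rate_min) |>
    arrange(desc(.data$rate), .data$gene_id)
}

#' Volcano-style overview of one layer's aberration calls
#'
#' @param object An `aberration_calls` tibble.
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 FDR, passing calls
#'   coloured by direction.
#' @method autoplot aberration_calls
#' @export
autoplot.aberration_calls <- function(object, ...) {
  df <- mutate(object,
               status = ifelse(.data$passed, .data$direction, "ns"))
  ggplot(df, aes(x = log2(.data$fold_change),
                 y = -log10(pmax(.data$fdr, 1e-300)),
                 colour = .data$status)) +
    geom_point(alpha = 0.6, size = 0.9) +
    labs(x = "log2 fold change", y = "-log10 FDR",
         colour = NULL,
         title = sprintf("Aberration calls (%s layer)", object$layer[1])) +
    theme_minimal()
}
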