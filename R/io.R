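#' Read a gene-by-sample TSV into a paired matrix
#'
#' Expects a first column of gene ids and sample columns named
#' `<pair>_T` / `<pair>_N`.
#'
#' @param path TSV path.
#' @param layer Layer tag passed to [paired_matrix()].
#' @return A [paired_matrix()].
#' @export
read_paired_expression <- function(path, layer = "expression") {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  mat <- as.matrix(df[-1])
  rownames(mat) <- as.character(df[[1]])
  split_paired(mat, layer = layer)
}

#' Read a SEG segment table
#'
#' @param path Path to a tab-separated SEG file with header `Sample`,
#'   `Chromosome`, `Start`, `End`, `Num_Probes`, `Segment_Mean`.
#' @return A validated tibble; malformed rows raise an error naming the
#'   first offending data line.
#' @export
read_seg <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_seg(df)
}

#' Read a gene annotation TSV
#'
#' @param path TSV with columns `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`.
#' @return A [gene_annotation()] tibble (with derived `tss`).
#' @export
read_annotation <- function(path) {
  gene_annotation(readr::read_tsv(path, col_types = readr::cols(),
                                  progress = FALSE))
}

#' Read a methylation probe table TSV
#'
#' @param path TSV with `probe_id`, `chrom`, `pos`, then per-sample beta
#'   columns.
#' @return A tibble.
#' @export
read_probe_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' Read a mutation table TSV
#'
#' @param path TSV with at least `gene_id` and `sample_id`.
#' @return A tibble.
#' @export
read_mutations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("gene_id", "sample_id") %in% names(df))) {
    abort("mutation table needs columns gene_id and sample_id.")
  }
  df
}

#' Write a simulated multi-omic cohort to plain-text files
#'
#' Writes `expression.tsv`, `segments.seg`, `probes.tsv`, `mutations.tsv`,
#' `annotation.tsv` and `truth.json` under `dir`.
#'
#' @param cohort An `omic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "omic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr <- cohort$expression
  wide <- bind_cols(
    tibble(gene_id = expr$gene_ids),
    as_tibble(`colnames<-`(expr$tumor, paste0(expr$pair_ids, "_T"))),
    as_tibble(`colnames<-`(expr$normal, paste0(expr$pair_ids, "_N")))
  )
  readr::write_tsv(wide, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$seg, file.path(dir, "segments.seg"))
  readr::write_tsv(cohort$probes, file.path(dir, "probes.tsv"))
  readr::write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"))
  readr::write_tsv(select(cohort$annotation, -"tss"),
                   file.path(dir, "annotation.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Write a survival cohort to plain-text files
#'
#' Writes `expression.tsv` (gene by patient) and `clinical.tsv`.
#'
#' @param cohort A [survival_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_survival_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "survival_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wide <- bind_cols(tibble(gene_id = rownames(cohort$expression)),
                    as_tibble(cohort$expression))
  readr::write_tsv(wide, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  invisible(dir)
}

#' Read a survival cohort from plain-text files
#'
#' @param dir Directory holding `expression.tsv` and `clinical.tsv` as
#'   written by [write_survival_cohort()].
#' @param cohort_id Label; defaults to the directory name.
#' @return A [survival_cohort()].
#' @export
read_survival_cohort <- function(dir, cohort_id = basename(dir)) {
  df <- readr::read_tsv(file.path(dir, "expression.tsv"),
                        col_types = readr::cols(), progress = FALSE)
  mat <- as.matrix(df[-1])
  rownames(mat) <- as.character(df[[1]])
  clin <- readr::read_tsv(file.path(dir, "clinical.tsv"),
                          col_types = readr::cols(), progress = FALSE)
  survival_cohort(mat, clin, cohort_id = cohort_id)
}

#' Kaplan-Meier curves for a median-split risk comparison
#'
#' @param split_result Output of [median_split_logrank()] (its
#'   `"assignments"` attribute provides the groups).
#' @param cohort The [survival_cohort()] the split was computed on.
#' @return A ggplot of the two survival curves with the log-rank p in the
#'   subtitle.
#' @export
plot_km <- function(split_result, cohort) {
  asg <- attr(split_result, "assignments")
  if (is.null(asg)) abort("`split_result` lacks the assignments attribute.")
  df <- dplyr::inner_join(cohort$clinical, asg, by = "patient_id")
  fit <- survival::survfit(
    survival::Surv(os_time, os_event) ~ risk_group, data = df
  )
  strata <- rep(sub("^risk_group=", "", names(fit$strata)),
                fit$strata)
  curves <- tibble(time = fit$time, surv = fit$surv, group = strata) |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, surv = 1), .x)) |>
    ungroup()
  ggplot(curves, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    labs(x = "time", y = "overall survival",
         colour = "risk group",
         subtitle = sprintf("log-rank p = %.3g", split_result$logrank_p)) +
    ylim(0, 1) +
    theme_minimal()
}
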