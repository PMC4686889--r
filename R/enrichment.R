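#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated, `name`, `description`,
#' then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(head(short, 5), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names in GMT.")
  sets
}

#' Over-representation test of a query gene list against gene sets
#'
#' Classic one-sided over-representation analysis: for each set, the
#' upper-tail hypergeometric probability of the observed query/set overlap
#' given the background universe, with multiple-testing correction across
#' sets. Genes outside the background are ignored on both sides.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param gene_sets Named list of character vectors, e.g. from
#'   [read_gmt()].
#' @param background Character vector: the gene universe.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @param alpha Significance level used to flag `significant` (default 0.05).
#' @return A tibble sorted by ascending p: `set`, `set_size`, `query_size`,
#'   `overlap`, `p_value`, `p_adjusted`, `significant`.
#' @export
gene_set_enrichment <- function(query, gene_sets, background,
                                correction = c("bonferroni", "bh"),
                                alpha = 0.05) {
  correction <- match.arg(correction)
  background <- unique(background)
  if (!length(background)) abort("`background` must be non-empty.")
  stray <- setdiff(query, background)
  if (length(stray)) {
    abort(paste0("query gene(s) outside the background: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  query <- unique(query)
  N <- length(background)
  M <- length(query)
  res <- purrr::imap_dfr(gene_sets, function(set, nm) {
    in_bg <- intersect(set, background)
    K <- length(in_bg)
    x <- length(intersect(in_bg, query))
    tibble(set = nm, set_size = K, query_size = M, overlap = x,
           p_value = hypergeometric_tail(N, K, M, x))
  })
  method <- if (correction == "bh") "BH" else "bonferroni"
  res |>
    mutate(p_adjusted = p.adjust(.data$p_value, method = method),
           significant = .data$p_adjusted < alpha) |>
    arrange(.data$p_value, .data$set)
}
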