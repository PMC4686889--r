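#' Paired tumor/normal omic matrix
#'
#' Container for one omic layer measured on matched tumor and adjacent-normal
#' samples from the same patients: a genes-by-pairs tumor matrix and a
#' normal matrix of identical shape. This is the unit every per-layer
#' aberration caller consumes.
#'
#' @param tumor,normal Numeric matrices, genes in rows, patient pairs in
#'   columns, identical dimensions. Row names are gene ids; column names are
#'   pair ids (both required).
#' @param layer One of `"expression"` (raw counts or log2 CPM),
#'   `"cnv_segmean"` (gene-level log2 copy-ratio segment means) or
#'   `"methylation_beta"` (promoter beta values in \[0, 1\]).
#'
#' @return An object of class `paired_matrix` with elements `tumor`,
#'   `normal`, `gene_ids`, `pair_ids` and `layer`.
#' @examples
#' t <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("p1", "p2")))
#' paired_matrix(t, t, layer = "cnv_segmean")
#' @export
paired_matrix <- function(tumor, normal,
                          layer = c("expression", "cnv_segmean",
                                    "methylation_beta")) {
  layer <- match.arg(layer)
  if (!is.matrix(tumor) || !is.matrix(normal) || !is.numeric(tumor) ||
      !is.numeric(normal)) {
    abort("`tumor` and `normal` must be numeric matrices.")
  }
  if (!identical(dim(tumor), dim(normal))) {
    abort("`tumor` and `normal` must have identical dimensions.")
  }
  # R drops the rowname vector of a 0-row subset to NULL; normalize it
  norm_names <- function(nm, extent) nm %||% (if (extent == 0) character(0))
  gene_ids <- norm_names(rownames(tumor), nrow(tumor))
  pair_ids <- norm_names(colnames(tumor), ncol(tumor))
  if (is.null(gene_ids) || is.null(pair_ids)) {
    abort("`tumor` must carry gene ids as row names and pair ids as column names.")
  }
  if (anyDuplicated(gene_ids)) abort("gene ids must be unique.")
  if (!identical(norm_names(rownames(normal), nrow(normal)), gene_ids) ||
      !identical(norm_names(colnames(normal), ncol(normal)), pair_ids)) {
    abort("`normal` dimnames must match `tumor` dimnames.")
  }
  if (anyNA(tumor) || anyNA(normal)) {
    abort("paired matrices must not contain missing values; drop incomplete genes first.")
  }
  if (length(tumor)) {
    if (layer == "methylation_beta" &&
        (min(tumor, normal) < 0 || max(tumor, normal) > 1)) {
      abort("methylation beta values must lie in [0, 1].")
    }
    if (layer == "expression" && min(tumor, normal) < 0) {
      abort("expression counts must be non-negative.")
    }
  }
  structure(
    list(tumor = tumor, normal = normal, gene_ids = gene_ids,
         pair_ids = pair_ids, layer = layer),
    class = "paired_matrix"
  )
}

#' @export
print.paired_matrix <- function(x, ...) {
  cat(sprintf("<paired_matrix> layer=%s: %d genes x %d pairs\n",
              x$layer, length(x$gene_ids), length(x$pair_ids)))
  invisible(x)
}

#' @export
dim.paired_matrix <- function(x) dim(x$tumor)

#' Tidy a paired matrix into long form
#'
#' @param x A [paired_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `pair_id`, `tumor`, `normal`.
#' @method tidy paired_matrix
#' @export
tidy.paired_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(x$gene_ids, times = length(x$pair_ids)),
    pair_id = rep(x$pair_ids, each = length(x$gene_ids)),
    tumor = as.vector(x$tumor),
    normal = as.vector(x$normal)
  )
}

#' Swap the tumor and normal arms of a paired matrix
#'
#' Useful for antisymmetry checks: callers must map up to down, amp to del
#' and hyper to hypo under this swap, with identical FDRs.
#'
#' @param x A [paired_matrix()].
#' @return A [paired_matrix()] with arms exchanged.
#' @export
swap_arms <- function(x) {
  stopifnot(inherits(x, "paired_matrix"))
  paired_matrix(x$normal, x$tumor, layer = x$layer)
}

#' Gene annotation table
#'
#' Validates a BED-like gene annotation and derives the transcription start
#' site from strand: the TSS is `tx_start` on the + strand and `tx_end` on
#' the - strand.
#'
#' @param df Data frame with columns `gene_id`, `chrom`, `strand` (`"+"` or
#'   `"-"`), `tx_start`, `tx_end` (1-based, inclusive).
#' @return A tibble with the input columns plus `tss`.
#' @examples
#' gene_annotation(data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
#'                            tx_start = 100, tx_end = 500))
#' @export
gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (anyDuplicated(df$gene_id)) abort("annotation gene_ids must be unique.")
  if (!all(df$strand %in% c("+", "-"))) abort("strand must be '+' or '-'.")
  if (any(df$tx_start > df$tx_end)) abort("tx_start must be <= tx_end.")
  mutate(df, tss = ifelse(.data$strand == "+", .data$tx_start, .data$tx_end))
}
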