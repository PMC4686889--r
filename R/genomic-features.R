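#' Map copy-number segments to a gene-level matrix
#'
#' For every gene and sample, the length-weighted mean of the segment means
#' of all segments overlapping the gene body `[tx_start, tx_end]`
#' (1-based, inclusive). Genes covered by no segment in some sample are
#' dropped entirely, with the count reported, so downstream paired tests
#' never see missing values.
#'
#' @param seg Segment table with columns `Sample`, `Chromosome`, `Start`,
#'   `End`, `Segment_Mean` (a `Num_Probes` column is tolerated and ignored).
#'   Segments must not overlap within a sample.
#' @param annotation A [gene_annotation()] table.
#' @param paired If `TRUE` (default) samples named `<pair>_T` / `<pair>_N`
#'   are split into a [paired_matrix()]; if `FALSE` the raw gene-by-sample
#'   matrix is returned.
#' @return A [paired_matrix()] with `layer = "cnv_segmean"`, or a matrix.
#' @export
gene_level_cnv <- function(seg, annotation, paired = TRUE) {
  seg <- validate_seg(seg)
  annotation <- gene_annotation(annotation)

  samples <- sort(unique(seg$Sample))
  mat <- matrix(NA_real_, nrow(annotation), length(samples),
                dimnames = list(annotation$gene_id, samples))
  weight <- matrix(0, nrow(annotation), length(samples),
                   dimnames = list(annotation$gene_id, samples))

  gene_gr <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$tx_start, annotation$tx_end)
  )
  seg_gr <- GenomicRanges::GRanges(
    seg$Chromosome, IRanges::IRanges(seg$Start, seg$End)
  )
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(annotation$tx_end[qh], seg$End[sh]) -
    pmax(annotation$tx_start[qh], seg$Start[sh]) + 1
  contrib <- tibble(
    gene_id = annotation$gene_id[qh],
    sample = seg$Sample[sh],
    w = as.numeric(ov),
    wx = as.numeric(ov) * seg$Segment_Mean[sh]
  ) |>
    group_by(.data$gene_id, .data$sample) |>
    summarise(w = sum(.data$w), wx = sum(.data$wx), .groups = "drop")

  idx <- cbind(match(contrib$gene_id, annotation$gene_id),
               match(contrib$sample, samples))
  mat[idx] <- contrib$wx / contrib$w
  weight[idx] <- contrib$w

  covered <- rowSums(is.na(mat)) == 0
  if (any(!covered)) {
    inform(sprintf("gene_level_cnv: dropped %d gene(s) lacking segment coverage in at least one sample.",
                   sum(!covered)))
  }
  mat <- mat[covered, , drop = FALSE]
  if (!paired) return(mat)
  split_paired(mat, layer = "cnv_segmean")
}

validate_seg <- function(seg) {
  need <- c("Sample", "Chromosome", "Start", "End", "Segment_Mean")
  missing_cols <- setdiff(need, names(seg))
  if (length(missing_cols)) {
    abort(paste0("segment table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  seg <- as_tibble(seg)
  bad <- which(!is.finite(seg$Start) | !is.finite(seg$End) |
                 !is.finite(seg$Segment_Mean) | seg$Start > seg$End)
  if (length(bad)) {
    abort(sprintf("malformed segment row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  # overlap within a sample breaks the weighted mean's interpretation
  chk <- seg |>
    arrange(.data$Sample, .data$Chromosome, .data$Start) |>
    group_by(.data$Sample, .data$Chromosome) |>
    summarise(ok = all(diff(.data$Start) > 0 &
                         .data$End[-n()] < .data$Start[-1]) || n() == 1L,
              .groups = "drop")
  if (!all(chk$ok)) {
    abort("segments overlap within a sample; resolve before gene mapping.")
  }
  seg
}

# split a gene x sample matrix with <pair>_T / <pair>_N columns into arms
split_paired <- function(mat, layer) {
  cols <- colnames(mat)
  t_cols <- grep("_T$", cols, value = TRUE)
  pairs <- sub("_T$", "", t_cols)
  n_cols <- paste0(pairs, "_N")
  if (!length(pairs) || !all(n_cols %in% cols)) {
    abort("paired splitting needs matched '<pair>_T' and '<pair>_N' columns.")
  }
  tum <- mat[, t_cols, drop = FALSE]
  nor <- mat[, n_cols, drop = FALSE]
  colnames(tum) <- colnames(nor) <- pairs
  paired_matrix(tum, nor, layer = layer)
}

#' Strand-aware promoter windows
#'
#' The promoter is the window from 1,000 bp upstream of the transcription
#' start site to 300 bp downstream of it, in the direction of transcription:
#' `[tss - 1000, tss + 300]` on the + strand and `[tss - 300, tss + 1000]`
#' on the - strand, both ends inclusive.
#'
#' @param annotation A [gene_annotation()] table.
#' @param upstream,downstream Window extent in bp (defaults 1000 and 300).
#' @return The annotation tibble with `prom_start`, `prom_end` added.
#' @export
promoter_windows <- function(annotation, upstream = 1000, downstream = 300) {
  annotation <- gene_annotation(annotation)
  mutate(
    annotation,
    prom_start = ifelse(.data$strand == "+",
                        .data$tss - upstream, .data$tss - downstream),
    prom_end = ifelse(.data$strand == "+",
                      .data$tss + downstream, .data$tss + upstream)
  )
}

#' Aggregate methylation probes to gene promoter level
#'
#' Each gene's methylation level per sample is the mean beta value of all
#' probes falling inside its promoter window (see [promoter_windows()]).
#' A probe may contribute to several genes with overlapping promoters.
#' Genes without any in-window probe are dropped with the count reported.
#'
#' @param probes Probe table: `probe_id`, `chrom`, `pos` (1-based), then one
#'   numeric beta column per sample.
#' @param annotation A [gene_annotation()] table.
#' @param upstream,downstream Promoter extent in bp, passed to
#'   [promoter_windows()].
#' @param paired As in [gene_level_cnv()].
#' @return A [paired_matrix()] with `layer = "methylation_beta"`, or a
#'   gene-by-sample matrix.
#' @export
promoter_methylation <- function(probes, annotation,
                                 upstream = 1000, downstream = 300,
                                 paired = TRUE) {
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(probes))) {
    abort("probe table needs columns probe_id, chrom, pos, then sample betas.")
  }
  sample_cols <- setdiff(names(probes), need)
  if (!length(sample_cols)) abort("probe table has no sample beta columns.")
  beta <- as.matrix(probes[sample_cols])
  if (!is.numeric(beta)) abort("beta columns must be numeric.")
  if (anyNA(beta) || min(beta) < 0 || max(beta) > 1) {
    abort("beta values must lie in [0, 1] with no missing entries.")
  }
  ann <- promoter_windows(annotation, upstream, downstream)

  rows <- vector("list", nrow(ann))
  for (ch in unique(ann$chrom)) {
    p_idx <- which(probes$chrom == ch)
    ord <- p_idx[order(probes$pos[p_idx])]
    pos_sorted <- probes$pos[ord]
    g_idx <- which(ann$chrom == ch)
    lo <- findInterval(ann$prom_start[g_idx] - 1L, pos_sorted) + 1L
    hi <- findInterval(ann$prom_end[g_idx], pos_sorted)
    for (k in seq_along(g_idx)) {
      if (lo[k] <= hi[k]) rows[[g_idx[k]]] <- ord[lo[k]:hi[k]]
    }
  }
  n_probes <- lengths(rows)
  if (any(n_probes == 0)) {
    inform(sprintf("promoter_methylation: dropped %d gene(s) with no promoter probe.",
                   sum(n_probes == 0)))
  }
  keep <- which(n_probes > 0)
  mat <- matrix(numeric(0), 0, length(sample_cols))
  if (length(keep)) {
    mat <- do.call(rbind, lapply(keep, function(i) {
      colMeans(beta[rows[[i]], , drop = FALSE])
    }))
  }
  dimnames(mat) <- list(ann$gene_id[keep], sample_cols)
  if (!paired) return(mat)
  split_paired(mat, layer = "methylation_beta")
}

#' Segment gain-or-loss (SGOL) scores
#'
#' Per unit (gene or bin), the sum across samples of positive values (gain)
#' and of negative values (loss). Gains are therefore >= 0 and losses <= 0
#' by construction.
#'
#' @param x A numeric units-by-samples matrix (e.g. from
#'   `gene_level_cnv(..., paired = FALSE)`), or a [paired_matrix()] whose
#'   tumor arm is scored.
#' @return A tibble `unit_id`, `sgol_gain`, `sgol_loss`.
#' @examples
#' m <- matrix(c(0.3, -0.2, 0.1), 1, 3, dimnames = list("g1", NULL))
#' sgol_scores(m) # gain 0.4, loss -0.2
#' @export
sgol_scores <- function(x) {
  if (inherits(x, "paired_matrix")) x <- x$tumor
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix.")
  tibble(
    unit_id = rownames(x) %||% as.character(seq_len(nrow(x))),
    sgol_gain = unname(rowSums(pmax(x, 0))),
    sgol_loss = unname(rowSums(pmin(x, 0)))
  )
}

#' Bin methylation probes along the genome
#'
#' Probes are assigned to contiguous fixed-width bins, half-open
#' `[k*bin_size, (k+1)*bin_size)` in 0-based coordinates, so a 1-based
#' position `p` lands in bin `floor((p - 1) / bin_size)` (position 500,000
#' is still in bin 0 at the default width). Per bin, the median and 75th
#' percentile of the per-probe mean beta across samples are reported.
#'
#' @param probes Probe table as in [promoter_methylation()].
#' @param bin_size Bin width in bp (default 500,000).
#' @return A tibble `chrom`, `bin`, `bin_start` (0-based), `bin_end`,
#'   `n_probes`, `median_beta`, `q75_beta`.
#' @export
bin_methylation <- function(probes, bin_size = 500000) {
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(probes))) {
    abort("probe table needs columns probe_id, chrom, pos, then sample betas.")
  }
  check_scalar_number(bin_size, "bin_size", 1)
  sample_cols <- setdiff(names(probes), need)
  probe_mean <- rowMeans(as.matrix(probes[sample_cols]))
  tibble(chrom = probes$chrom,
         bin = floor((probes$pos - 1) / bin_size),
         beta = probe_mean) |>
    group_by(.data$chrom, .data$bin) |>
    summarise(n_probes = n(),
              median_beta = median(.data$beta),
              q75_beta = as.numeric(quantile(.data$beta, 0.75)),
              .groups = "drop") |>
    mutate(bin_start = .data$bin * bin_size,
           bin_end = (.data$bin + 1) * bin_size) |>
    select("chrom", "bin", "bin_start", "bin_end",
           "n_probes", "median_beta", "q75_beta") |>
    arrange(.data$chrom, .data$bin)
}
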