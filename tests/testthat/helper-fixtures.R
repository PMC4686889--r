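# fixture builders shared across test files; everything is generated in code

# paired matrix with constant baseline and optional per-gene tumor effects
toy_paired <- function(n_genes = 5, n_pairs = 4, base = 100,
                       tumor_effect = NULL, layer = "expression",
                       noise_sd = 0, seed = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  pairs <- paste0("p", seq_len(n_pairs))
  normal <- matrix(base, n_genes, n_pairs, dimnames = list(genes, pairs))
  tumor <- normal
  if (!is.null(tumor_effect)) {
    for (g in names(tumor_effect)) tumor[g, ] <- tumor[g, ] * tumor_effect[[g]]
  }
  if (noise_sd > 0) {
    tumor <- tumor + matrix(rnorm(length(tumor), sd = noise_sd), n_genes)
    normal <- normal + matrix(rnorm(length(normal), sd = noise_sd), n_genes)
  }
  paired_matrix(tumor, normal, layer = layer)
}

# minimal single-chromosome annotation
toy_annotation <- function(n = 3, strand = "+", chrom = "chr1",
                           start = 10000, len = 5000, gap = 20000) {
  tibble::tibble(
    gene_id = paste0("g", seq_len(n)),
    chrom = chrom,
    strand = rep_len(strand, n),
    tx_start = start + (seq_len(n) - 1) * (len + gap),
    tx_end = start + (seq_len(n) - 1) * (len + gap) + len - 1
  )
}

# aberration-call tibble rows built by hand
toy_calls <- function(gene_id, layer, direction, passed = TRUE) {
  tibble::tibble(
    gene_id = gene_id, layer = layer, direction = direction,
    fold_change = ifelse(direction %in% c("up", "amp", "hyper"), 3, 1 / 3),
    p_value = 1e-6, fdr = 1e-5, passed = passed
  )
}

# ring (cycle) network on n nodes
ring_network <- function(n = 12, prefix = "r") {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  gene_network(data.frame(from = ids, to = ids[c(2:n, 1)]))
}

# d-dimensional hypercube: vertex-transitive with strong mixing
hypercube_network <- function(d = 8) {
  n <- 2^d
  ids <- sprintf("h%03d", seq_len(n))
  edges <- do.call(rbind, lapply(seq_len(d), function(b) {
    data.frame(from = ids, to = ids[bitwXor(0:(n - 1), 2^(b - 1)) + 1])
  }))
  gene_network(edges)
}

# connected scale-free test graph
random_connected_network <- function(n, m = 2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%04d", seq_len(n))
  g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  gene_network(data.frame(from = ids[el[, 1]], to = ids[el[, 2]]))
}

# independent oracle: upper-tail hypergeometric by exhaustive enumeration
# of all size-M draws from 1..N against the fixed set 1..K
enumerate_tail <- function(N, K, M, x) {
  if (M == 0 || K == 0) return(as.numeric(x == 0))
  draws <- utils::combn(N, M)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= x)
}

# independent oracle: per-base mean of covering segments over a gene span
brute_force_gene_cnv <- function(seg_one_sample, tx_start, tx_end) {
  vals <- rep(NA_real_, tx_end - tx_start + 1)
  for (i in seq_len(nrow(seg_one_sample))) {
    lo <- max(seg_one_sample$Start[i], tx_start)
    hi <- min(seg_one_sample$End[i], tx_end)
    if (lo <= hi) vals[(lo:hi) - tx_start + 1] <- seg_one_sample$Segment_Mean[i]
  }
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

# tiny survival cohort with a deterministic hazard ordering
toy_survival_cohort <- function(n = 40, n_genes = 3, seed = 1,
                                cohort_id = "toy") {
  set.seed(seed)
  genes <- paste0("s", seq_len(n_genes))
  pid <- sprintf("pt%03d", seq_len(n))
  x <- matrix(rnorm(n_genes * n), n_genes, n, dimnames = list(genes, pid))
  eta <- x[1, ]
  time <- -log(runif(n)) / (0.01 * exp(eta))
  survival_cohort(
    x,
    tibble::tibble(patient_id = pid, os_time = unname(time), os_event = 1L,
                   stage = rep_len(c("I", "II", "III", "IV"), n)),
    cohort_id = cohort_id
  )
}
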