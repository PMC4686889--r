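#' Configuration for the paired multi-omic cohort simulator
#'
#' Collects all knobs of [simulate_cohort()] with validated defaults. The
#' defaults describe a mid-sized paired tumor/normal cohort: 2,000 genes,
#' 32 pairs, and 50 implanted genes per aberration class at effect sizes a
#' paired design can be expected to detect (4-fold expression change, +/-
#' 0.5 log2 copy-ratio shift, promoter beta moving between 0.2 and 0.6,
#' somatic mutation rate lifted from 0.2% to 40% of patients).
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_pairs Number of tumor/normal pairs (>= 3 for paired testing).
#' @param n_deg_up,n_deg_down,n_amp,n_del,n_hyper,n_hypo,n_mutated Implant
#'   counts per class. Set all to 0 for a null cohort.
#' @param consistent_frac Fraction of each non-expression implant class
#'   drawn from the sign-consistent differential-expression implants
#'   (amplified genes from the up-regulated set, deleted and
#'   hypermethylated genes from the down-regulated set, hypomethylated
#'   from the up-regulated set, mutated from either), so the candidate
#'   groups the pipeline forms downstream are non-trivially populated
#'   (default 0.5). The remainder of each class is drawn from otherwise
#'   unimplanted genes.
#' @param lfc Implanted absolute log2 fold change for expression (default 2).
#' @param count_meanlog,count_sdlog Log-normal distribution of baseline
#'   gene mean counts.
#' @param nb_dispersion Negative-binomial dispersion (1/size; > 0).
#' @param seg_shift Log2 segment-mean shift for amplification (deletion uses
#'   the negative; default 0.5).
#' @param seg_noise_sd SD of Gaussian noise on per-sample segment means.
#' @param meth_low,meth_high The two promoter beta means used for implants
#'   (normal/tumor for hypermethylation, reversed for hypomethylation).
#' @param beta_precision Precision (a + b) of the Beta draws around a mean.
#' @param mut_rate_background,mut_rate_implanted Per-gene per-patient
#'   somatic mutation probabilities, in `[0, 1]`.
#' @param n_chroms Chromosomes over which genes are laid out.
#' @param seed RNG seed; identical seeds give identical cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_pairs = 32,
                       n_deg_up = 50, n_deg_down = 50,
                       n_amp = 50, n_del = 50,
                       n_hyper = 50, n_hypo = 50, n_mutated = 50,
                       consistent_frac = 0.5,
                       lfc = 2,
                       count_meanlog = log(150), count_sdlog = 1.2,
                       nb_dispersion = 0.1,
                       seg_shift = 0.5, seg_noise_sd = 0.15,
                       meth_low = 0.2, meth_high = 0.6,
                       beta_precision = 50,
                       mut_rate_background = 0.002,
                       mut_rate_implanted = 0.4,
                       n_chroms = 5,
                       seed = NULL) {
  cfg <- list(
    n_genes = n_genes, n_pairs = n_pairs,
    n_deg_up = n_deg_up, n_deg_down = n_deg_down, n_amp = n_amp,
    n_del = n_del, n_hyper = n_hyper, n_hypo = n_hypo,
    n_mutated = n_mutated, consistent_frac = consistent_frac, lfc = lfc,
    count_meanlog = count_meanlog, count_sdlog = count_sdlog,
    nb_dispersion = nb_dispersion, seg_shift = seg_shift,
    seg_noise_sd = seg_noise_sd, meth_low = meth_low,
    meth_high = meth_high, beta_precision = beta_precision,
    mut_rate_background = mut_rate_background,
    mut_rate_implanted = mut_rate_implanted,
    n_chroms = n_chroms, seed = seed
  )
  check_scalar_number(n_genes, "n_genes", 1)
  check_scalar_number(n_pairs, "n_pairs", 3)
  for (nm in c("n_deg_up", "n_deg_down", "n_amp", "n_del", "n_hyper",
               "n_hypo", "n_mutated")) {
    check_scalar_number(cfg[[nm]], nm, 0)
  }
  check_scalar_number(nb_dispersion, "nb_dispersion", 0, strict_lower = TRUE)
  check_scalar_number(seg_noise_sd, "seg_noise_sd", 0, strict_lower = TRUE)
  check_scalar_number(beta_precision, "beta_precision", 0, strict_lower = TRUE)
  for (nm in c("mut_rate_background", "mut_rate_implanted",
               "consistent_frac")) {
    check_scalar_number(cfg[[nm]], nm, 0, 1)
  }
  for (nm in c("meth_low", "meth_high")) {
    check_scalar_number(cfg[[nm]], nm, 0, 1, strict_lower = TRUE,
                        strict_upper = TRUE)
  }
  check_scalar_number(n_chroms, "n_chroms", 1)
  n_fresh_needed <- n_deg_up + n_deg_down +
    sum(vapply(c(n_amp, n_del, n_hyper, n_hypo, n_mutated),
               function(nc) nc - round(consistent_frac * nc), numeric(1)))
  if (n_fresh_needed > n_genes) {
    abort("`n_genes` is too small for the requested implant sets.")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a paired tumor/normal multi-omic cohort with known truth
#'
#' Generates, from one seed, a coherent cohort across four layers:
#' * a gene annotation laying genes end to end on `n_chroms` chromosomes
#'   with random strand;
#' * RNA-seq counts: negative binomial with log-normal baseline means and
#'   common dispersion; implanted genes get a multiplicative `2^lfc`
#'   (or `2^-lfc`) effect on the tumor mean;
#' * a SEG table: one segment per gene per sample arm with Gaussian noise
#'   on the segment mean; amplification/deletion implants shift the tumor
#'   segment mean by `+/- seg_shift`;
#' * a methylation probe table: `Poisson(3) + 1` probes per promoter
#'   window, beta values drawn from Beta distributions around the
#'   gene/arm mean, implants moving the tumor mean between `meth_low` and
#'   `meth_high`;
#' * a mutation table: Bernoulli per gene and patient at the background
#'   rate, lifted for implanted genes.
#' Implant classes are disjoint gene sets recorded in `truth`.
#'
#' @param config A [sim_config()].
#' @return An object of class `omic_cohort`: list with `annotation`,
#'   `expression` (raw-count [paired_matrix()]), `seg`, `probes`,
#'   `mutations`, `truth` and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must come from sim_config().")
  }
  use_seed(config$seed)
  n_g <- config$n_genes
  n_p <- config$n_pairs
  genes <- sprintf("g%04d", seq_len(n_g))
  pairs <- sprintf("p%03d", seq_len(n_p))
  samples <- c(paste0(pairs, "_T"), paste0(pairs, "_N"))

  # --- annotation: genes laid out end to end, random strand
  chrom <- paste0("chr", rep_len(seq_len(config$n_chroms), n_g))
  ord <- order(chrom)
  lens <- sample(2000:20000, n_g, replace = TRUE)
  gaps <- sample(5000:20000, n_g, replace = TRUE)
  start <- integer(n_g)
  pos_by_chr <- setNames(rep(10000L, config$n_chroms),
                         paste0("chr", seq_len(config$n_chroms)))
  for (i in ord) {
    start[i] <- pos_by_chr[[chrom[i]]]
    pos_by_chr[[chrom[i]]] <- start[i] + lens[i] + gaps[i]
  }
  annotation <- gene_annotation(tibble(
    gene_id = genes, chrom = chrom,
    strand = sample(c("+", "-"), n_g, replace = TRUE),
    tx_start = start, tx_end = start + lens - 1L
  ))

  # --- implant assignment: expression sets first, then each other class
  # draws `consistent_frac` of its members from the sign-consistent
  # expression implants and the rest from untouched genes
  n_expr <- config$n_deg_up + config$n_deg_down
  expr_pick <- sample(genes, n_expr)
  truth <- list(
    deg_up = sort(head(expr_pick, config$n_deg_up)),
    deg_down = sort(utils::tail(expr_pick, config$n_deg_down))
  )
  free <- setdiff(genes, expr_pick)
  partner <- list(amp = truth$deg_up, del = truth$deg_down,
                  hyper = truth$deg_down, hypo = truth$deg_up,
                  mutated = expr_pick)
  n_other <- c(amp = config$n_amp, del = config$n_del,
               hyper = config$n_hyper, hypo = config$n_hypo,
               mutated = config$n_mutated)
  for (cls in names(n_other)) {
    n_cls <- n_other[[cls]]
    k <- min(round(config$consistent_frac * n_cls), length(partner[[cls]]))
    cons <- if (k > 0) sample(partner[[cls]], k) else character(0)
    n_free <- n_cls - length(cons)
    if (n_free > length(free)) {
      abort("`n_genes` is too small for the requested implant sets.")
    }
    fresh <- if (n_free > 0) sample(free, n_free) else character(0)
    free <- setdiff(free, fresh)
    truth[[cls]] <- sort(c(cons, fresh))
  }
  truth <- truth[c("deg_up", "deg_down", "amp", "del",
                   "hyper", "hypo", "mutated")]

  # --- expression counts
  base_mu <- rlnorm(n_g, config$count_meanlog, config$count_sdlog)
  effect <- rep(1, n_g)
  effect[genes %in% truth$deg_up] <- 2^config$lfc
  effect[genes %in% truth$deg_down] <- 2^-config$lfc
  size <- 1 / config$nb_dispersion
  draw_counts <- function(mu_vec) {
    matrix(rnbinom(n_g * n_p, mu = rep(mu_vec, n_p), size = size),
           n_g, n_p, dimnames = list(genes, pairs))
  }
  expr <- paired_matrix(draw_counts(base_mu * effect), draw_counts(base_mu),
                        layer = "expression")

  # --- copy-number segments (one per gene per sample arm)
  cn_shift <- rep(0, n_g)
  cn_shift[genes %in% truth$amp] <- config$seg_shift
  cn_shift[genes %in% truth$del] <- -config$seg_shift
  seg <- tibble(
    Sample = rep(samples, each = n_g),
    Chromosome = rep(annotation$chrom, length(samples)),
    Start = rep(annotation$tx_start, length(samples)),
    End = rep(annotation$tx_end, length(samples)),
    Num_Probes = rep(pmax(1L, as.integer(round(lens / 1000))),
                     length(samples)),
    # tumor samples come first in `samples`; only they carry the implant
    Segment_Mean = rnorm(n_g * length(samples), sd = config$seg_noise_sd) +
      c(rep(cn_shift, n_p), rep(0, n_g * n_p))
  )

  # --- methylation probes
  windows <- promoter_windows(annotation)
  n_probes <- rpois(n_g, 3) + 1L
  probe_gene <- rep(seq_len(n_g), n_probes)
  probe_pos <- as.integer(floor(runif(
    length(probe_gene),
    windows$prom_start[probe_gene],
    windows$prom_end[probe_gene] + 1
  )))
  m_normal <- runif(n_g, 0.15, 0.65)
  m_tumor <- m_normal
  m_normal[genes %in% truth$hyper] <- config$meth_low
  m_tumor[genes %in% truth$hyper] <- config$meth_high
  m_normal[genes %in% truth$hypo] <- config$meth_high
  m_tumor[genes %in% truth$hypo] <- config$meth_low
  kappa <- config$beta_precision
  draw_beta <- function(m_vec) {
    mm <- m_vec[probe_gene]
    matrix(rbeta(length(probe_gene) * n_p,
                 shape1 = rep(mm, n_p) * kappa,
                 shape2 = (1 - rep(mm, n_p)) * kappa),
           length(probe_gene), n_p)
  }
  beta_t <- draw_beta(m_tumor)
  beta_n <- draw_beta(m_normal)
  colnames(beta_t) <- paste0(pairs, "_T")
  colnames(beta_n) <- paste0(pairs, "_N")
  probes <- bind_cols(
    tibble(probe_id = sprintf("cg%06d", seq_along(probe_gene)),
           chrom = annotation$chrom[probe_gene],
           pos = probe_pos),
    as_tibble(beta_t), as_tibble(beta_n)
  )

  # --- somatic mutations
  rate <- rep(config$mut_rate_background, n_g)
  rate[genes %in% truth$mutated] <- config$mut_rate_implanted
  hit <- matrix(rbinom(n_g * n_p, 1, rep(rate, n_p)), n_g, n_p)
  hit_idx <- which(hit == 1, arr.ind = TRUE)
  mutations <- tibble(gene_id = genes[hit_idx[, 1]],
                      sample_id = pairs[hit_idx[, 2]]) |>
    arrange(.data$gene_id, .data$sample_id)

  structure(
    list(annotation = annotation, expression = expr, seg = seg,
         probes = probes, mutations = mutations,
         truth = truth, config = config),
    class = "omic_cohort"
  )
}

#' @export
print.omic_cohort <- function(x, ...) {
  cat(sprintf(
    "<omic_cohort> %d genes x %d pairs; %d implanted genes; %d mutation rows\n",
    x$config$n_genes, x$config$n_pairs,
    length(unlist(x$truth)), nrow(x$mutations)
  ))
  invisible(x)
}
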