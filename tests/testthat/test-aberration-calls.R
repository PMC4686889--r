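test_that("normalize_counts matches the closed-form CPM transform", {
  # single gene holding the whole library: CPM is exactly 1e6
  m <- matrix(c(999999, 10), 2, 1, dimnames = list(c("g1", "g2"), "p1"))
  m[2, 1] <- 1
  pm <- paired_matrix(m, m)
  norm <- normalize_counts(pm)
  expect_equal(norm$tumor["g1", "p1"], log2(1e6 * 999999 / 1e6 + 1))

  # hand-computed 3x2 toy matrix
  tum <- matrix(c(10, 20, 70, 5, 5, 90), 3, 2,
                dimnames = list(paste0("g", 1:3), c("p1", "p2")))
  norm2 <- normalize_counts(paired_matrix(tum, tum))
  expect_equal(norm2$tumor, log2(sweep(tum, 2, colSums(tum), "/") * 1e6 + 1))

  # per-column scale invariance
  tum2 <- tum
  tum2[, 1] <- tum2[, 1] * 2
  expect_equal(normalize_counts(paired_matrix(tum2, tum))$tumor[, 1],
               norm2$tumor[, 1])

  zero <- tum
  zero[, 2] <- 0
  expect_error(normalize_counts(paired_matrix(zero, tum)), "p2")
})

test_that("call_deg flags only the implanted gene and needs 3 pairs", {
  pm <- toy_paired(n_genes = 30, n_pairs = 32, base = 200,
                   tumor_effect = list(g1 = 8), noise_sd = 5, seed = 2)
  calls <- call_deg(pm)
  expect_identical(calls$gene_id[calls$passed], "g1")
  expect_identical(calls$direction[calls$gene_id == "g1"], "up")
  expect_gt(calls$fold_change[calls$gene_id == "g1"], 2)

  null_pm <- toy_paired(n_genes = 10, n_pairs = 8, noise_sd = 3, seed = 3)
  expect_equal(sum(call_deg(null_pm)$passed), 0)

  tiny <- toy_paired(n_pairs = 2)
  expect_error(call_deg(tiny), "3 pairs")
})

test_that("tumor/normal swap maps directions to their mirrors with equal FDRs", {
  pm <- toy_paired(n_genes = 40, n_pairs = 16, base = 150,
                   tumor_effect = list(g1 = 6, g2 = 1 / 6),
                   noise_sd = 4, seed = 4)
  fwd <- call_deg(pm)
  rev <- call_deg(swap_arms(pm))
  expect_equal(fwd$fdr, rev$fdr, tolerance = 1e-12)
  flip <- c(up = "down", down = "up")
  expect_identical(unname(flip[fwd$direction[fwd$passed]]),
                   rev$direction[rev$passed])

  # same antisymmetry on the methylation layer
  set.seed(5)
  tum <- matrix(rbeta(200, 12, 8), 20, 10,
                dimnames = list(paste0("g", 1:20), paste0("p", 1:10)))
  nor <- matrix(rbeta(200, 8, 12), 20, 10, dimnames = dimnames(tum))
  mp <- paired_matrix(tum, nor, layer = "methylation_beta")
  f <- call_methylation(mp)
  r <- call_methylation(swap_arms(mp))
  expect_equal(f$fdr, r$fdr, tolerance = 1e-12)
  expect_equal(f$fold_change, 1 / r$fold_change, tolerance = 1e-12)
})

test_that("call_cnv passes the closed-form +/-0.5 segment-mean shift", {
  genes <- paste0("g", 1:20)
  pairs <- paste0("p", 1:12)
  set.seed(6)
  nor <- matrix(rnorm(240, 0, 0.02), 20, 12, dimnames = list(genes, pairs))
  tum <- nor
  tum["g1", ] <- tum["g1", ] + 0.5
  tum["g2", ] <- tum["g2", ] - 0.5
  calls <- call_cnv(paired_matrix(tum, nor, layer = "cnv_segmean"))
  expect_identical(sort(calls$gene_id[calls$passed]), c("g1", "g2"))
  expect_identical(calls$direction[calls$gene_id == "g1"], "amp")
  expect_identical(calls$direction[calls$gene_id == "g2"], "del")
  # fold change is on the linear copy-ratio scale: 2^0.5
  expect_equal(calls$fold_change[calls$gene_id == "g1"], 2^0.5,
               tolerance = 0.02)
  expect_equal(sum(call_cnv(paired_matrix(nor, nor,
                                          layer = "cnv_segmean"))$passed), 0)
})

test_that("call_methylation enforces both the FDR and the strict FC gate", {
  genes <- paste0("g", 1:10)
  pairs <- paste0("p", 1:45)
  set.seed(7)
  nor <- matrix(rbeta(450, 0.2 * 80, 0.8 * 80), 10, 45,
                dimnames = list(genes, pairs))
  tum <- nor
  tum["g1", ] <- rbeta(45, 0.6 * 80, 0.4 * 80)
  calls <- call_methylation(paired_matrix(tum, nor, layer = "methylation_beta"))
  expect_identical(calls$gene_id[calls$passed], "g1")
  expect_identical(calls$direction[calls$gene_id == "g1"], "hyper")
  expect_equal(calls$fold_change[calls$gene_id == "g1"], 3, tolerance = 0.1)

  # a tiny FDR cannot rescue a fold change below the 1.5 gate
  nor2 <- matrix(0.4, 10, 45, dimnames = list(genes, pairs)) +
    matrix(rnorm(450, 0, 0.005), 10, 45)
  tum2 <- nor2 * 1.49
  calls2 <- call_methylation(paired_matrix(tum2, nor2,
                                           layer = "methylation_beta"))
  g1 <- calls2[calls2$gene_id == "g1", ]
  expect_lt(g1$fdr, 0.001)
  expect_lt(g1$fold_change, 1.5)
  expect_false(g1$passed)
})

test_that("call_mutated applies a strict >5% patient-rate rule and dedupes", {
  mk <- function(n_pat, gene = "gX") {
    tibble::tibble(gene_id = gene, sample_id = sprintf("s%03d", seq_len(n_pat)))
  }
  at_rate <- call_mutated(mk(15), n_patients = 300)
  expect_false(at_rate$passed[1]) # 15/300 = 5% exactly: not kept
  above <- call_mutated(mk(16), n_patients = 300)
  expect_true(above$passed[1])

  dup <- dplyr::bind_rows(mk(16), mk(16)[1:5, ])
  expect_equal(call_mutated(dup, 300)$rate, 16 / 300)

  expect_error(call_mutated(mk(3), 300, roster = c("s001", "s002")),
               "not in roster")
})

test_that("FDR ordering agrees with raw-p ordering within every layer", {
  pm <- toy_paired(n_genes = 50, n_pairs = 10, base = 100,
                   tumor_effect = list(g1 = 3, g2 = 2, g3 = 1.5),
                   noise_sd = 8, seed = 8)
  calls <- call_deg(pm)
  ord_p <- order(calls$p_value, calls$gene_id)
  expect_true(all(diff(calls$fdr[ord_p]) >= -1e-12))
  expect_equal(calls$fdr, p.adjust(calls$p_value, "BH"))
})

test_that("paired tests are calibrated on a null synthetic cohort", {
  cfg <- sim_config(n_genes = 2000, n_pairs = 16, n_deg_up = 0,
                    n_deg_down = 0, n_amp = 0, n_del = 0, n_hyper = 0,
                    n_hypo = 0, n_mutated = 0, seed = 101)
  co <- simulate_cohort(cfg)
  frac <- function(calls) mean(calls$p_value < 0.05)
  expect_gt(frac(call_deg(co$expression)), 0.03)
  expect_lt(frac(call_deg(co$expression)), 0.07)
  cnv <- suppressMessages(call_cnv(gene_level_cnv(co$seg, co$annotation)))
  expect_gt(frac(cnv), 0.03)
  expect_lt(frac(cnv), 0.07)
  meth <- suppressMessages(
    call_methylation(promoter_methylation(co$probes, co$annotation))
  )
  expect_gt(frac(meth), 0.03)
  expect_lt(frac(meth), 0.07)
})
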