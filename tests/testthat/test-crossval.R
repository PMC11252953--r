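ms_toy <- function(values, n_peptides = NULL, proteotypic = NULL) {
  n <- nrow(values)
  if (is.null(n_peptides)) n_peptides <- rep(3L, n)
  if (is.null(proteotypic)) proteotypic <- rep(TRUE, n)
  ms_protein_table(values, n_peptides = n_peptides,
                   proteotypic = proteotypic, scale = "log2")
}

test_that("ms_protein_table validates its inputs", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("P1", "P2"), c("s1", "s2")))
  expect_s3_class(ms_toy(v), "sfggm_ms")
  dup <- v; rownames(dup) <- c("P1", "P1")
  expect_error(ms_toy(dup), "duplicated UniProt")
  expect_error(ms_protein_table(v, n_peptides = c(-1, 2),
                                proteotypic = c(TRUE, TRUE), scale = "log2"))
})

test_that("MS tables round-trip through TSV", {
  v <- matrix(c(1.5, NA, 3, 4), 2, 2,
              dimnames = list(c("P1", "P2"), c("s1", "s2")))
  ms <- ms_protein_table(v, gene = c("G1", "G2"), n_peptides = c(2, 1),
                         proteotypic = c(TRUE, FALSE), scale = "log2")
  path <- withr::local_tempfile(fileext = ".tsv")
  d <- data.frame(uniprot = ms$uniprot, gene = ms$gene,
                  n_peptides = ms$n_peptides, proteotypic = ms$proteotypic,
                  ms$values, check.names = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_ms_table(path)
  expect_equal(back$values, ms$values)
  expect_equal(back$n_peptides, ms$n_peptides)
  expect_equal(back$proteotypic, ms$proteotypic)
})

test_that("overlap filters apply sequentially with exact counts", {
  # P1 kept; P2 not in network; P3 not proteotypic; P4 single peptide;
  # P5 exactly 50% non-missing (removed: not strictly more than half);
  # P6 60% non-missing (kept)
  samples <- sprintf("s%d", 1:5)
  v <- matrix(10, 6, 5, dimnames = list(sprintf("P%d", 1:6), samples))
  v["P5", ] <- c(10, 10, NA, NA, NA)  # 2/5 = 40% non-missing
  v["P6", ] <- c(10, 10, 10, NA, NA)  # 3/5 = 60%
  ms <- ms_toy(v, n_peptides = c(3, 3, 3, 1, 3, 3),
               proteotypic = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  res <- overlap_filter(ms, c("P1", "P3", "P4", "P5", "P6", "P9"))
  expect_equal(unname(res$counts),
               c(overlap = 5, removed_no_proteotypic = 1,
                 removed_single_peptide = 1, removed_missingness = 1,
                 retained = 2), ignore_attr = TRUE)
  expect_setequal(res$retained, c("P1", "P6"))
  # removals sum to overlap - retained
  expect_equal(sum(res$counts[2:4]),
               res$counts[["overlap"]] - res$counts[["retained"]])
  # the 50% boundary is strict: exactly half non-missing is removed
  v2 <- v; v2["P6", ] <- 10
  v2 <- v2[, 1:4]
  v2["P5", ] <- c(10, 10, NA, NA)  # exactly 50%
  ms2 <- ms_toy(v2, n_peptides = c(3, 3, 3, 1, 3, 3),
                proteotypic = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  res2 <- overlap_filter(ms2, "P5")
  expect_equal(res2$counts[["removed_missingness"]], 1)
  expect_warning(overlap_filter(ms, "P99"), "no overlap")
})

test_that("cross_correlate detects agreement and is affine-invariant", {
  set.seed(10)
  samples <- sprintf("s%d", 1:12)
  base <- matrix(rnorm(36), 3, 12, dimnames = list(c("P1", "P2", "P3"),
                                                   samples))
  soma <- base
  msv <- base + matrix(rnorm(36, 0, 0.05), 3, 12)
  msv["P3", ] <- -base["P3", ]          # anti-correlated protein
  ms <- ms_toy(msv)
  out <- cross_correlate(ms, soma)
  expect_gt(out$r[out$uniprot == "P1"], 0.9)
  expect_lt(out$r[out$uniprot == "P3"], -0.9)
  expect_equal(out$n, rep(12, 3))
  # affine rescaling of either platform leaves r unchanged
  out2 <- cross_correlate(ms_toy(3 * msv + 7), 0.5 * soma - 2)
  expect_equal(out2$r, out$r, tolerance = 1e-10)
  # fewer than 3 complete pairs gives NA
  msv_na <- msv; msv_na["P1", 3:12] <- NA
  out3 <- cross_correlate(ms_toy(msv_na), soma)
  expect_true(is.na(out3$r[out3$uniprot == "P1"]))
  expect_error(cross_correlate(ms, soma[, 1:2, drop = FALSE]),
               "fewer than 3 shared samples")
})

test_that("aggregate_to_proteins averages aptamers per accession", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3,
              dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
  m <- intensity_matrix(v, "log2")
  ann <- data.frame(seq_id = c("a1", "a2", "a3"),
                    uniprot_ids = c("P1", "P1", "P2"),
                    stringsAsFactors = FALSE)
  out <- aggregate_to_proteins(m, ann)
  expect_equal(out["P1", ], c(s1 = 2, s2 = 3))
  expect_equal(out["P2", ], c(s1 = 5, s2 = 6))
})

test_that("compare_foldchanges pairs both platforms per protein", {
  cfg <- synthetic_config(p = 12, n_per_group = c(healthy = 10, mild = 10),
                          n_shared_edges = 0, n_unique_edges_per_group = 0,
                          n_differential = 12, effect_range = c(1, 1.5),
                          sigma_noise = 0.25, sigma_subject = 0.05,
                          n_buffer = 0, n_covariate_affected = 0,
                          frac_unmapped = 0, frac_nonhuman = 0,
                          frac_shared_protein = 0, seed = 63)
  tr <- make_precision_matrices(cfg)
  ds <- sample_dataset(tr)
  lm2 <- log2_transform(ds$intensity)
  soma_ct <- diff_abundance(lm2, ds$samples, ds$annotations,
                            batch_size = 12, seed = 3)
  ms <- simulate_ms_validation(ds, sigma_platform = 0.2,
                               frac_missing = c(0, 0), seed = 4)
  out <- compare_foldchanges(ms, ds$samples, soma_ct)
  expect_true(all(c("log2fc_ms", "log2fc_soma", "sign_agree") %in%
                    names(out)))
  expect_equal(nrow(out), 12)
  # strong true shifts on both platforms: signs agree and estimates track
  expect_true(all(out$sign_agree))
  expect_equal(out$log2fc_ms, out$log2fc_soma, tolerance = 0.5)
  seq_of <- ds$annotations$seq_id[match(out$uniprot,
                                        ds$annotations$uniprot_ids)]
  truth <- tr$shifts[seq_of, "mild"]
  expect_equal(sign(out$log2fc_soma), unname(sign(truth)))
})
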