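test_that("synthetic_config validates its inputs", {
  expect_s3_class(synthetic_config(p = 20, seed = 7), "sfggm_config")
  # shared + K * unique must fit in p(p-1)/2
  expect_error(synthetic_config(p = 5, n_shared_edges = 9,
                                n_unique_edges_per_group = 1),
               "infeasible")
  expect_error(synthetic_config(p = 10, frac_unmapped = 1.2), "fractions")
  expect_error(synthetic_config(p = 10, sigma_noise = -1), "SD")
  expect_error(synthetic_config(p = 10, partial_corr_range = c(0.5, 1.5)))
  expect_error(synthetic_config(p = 10,
                                n_per_group = c(a = 5, a = 5)), "unique")
})

test_that("precision matrices have the requested sparsity structure", {
  cfg <- synthetic_config(p = 25, n_shared_edges = 20,
                          n_unique_edges_per_group = 3, seed = 3)
  tr <- make_precision_matrices(cfg)
  expect_named(tr$precision, names(cfg$n_per_group))
  expect_equal(nrow(tr$shared_edges), 20)
  for (g in names(tr$unique_edges))
    expect_equal(nrow(tr$unique_edges[[g]]), 3)

  # shared and unique edge sets are pairwise disjoint
  keys <- function(e) paste(e[, 1], e[, 2], sep = "-")
  all_keys <- c(keys(tr$shared_edges),
                unlist(lapply(tr$unique_edges, keys)))
  expect_equal(anyDuplicated(all_keys), 0)

  for (g in names(tr$precision)) {
    P <- tr$precision[[g]]
    expect_true(isSymmetric(P))
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    # edge set of the matrix equals sampled shared + this group's unique set
    got <- keys(edges_from_precision(P))
    want <- sort(c(keys(tr$shared_edges), keys(tr$unique_edges[[g]])))
    expect_equal(sort(got), want)
  }

  # shared edges carry the same value in every group
  e <- tr$shared_edges
  v1 <- tr$precision[[1]][e]
  for (g in names(tr$precision))
    expect_equal(tr$precision[[g]][e], v1)
})

test_that("precision generation is deterministic given the seed", {
  cfg <- synthetic_config(p = 15, seed = 99)
  t1 <- make_precision_matrices(cfg)
  t2 <- make_precision_matrices(cfg)
  expect_identical(t1$precision, t2$precision)
  expect_identical(t1$shifts, t2$shifts)
  expect_identical(t1$annotations, t2$annotations)
})

test_that("annotation defects occur in the requested deterministic counts", {
  cfg <- synthetic_config(p = 200, frac_unmapped = 0.05, frac_nonhuman = 0.1,
                          frac_shared_protein = 0.02, seed = 5)
  ann <- make_precision_matrices(cfg)$annotations
  expect_equal(sum(!nzchar(ann$uniprot_ids)), round(0.05 * 200))
  expect_equal(sum(ann$organism != "Human"), round(0.1 * 200))
  mapped <- ann$uniprot_ids[nzchar(ann$uniprot_ids)]
  expect_gte(sum(duplicated(mapped)), 1)
  # unmapped aptamers are never also counted as non-human
  expect_true(all(ann$organism[!nzchar(ann$uniprot_ids)] == "Human"))
})

test_that("sample_dataset emits the right samples and is deterministic", {
  cfg <- synthetic_config(p = 12, n_per_group = c(healthy = 5, mild = 6),
                          n_shared_edges = 8, n_unique_edges_per_group = 1,
                          n_buffer = 3, n_replicate_pairs = 2, seed = 21)
  tr <- make_precision_matrices(cfg)
  ds <- sample_dataset(tr)
  expect_equal(nrow(ds$intensity$values), 5 + 6 + 3 + 2)
  expect_equal(ncol(ds$intensity$values), 12)
  expect_equal(ds$intensity$scale, "linear")
  expect_true(all(ds$intensity$values > 0))
  expect_equal(sum(ds$samples$sample_type == "buffer"), 3)
  reps <- ds$samples[!is.na(ds$samples$replicate_of), ]
  expect_equal(nrow(reps), 2)
  expect_true(all(reps$replicate_of %in% ds$samples$sample_id))
  # replicate rows share group/sex/age with their source
  src <- ds$samples[match(reps$replicate_of, ds$samples$sample_id), ]
  expect_equal(reps$group, src$group)
  expect_equal(reps$age, src$age)
  expect_true(all(ds$samples$age >= 50 & ds$samples$age <= 95, na.rm = TRUE))
  ds2 <- sample_dataset(tr)
  expect_identical(ds$intensity$values, ds2$intensity$values)
})

test_that("group shifts land in the sample means", {
  cfg <- synthetic_config(p = 8, n_per_group = c(healthy = 200, mild = 200),
                          n_shared_edges = 0, n_unique_edges_per_group = 0,
                          n_differential = 8, effect_range = c(1, 1),
                          sigma_noise = 0.3, sigma_subject = 0, n_buffer = 0,
                          n_covariate_affected = 0, seed = 31)
  tr <- make_precision_matrices(cfg)
  ds <- sample_dataset(tr)
  lv <- log2(ds$intensity$values)
  g <- ds$samples$group
  obs <- colMeans(lv[g == "mild", ]) - colMeans(lv[g == "healthy", ])
  expect_equal(unname(obs), unname(tr$shifts[, "mild"]), tolerance = 0.1)
  expect_true(all(abs(tr$shifts[, "mild"]) == 1))
})

test_that("synthetic dataset round-trips through CSV", {
  cfg <- synthetic_config(p = 6, n_per_group = c(healthy = 3, mild = 3),
                          n_shared_edges = 4, n_unique_edges_per_group = 0,
                          n_buffer = 2, seed = 8)
  tr <- make_precision_matrices(cfg)
  ds <- sample_dataset(tr)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ds, dir, truth = tr)
  expect_true(all(file.exists(paths)))
  back <- read_dataset_csv(dir)
  expect_equal(back$intensity$values, ds$intensity$values, tolerance = 1e-12)
  expect_equal(back$samples$sample_id, ds$samples$sample_id)
  expect_equal(back$annotations$uniprot_ids, ds$annotations$uniprot_ids)
  truth_json <- jsonlite::read_json(file.path(dir, "truth.json"),
                                    simplifyVector = TRUE)
  expect_equal(nrow(truth_json$shared_edges), nrow(tr$shared_edges))
})

test_that("ADAT-like file round-trips", {
  cfg <- synthetic_config(p = 5, n_per_group = c(healthy = 3, mild = 3),
                          n_shared_edges = 3, n_unique_edges_per_group = 0,
                          n_buffer = 2, n_replicate_pairs = 1, seed = 13)
  ds <- sample_dataset(make_precision_matrices(cfg))
  path <- withr::local_tempfile(fileext = ".adat")
  write_adat_like(ds, path)
  back <- read_adat_like(path)
  expect_equal(back$intensity$values, ds$intensity$values, tolerance = 1e-10)
  expect_equal(back$samples$replicate_of, ds$samples$replicate_of)
  expect_equal(back$intensity$scale, "linear")
})

test_that("simulate_ms_validation produces a coherent MS table", {
  cfg <- synthetic_config(p = 30, n_per_group = c(healthy = 6, mild = 6),
                          n_shared_edges = 10, n_unique_edges_per_group = 0,
                          frac_unmapped = 0.1, frac_nonhuman = 0.1, seed = 17)
  ds <- sample_dataset(make_precision_matrices(cfg))
  ms <- simulate_ms_validation(ds, seed = 2)
  expect_s3_class(ms, "sfggm_ms")
  # only mapped human proteins are simulated
  ann <- ds$annotations
  human <- unique(ann$uniprot_ids[nzchar(ann$uniprot_ids) &
                                    ann$organism == "Human"])
  expect_setequal(ms$uniprot, human)
  expect_equal(colnames(ms$values),
               ds$samples$sample_id[ds$samples$sample_type == "study"])
  expect_true(any(!ms$proteotypic))
  expect_true(any(ms$n_peptides == 1))
})
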