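#' Configuration for the synthetic synovial-fluid proteomics generator
#'
#' Bundles every parameter of the generative model: group-specific sparse
#' precision matrices sharing a common edge backbone, log2-scale Gaussian
#' noise, additive group/sex/age effects on subsets of aptamers, per-subject
#' random intercepts, buffer samples near a noise floor, replicate pairs and
#' annotation defects (unmapped / non-human aptamers).
#'
#' Defaults emulate the cohort the analysis targets: three groups of
#' independent donors (12 healthy, 13 with mild cartilage/meniscus
#' degeneration, 14 with late-stage osteoarthritis), ages centred near 71
#' years, sexes balanced, and abundances reported on a linear RFU-like scale
#' after median normalization (hence a modest residual subject effect).
#'
#' @param p number of aptamers.
#' @param n_per_group named integer vector of samples per group; names are
#'   the group labels, first name is the reference (healthy) group.
#' @param n_shared_edges number of edges shared by all group networks.
#' @param n_unique_edges_per_group number of edges unique to each group.
#' @param partial_corr_range magnitude range for edge partial correlations.
#' @param n_differential number of aptamers given true group mean shifts.
#' @param effect_range log2 shift magnitude range for non-reference groups.
#' @param effect_range_late log2 shift magnitude range for the last group
#'   (late-stage disease shows much larger fold changes); ignored when only
#'   two groups are simulated.
#' @param sigma_noise scale multiplying the correlated multivariate normal
#'   component (log2 units); partial correlations are scale-invariant so the
#'   network structure is unaffected.
#' @param sigma_subject SD of the per-subject random intercept (log2 units).
#' @param sigma_resid_extra SD of extra independent residual noise.
#' @param n_buffer number of buffer (no-sample) wells.
#' @param buffer_floor_log2,buffer_sd_log2 buffer noise-floor parameters.
#' @param n_replicate_pairs number of re-assayed replicate sample pairs.
#' @param sigma_replicate_log2 SD of replicate re-noising (log2 units); the
#'   default reproduces a repeatability coefficient near 13 percent.
#' @param frac_unmapped fraction of aptamers without a UniProt mapping.
#' @param frac_nonhuman fraction of aptamers targeting non-human proteins.
#' @param frac_shared_protein fraction of aptamers mapped to a protein that
#'   already has another aptamer (multiple aptamers per protein).
#' @param n_covariate_affected number of aptamers with sex and age effects.
#' @param sex_effect_range,age_slope_range magnitude ranges for sex effects
#'   (log2) and age slopes (log2 per year).
#' @param baseline_range range of per-aptamer baseline log2 abundances.
#' @param seed RNG seed (integer below 2^31).
#'
#' @return an object of class `sfggm_config` (a validated list).
#' @export
synthetic_config <- function(p,
                             n_per_group = c(healthy = 12, mild = 13, lateOA = 14),
                             n_shared_edges = round(p),
                             n_unique_edges_per_group = round(p / 10),
                             partial_corr_range = c(0.3, 0.7),
                             n_differential = round(p / 5),
                             effect_range = c(0.4, 1.5),
                             effect_range_late = c(0.5, 4),
                             sigma_noise = 0.5,
                             sigma_subject = 0.1,
                             sigma_resid_extra = 0,
                             n_buffer = 3,
                             buffer_floor_log2 = 4,
                             buffer_sd_log2 = 0.3,
                             n_replicate_pairs = 0,
                             sigma_replicate_log2 = 0.09,
                             frac_unmapped = 0.005,
                             frac_nonhuman = 0.036,
                             frac_shared_protein = 0.02,
                             n_covariate_affected = round(p / 10),
                             sex_effect_range = c(0.2, 0.5),
                             age_slope_range = c(0.01, 0.03),
                             baseline_range = c(6.5, 14),
                             seed = 1L) {
  stopifnot(length(p) == 1, p >= 2, p == round(p))
  if (is.null(names(n_per_group)) || anyDuplicated(names(n_per_group)))
    stop("n_per_group must have unique group names")
  K <- length(n_per_group)
  max_edges <- p * (p - 1) / 2
  if (n_shared_edges + K * n_unique_edges_per_group > max_edges)
    stop("infeasible edge counts: n_shared_edges + K * n_unique_edges_per_group ",
         "exceeds p(p-1)/2 = ", max_edges)
  if (n_shared_edges < 0 || n_unique_edges_per_group < 0)
    stop("edge counts must be non-negative")
  for (fr in c(frac_unmapped, frac_nonhuman, frac_shared_protein))
    if (fr < 0 || fr > 1) stop("fractions must lie in [0, 1]")
  for (s in c(sigma_noise, sigma_subject, sigma_resid_extra, buffer_sd_log2,
              sigma_replicate_log2))
    if (s < 0) stop("all SDs must be >= 0")
  stopifnot(length(partial_corr_range) == 2,
            all(partial_corr_range > 0), all(partial_corr_range < 1),
            partial_corr_range[1] <= partial_corr_range[2])
  stopifnot(n_buffer >= 0, n_replicate_pairs >= 0,
            n_differential >= 0, n_differential <= p,
            n_covariate_affected >= 0, n_covariate_affected <= p,
            abs(seed) < 2^31)
  cfg <- list(p = as.integer(p), n_per_group = n_per_group,
              n_shared_edges = as.integer(n_shared_edges),
              n_unique_edges_per_group = as.integer(n_unique_edges_per_group),
              partial_corr_range = partial_corr_range,
              n_differential = as.integer(n_differential),
              effect_range = effect_range,
              effect_range_late = effect_range_late,
              sigma_noise = sigma_noise, sigma_subject = sigma_subject,
              sigma_resid_extra = sigma_resid_extra,
              n_buffer = as.integer(n_buffer),
              buffer_floor_log2 = buffer_floor_log2,
              buffer_sd_log2 = buffer_sd_log2,
              n_replicate_pairs = as.integer(n_replicate_pairs),
              sigma_replicate_log2 = sigma_replicate_log2,
              frac_unmapped = frac_unmapped, frac_nonhuman = frac_nonhuman,
              frac_shared_protein = frac_shared_protein,
              n_covariate_affected = as.integer(n_covariate_affected),
              sex_effect_range = sex_effect_range,
              age_slope_range = age_slope_range,
              baseline_range = baseline_range,
              seed = as.integer(seed))
  class(cfg) <- "sfggm_config"
  cfg
}

#' Read edge positions back from a precision matrix
#'
#' @param P symmetric matrix.
#' @param tol entries with absolute value above `tol` count as edges.
#' @return two-column integer matrix of (i, j) pairs with i < j.
#' @export
edges_from_precision <- function(P, tol = 1e-12) {
  idx <- which(abs(P) > tol & upper.tri(P), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("i", "j"))
  idx
}

.edge_key <- function(e) paste(e[, 1], e[, 2], sep = "-")

#' Build group-specific precision matrices and ground truth
#'
#' Samples disjoint shared and group-unique edge positions uniformly without
#' replacement, assigns each edge a partial-correlation magnitude drawn from
#' `partial_corr_range` with random sign (the same value in every group for
#' shared edges), converts partial correlations to off-diagonal precision
#' entries (unit diagonal, \eqn{\omega_{ij} = -\rho_{ij}}), and enforces
#' positive definiteness by diagonal loading: the smallest \eqn{\delta \ge 0}
#' such that the minimum eigenvalue is at least 0.1 is added to the diagonal.
#' Diagonal loading preserves the off-diagonal zero pattern, so the edge sets
#' of the returned matrices equal the sampled edge sets exactly.
#'
#' Also draws the remaining ground truth the sampler needs: per-aptamer
#' baseline abundances, true differential group shifts, sex/age covariate
#' effects, and the aptamer annotation table (including deliberate
#' annotation defects).
#'
#' @param config an [synthetic_config()] object.
#' @return an object of class `sfggm_truth`: a list with elements
#'   `precision` (named list of p x p matrices), `shared_edges`,
#'   `unique_edges` (named list), `edge_values`, `baseline`, `shifts`
#'   (p x K matrix of true log2 group shifts, zero for the reference group),
#'   `sex_effects`, `age_slopes`, `annotations` and `config`.
#' @export
make_precision_matrices <- function(config) {
  stopifnot(inherits(config, "sfggm_config"))
  set.seed(config$seed)
  p <- config$p
  groups <- names(config$n_per_group)
  K <- length(groups)
  all_pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  all_pairs <- all_pairs[order(all_pairs[, 1], all_pairs[, 2]), , drop = FALSE]
  n_total <- config$n_shared_edges + K * config$n_unique_edges_per_group
  sel <- if (n_total > 0) sample(nrow(all_pairs), n_total) else integer(0)
  shared_idx <- sel[seq_len(config$n_shared_edges)]
  shared <- all_pairs[shared_idx, , drop = FALSE]
  unique_edges <- vector("list", K)
  names(unique_edges) <- groups
  offset <- config$n_shared_edges
  for (k in seq_len(K)) {
    take <- sel[offset + seq_len(config$n_unique_edges_per_group)]
    ue <- all_pairs[take, , drop = FALSE]
    unique_edges[[k]] <- ue[order(ue[, 1], ue[, 2]), , drop = FALSE]
    offset <- offset + config$n_unique_edges_per_group
  }
  shared <- shared[order(shared[, 1], shared[, 2]), , drop = FALSE]
  dimnames(shared) <- list(NULL, c("i", "j"))

  draw_pc <- function(n) {
    mag <- runif(n, config$partial_corr_range[1], config$partial_corr_range[2])
    mag * sample(c(-1, 1), n, replace = TRUE)
  }
  shared_vals <- draw_pc(nrow(shared))
  unique_vals <- lapply(unique_edges, function(e) draw_pc(nrow(e)))

  precision <- vector("list", K)
  names(precision) <- groups
  for (k in seq_len(K)) {
    P <- diag(p)
    put <- function(e, v) {
      for (r in seq_len(nrow(e))) {
        P[e[r, 1], e[r, 2]] <<- -v[r]
        P[e[r, 2], e[r, 1]] <<- -v[r]
      }
    }
    if (nrow(shared)) put(shared, shared_vals)
    if (nrow(unique_edges[[k]])) put(unique_edges[[k]], unique_vals[[k]])
    ev_min <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
    delta <- max(0, 0.1 - ev_min)
    P <- P + delta * diag(p)
    ev_check <- min(eigen(P, symmetric = TRUE, only.values = TRUE)$values)
    stopifnot(ev_check > 0)  # diagonal loading always suffices
    precision[[k]] <- P
  }

  seq_ids <- sprintf("apt_%04d", seq_len(p))
  baseline <- runif(p, config$baseline_range[1], config$baseline_range[2])
  names(baseline) <- seq_ids

  shifts <- matrix(0, p, K, dimnames = list(seq_ids, groups))
  diff_idx <- if (config$n_differential > 0)
    sort(sample(p, config$n_differential)) else integer(0)
  for (k in seq_len(K)[-1]) {
    rng <- if (k == K && K >= 3) config$effect_range_late else config$effect_range
    if (length(diff_idx))
      shifts[diff_idx, k] <- runif(length(diff_idx), rng[1], rng[2]) *
        sample(c(-1, 1), length(diff_idx), replace = TRUE)
  }

  sex_effects <- age_slopes <- setNames(numeric(p), seq_ids)
  cov_idx <- if (config$n_covariate_affected > 0)
    sort(sample(p, config$n_covariate_affected)) else integer(0)
  if (length(cov_idx)) {
    sex_effects[cov_idx] <- runif(length(cov_idx), config$sex_effect_range[1],
                                  config$sex_effect_range[2]) *
      sample(c(-1, 1), length(cov_idx), replace = TRUE)
    age_slopes[cov_idx] <- runif(length(cov_idx), config$age_slope_range[1],
                                 config$age_slope_range[2]) *
      sample(c(-1, 1), length(cov_idx), replace = TRUE)
  }

  annotations <- .make_annotations(config, seq_ids)

  truth <- list(precision = precision, shared_edges = shared,
                unique_edges = unique_edges,
                edge_values = list(shared = shared_vals, unique = unique_vals),
                baseline = baseline, shifts = shifts,
                differential_aptamers = seq_ids[diff_idx],
                sex_effects = sex_effects, age_slopes = age_slopes,
                annotations = annotations, config = config)
  class(truth) <- "sfggm_truth"
  truth
}

# Annotation table with deterministic defect counts: round(frac * p) aptamers
# lose their UniProt mapping, round(frac_nonhuman * p) of the remainder are
# assigned a non-human organism. Defects are drawn preferentially outside the
# network-bearing aptamers would require knowledge of downstream use; drawn
# uniformly here.
.make_annotations <- function(config, seq_ids) {
  p <- config$p
  n_dup <- round(config$frac_shared_protein * p)
  protein_idx <- seq_len(p)
  if (n_dup > 0 && p > 1) {
    dup_targets <- sample(p, n_dup)
    for (d in dup_targets) {
      donor <- sample(setdiff(seq_len(p), d), 1)
      protein_idx[d] <- protein_idx[donor]
    }
  }
  uniprot <- sprintf("Q%05d", protein_idx)
  gene <- sprintf("GENE%04d", protein_idx)
  organism <- rep("Human", p)
  n_unmapped <- round(config$frac_unmapped * p)
  n_nonhuman <- round(config$frac_nonhuman * p)
  unmapped_idx <- if (n_unmapped > 0) sample(p, n_unmapped) else integer(0)
  pool <- setdiff(seq_len(p), unmapped_idx)
  nonhuman_idx <- if (n_nonhuman > 0) sample(pool, min(n_nonhuman, length(pool)))
    else integer(0)
  uniprot[unmapped_idx] <- ""
  organism[nonhuman_idx] <- "Mouse"
  data.frame(seq_id = seq_ids, uniprot_ids = uniprot, gene_symbol = gene,
             organism = organism,
             dilution_bin = sample(c("20%", "0.5%", "0.005%"), p, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Draw a synthetic dataset from generated ground truth
#'
#' For each group, draws multivariate normal log2 vectors with covariance
#' equal to the inverse of that group's precision matrix (scaled by
#' `sigma_noise`), adds baseline abundances, true group shifts, sex and age
#' effects and one subject random intercept per sample (each sample is one
#' independent donor). Buffer wells are appended as i.i.d. normal noise
#' around the buffer floor; replicate pairs are appended by re-noising
#' existing study samples. The returned intensity matrix is on the linear
#' scale (2^log2) so downstream log2 transformation is exercised.
#'
#' Ages are drawn Normal(71, 8) truncated to [50, 95]; sex is Bernoulli(0.5).
#'
#' @param truth an `sfggm_truth` object from [make_precision_matrices()].
#' @param config the same `sfggm_config` used to build `truth`.
#' @return list with elements `intensity` (an [intensity_matrix()], linear
#'   scale, buffer and replicate rows included), `samples` (sample metadata
#'   data frame with `sample_id`, `subject_id`, `group`, `sex`, `age`,
#'   `sample_type`, `replicate_of`) and `annotations`.
#' @export
sample_dataset <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sfggm_truth"), inherits(config, "sfggm_config"))
  if (!identical(truth$config$p, config$p))
    stop("truth and config disagree on p")
  set.seed(config$seed + 1L)
  p <- config$p
  groups <- names(config$n_per_group)
  seq_ids <- truth$annotations$seq_id

  rows <- list(); meta <- list()
  sample_no <- 0
  for (k in seq_along(groups)) {
    n_k <- config$n_per_group[[k]]
    if (n_k == 0) next
    Sigma <- chol2inv(chol(truth$precision[[k]]))
    L <- chol(Sigma)
    Z <- matrix(rnorm(n_k * p), n_k, p) %*% L
    age <- numeric(n_k); sex <- character(n_k)
    for (s in seq_len(n_k)) {
      a <- rnorm(1, 71, 8)
      while (a < 50 || a > 95) a <- rnorm(1, 71, 8)
      age[s] <- a
      sex[s] <- if (rbinom(1, 1, 0.5) == 1) "F" else "M"
    }
    b_subj <- rnorm(n_k, 0, config$sigma_subject)
    for (s in seq_len(n_k)) {
      sample_no <- sample_no + 1
      mu <- truth$baseline + truth$shifts[, k] +
        (sex[s] == "F") * truth$sex_effects +
        (age[s] - 71) * truth$age_slopes
      val <- mu + b_subj[s] + config$sigma_noise * Z[s, ]
      if (config$sigma_resid_extra > 0)
        val <- val + rnorm(p, 0, config$sigma_resid_extra)
      rows[[sample_no]] <- val
      meta[[sample_no]] <- data.frame(
        sample_id = sprintf("S%03d", sample_no),
        subject_id = sprintf("subj%03d", sample_no),
        group = groups[k], sex = sex[s], age = age[s],
        sample_type = "study", replicate_of = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  n_study <- sample_no

  # buffer wells: noise floor, i.i.d. per aptamer
  for (b in seq_len(config$n_buffer)) {
    sample_no <- sample_no + 1
    rows[[sample_no]] <- rnorm(p, config$buffer_floor_log2, config$buffer_sd_log2)
    meta[[sample_no]] <- data.frame(
      sample_id = sprintf("BUF%02d", b), subject_id = NA_character_,
      group = NA_character_, sex = NA_character_, age = NA_real_,
      sample_type = "buffer", replicate_of = NA_character_,
      stringsAsFactors = FALSE)
  }

  # replicate pairs: re-noise existing study samples
  n_rep <- min(config$n_replicate_pairs, n_study)
  rep_src <- if (n_rep > 0) sample(n_study, n_rep) else integer(0)
  for (r in seq_along(rep_src)) {
    sample_no <- sample_no + 1
    src <- rep_src[r]
    rows[[sample_no]] <- rows[[src]] + rnorm(p, 0, config$sigma_replicate_log2)
    m <- meta[[src]]
    m$sample_id <- paste0(m$sample_id, "rep")
    m$replicate_of <- meta[[src]]$sample_id
    meta[[sample_no]] <- m
  }

  log2_mat <- do.call(rbind, rows)
  samples <- do.call(rbind, meta)
  dimnames(log2_mat) <- list(samples$sample_id, seq_ids)
  intensity <- intensity_matrix(2^log2_mat, scale = "linear")
  list(intensity = intensity, samples = samples,
       annotations = truth$annotations)
}

#' Simulate a mass-spectrometry validation table from a synthetic dataset
#'
#' Builds a protein-level quantification table for a second, noisier platform
#' sharing the true underlying abundances with a subset of the aptamer
#' dataset: per-protein log2 values are the (aptamer-averaged) study-sample
#' log2 values plus independent platform noise, with engineered missingness
#' and peptide-identification metadata so that the cross-validation overlap
#' filters have something to act on.
#'
#' @param dataset a list as returned by [sample_dataset()].
#' @param proteins UniProt accessions to include (default: all mapped human
#'   proteins present in the dataset annotations).
#' @param sigma_platform SD of independent platform noise (log2 units).
#' @param frac_missing per-protein fraction of missing sample values drawn
#'   uniformly from this range.
#' @param frac_nonproteotypic fraction of proteins without a proteotypic
#'   peptide; `frac_single_peptide` fraction identified by a single stripped
#'   peptide.
#' @param seed RNG seed.
#' @return an `sfggm_ms` object; see [ms_protein_table()].
#' @export
simulate_ms_validation <- function(dataset, proteins = NULL,
                                   sigma_platform = 0.4,
                                   frac_missing = c(0, 0.6),
                                   frac_nonproteotypic = 0.1,
                                   frac_single_peptide = 0.1,
                                   seed = 1L) {
  set.seed(seed)
  ann <- dataset$annotations
  ann <- ann[ann$uniprot_ids != "" & tolower(ann$organism) %in%
               c("human", "homo sapiens"), , drop = FALSE]
  if (is.null(proteins)) proteins <- unique(ann$uniprot_ids)
  study <- dataset$samples$sample_type == "study"
  m <- as_log2(dataset$intensity)
  vals <- m$values[dataset$samples$sample_id[study], , drop = FALSE]
  out <- matrix(NA_real_, length(proteins), nrow(vals),
                dimnames = list(proteins, rownames(vals)))
  for (i in seq_along(proteins)) {
    apts <- ann$seq_id[ann$uniprot_ids == proteins[i]]
    apts <- intersect(apts, colnames(vals))
    if (!length(apts)) next
    base <- rowMeans(vals[, apts, drop = FALSE])
    v <- base + rnorm(length(base), 0, sigma_platform)
    fm <- runif(1, frac_missing[1], frac_missing[2])
    n_miss <- round(fm * length(v))
    if (n_miss > 0) v[sample(length(v), n_miss)] <- NA_real_
    out[i, ] <- v
  }
  n_prot <- length(proteins)
  proteotypic <- rep(TRUE, n_prot)
  n_np <- round(frac_nonproteotypic * n_prot)
  if (n_np > 0) proteotypic[sample(n_prot, n_np)] <- FALSE
  peptides <- pmax(2L, rpois(n_prot, 6))
  n_sp <- round(frac_single_peptide * n_prot)
  if (n_sp > 0) peptides[sample(which(proteotypic), min(n_sp, sum(proteotypic)))] <- 1L
  gene <- ann$gene_symbol[match(proteins, ann$uniprot_ids)]
  ms_protein_table(values = out, uniprot = proteins, gene = gene,
                   n_peptides = peptides, proteotypic = proteotypic,
                   scale = "log2")
}

#' Write a synthetic dataset to disk as plain-text tables
#'
#' Writes the intensity matrix (samples as rows, aptamer sequence IDs as
#' columns), the sample metadata table and the aptamer annotation table as
#' CSV, and the ground-truth bundle (edge lists, true effects) as JSON.
#'
#' @param dataset list from [sample_dataset()].
#' @param truth optional `sfggm_truth` to serialize alongside.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_synthetic_dataset <- function(dataset, dir, truth = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(intensity = file.path(dir, "intensity.csv"),
             samples = file.path(dir, "samples.csv"),
             annotations = file.path(dir, "annotations.csv"))
  write.csv(data.frame(sample_id = dataset$intensity$sample_ids,
                       dataset$intensity$values, check.names = FALSE),
            paths["intensity"], row.names = FALSE)
  write.csv(dataset$samples, paths["samples"], row.names = FALSE)
  write.csv(dataset$annotations, paths["annotations"], row.names = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    tr <- list(shared_edges = unname(as.data.frame(truth$shared_edges)),
               unique_edges = lapply(truth$unique_edges, function(e)
                 unname(as.data.frame(e))),
               shifts = as.data.frame(truth$shifts),
               differential_aptamers = truth$differential_aptamers)
    jsonlite::write_json(tr, paths["truth"], digits = NA)
  }
  invisible(paths)
}

#' Read a synthetic dataset written by [write_synthetic_dataset()]
#'
#' @param dir directory containing `intensity.csv`, `samples.csv` and
#'   `annotations.csv`.
#' @param scale scale flag of the stored intensity matrix.
#' @return list with `intensity`, `samples`, `annotations`.
#' @export
read_dataset_csv <- function(dir, scale = "linear") {
  ints <- read.csv(file.path(dir, "intensity.csv"), check.names = FALSE)
  vals <- as.matrix(ints[, -1, drop = FALSE])
  rownames(vals) <- ints[[1]]
  samples <- read.csv(file.path(dir, "samples.csv"), stringsAsFactors = FALSE)
  ann <- read.csv(file.path(dir, "annotations.csv"), stringsAsFactors = FALSE)
  ann$uniprot_ids[is.na(ann$uniprot_ids)] <- ""
  list(intensity = intensity_matrix(vals, scale = scale),
       samples = samples, annotations = ann)
}
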