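#' Construct a mass-spectrometry protein quantification table
#'
#' Protein-level quantification from a DIA search export, keyed by UniProt
#' accession, with the peptide-identification metadata the overlap filters
#' act on.
#'
#' @param values proteins x samples numeric matrix (may contain NA);
#'   row names are UniProt accessions, column names sample ids.
#' @param uniprot accessions (defaults to row names).
#' @param gene gene symbols (optional).
#' @param n_peptides per-protein count of stripped (unmodified) peptides
#'   used for identification, dataset-wide.
#' @param proteotypic logical, whether the protein has at least one
#'   proteotypic peptide.
#' @param scale `"log2"` or `"linear"`.
#' @return an object of class `sfggm_ms`.
#' @export
ms_protein_table <- function(values, uniprot = rownames(values), gene = NULL,
                             n_peptides, proteotypic,
                             scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), length(uniprot) == nrow(values),
            length(n_peptides) == nrow(values),
            length(proteotypic) == nrow(values),
            all(n_peptides >= 0))
  if (anyDuplicated(uniprot)) stop("duplicated UniProt accessions")
  rownames(values) <- uniprot
  structure(list(values = values, uniprot = uniprot,
                 gene = if (is.null(gene)) rep(NA_character_, nrow(values))
                        else gene,
                 n_peptides = as.integer(n_peptides),
                 proteotypic = as.logical(proteotypic), scale = scale),
            class = "sfggm_ms")
}

#' Read a Spectronaut-like protein quantification TSV
#'
#' Expects columns `uniprot`, `gene`, `n_peptides`, `proteotypic`, then one
#' column per sample.
#'
#' @param path TSV path.
#' @param scale scale of the stored values.
#' @return an `sfggm_ms` object.
#' @export
read_ms_table <- function(path, scale = "log2") {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("uniprot", "gene", "n_peptides", "proteotypic")
  stopifnot(all(meta %in% names(d)))
  vals <- as.matrix(d[, setdiff(names(d), meta), drop = FALSE])
  rownames(vals) <- d$uniprot
  ms_protein_table(vals, uniprot = d$uniprot, gene = d$gene,
                   n_peptides = d$n_peptides,
                   proteotypic = as.logical(d$proteotypic), scale = scale)
}

#' Overlap filters between MS proteins and network proteins
#'
#' Intersects the MS table with the network protein set, then sequentially
#' drops proteins (1) without a proteotypic peptide, (2) identified by at
#' most one stripped peptide, and (3) with 50 percent or more missing
#' sample values.
#'
#' @param ms an `sfggm_ms` table.
#' @param network_proteins UniProt accessions of network nodes.
#' @return list with `retained` (accessions passing all filters) and
#'   `counts`: `overlap`, `removed_no_proteotypic`, `removed_single_peptide`,
#'   `removed_missingness`, `retained`.
#' @export
overlap_filter <- function(ms, network_proteins) {
  stopifnot(inherits(ms, "sfggm_ms"))
  keep <- intersect(ms$uniprot, network_proteins)
  n_overlap <- length(keep)
  if (n_overlap == 0)
    warning("no overlap between MS proteins and network proteins")
  i <- match(keep, ms$uniprot)
  pt <- ms$proteotypic[i]
  rm1 <- keep[!pt]; keep <- keep[pt]; i <- i[pt]
  multi <- ms$n_peptides[i] > 1
  rm2 <- keep[!multi]; keep <- keep[multi]; i <- i[multi]
  frac_nonmiss <- rowMeans(!is.na(ms$values[i, , drop = FALSE]))
  ok <- frac_nonmiss > 0.5
  rm3 <- keep[!ok]; keep <- keep[ok]
  list(retained = keep,
       counts = c(overlap = n_overlap,
                  removed_no_proteotypic = length(rm1),
                  removed_single_peptide = length(rm2),
                  removed_missingness = length(rm3),
                  retained = length(keep)))
}

#' Per-protein cross-platform correlation
#'
#' Pearson correlation between the two platforms per protein, computed on
#' z-scored log2 values across the shared samples with pairwise-complete
#' handling. Correlations based on fewer than 3 complete pairs are NA. The
#' result is invariant to affine rescaling of either platform.
#'
#' @param ms an `sfggm_ms` (log2 scale).
#' @param soma proteins x samples matrix of log2 aptamer values aggregated
#'   to the protein level (row names UniProt), or an `sfggm_intensity` plus
#'   `annotations` to aggregate internally.
#' @param annotations required when `soma` is an intensity matrix: used to
#'   average aptamers per protein.
#' @return data frame with columns `uniprot`, `r`, `n` (complete pairs).
#' @export
cross_correlate <- function(ms, soma, annotations = NULL) {
  stopifnot(inherits(ms, "sfggm_ms"))
  if (ms$scale != "log2") stop("MS values must be on the log2 scale")
  if (inherits(soma, "sfggm_intensity")) {
    if (is.null(annotations))
      stop("annotations needed to aggregate aptamers to proteins")
    soma <- aggregate_to_proteins(soma, annotations)
  }
  shared_samples <- intersect(colnames(ms$values), colnames(soma))
  if (length(shared_samples) < 3)
    stop("fewer than 3 shared samples between platforms")
  prots <- intersect(rownames(ms$values), rownames(soma))
  z <- function(x) {
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x, na.rm = TRUE)) / s
  }
  out <- lapply(prots, function(pr) {
    a <- z(ms$values[pr, shared_samples])
    b <- z(soma[pr, shared_samples])
    ok <- complete.cases(a, b)
    r <- if (sum(ok) < 3) NA_real_ else cor(a[ok], b[ok])
    data.frame(uniprot = pr, r = r, n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Average aptamer log2 values to the protein level
#'
#' @param matrix a log2 [intensity_matrix()].
#' @param annotations annotation table mapping seq_id to UniProt.
#' @return proteins x samples matrix.
#' @export
aggregate_to_proteins <- function(matrix, annotations) {
  stopifnot(inherits(matrix, "sfggm_intensity"))
  lv <- as_log2(matrix)$values
  prot <- annotations$uniprot_ids[match(colnames(lv), annotations$seq_id)]
  ok <- !is.na(prot) & nzchar(prot)
  lv <- lv[, ok, drop = FALSE]
  prot <- prot[ok]
  t(vapply(split(seq_along(prot), prot),
           function(j) rowMeans(lv[, j, drop = FALSE]),
           numeric(nrow(lv))))
}

#' Side-by-side fold changes from both platforms
#'
#' Fits the batched mixed model on the MS protein quantifications (protein
#' in place of aptamer: fixed effects group, protein, age, sex plus protein
#' interactions; random intercept per subject) and pairs the resulting
#' contrasts with the aptamer-platform contrasts per protein.
#'
#' @param ms an `sfggm_ms` (log2 scale).
#' @param samples sample metadata (`sample_id`, `subject_id`, `group`,
#'   `sex`, `age`).
#' @param soma_contrasts an `sfggm_contrasts` table from the aptamer
#'   platform (must carry `uniprot`).
#' @param contrast which contrast to compare.
#' @param level confidence level.
#' @param df_method degrees-of-freedom approximation.
#' @param ref_group reference group.
#' @return data frame with per-protein paired estimates
#'   (`log2fc_ms`, `ci_low_ms`, `ci_high_ms`, `log2fc_soma`, `ci_low_soma`,
#'   `ci_high_soma`) and `sign_agree`. Proteins absent on either platform
#'   are dropped with a note attribute `n_dropped`.
#' @export
compare_foldchanges <- function(ms, samples, soma_contrasts,
                                contrast = "mild-healthy", level = 0.95,
                                df_method = "satterthwaite",
                                ref_group = "healthy") {
  stopifnot(inherits(ms, "sfggm_ms"))
  keep_samp <- intersect(colnames(ms$values), samples$sample_id)
  lv <- t(ms$values[, keep_samp, drop = FALSE])   # samples x proteins
  lv <- lv[, colSums(!is.na(lv)) > 0, drop = FALSE]
  samples2 <- samples[samples$sample_id %in% rownames(lv), ]
  m2 <- structure(list(values = lv, scale = "log2",
                       sample_ids = rownames(lv), seq_ids = colnames(lv)),
                  class = "sfggm_intensity")
  fit <- fit_batch(m2, samples2, colnames(lv), ref_group = ref_group,
                   drop_na = TRUE)
  ms_ct <- batch_contrasts(fit, level = level, df_method = df_method,
                           batch_id = 1L)
  ms_ct <- ms_ct[ms_ct$contrast == contrast, ]
  soma <- soma_contrasts[soma_contrasts$contrast == contrast &
                           !is.na(soma_contrasts$uniprot), ]
  # one row per protein on the aptamer side: aptamer with smallest SE
  soma <- soma[order(soma$uniprot, soma$se), ]
  soma <- soma[!duplicated(soma$uniprot), ]
  merged <- merge(ms_ct, soma, by.x = "seq_id", by.y = "uniprot",
                  suffixes = c("_ms", "_soma"))
  out <- data.frame(uniprot = merged$seq_id,
                    log2fc_ms = merged$log2fc_ms,
                    ci_low_ms = merged$ci_low_ms,
                    ci_high_ms = merged$ci_high_ms,
                    log2fc_soma = merged$log2fc_soma,
                    ci_low_soma = merged$ci_low_soma,
                    ci_high_soma = merged$ci_high_soma,
                    stringsAsFactors = FALSE)
  out$sign_agree <- sign(out$log2fc_ms) == sign(out$log2fc_soma)
  attr(out, "n_dropped") <- nrow(ms_ct) - nrow(out)
  out[order(out$uniprot), , drop = FALSE]
}
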