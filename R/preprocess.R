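#' Construct an intensity matrix
#'
#' Samples-by-aptamers relative abundance values with an explicit scale flag,
#' the container all preprocessing operates on.
#'
#' @param values numeric matrix, samples in rows, aptamers in columns; must
#'   carry row and column names (sample and aptamer sequence identifiers).
#' @param scale `"linear"` (RFU) or `"log2"`.
#' @return an object of class `sfggm_intensity`.
#' @export
intensity_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have sample row names and aptamer column names")
  if (anyDuplicated(rownames(values))) stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicated aptamer identifiers")
  if (scale == "linear" && any(values <= 0))
    stop("linear-scale values must be strictly positive")
  structure(list(values = values, scale = scale,
                 sample_ids = rownames(values),
                 seq_ids = colnames(values)),
            class = "sfggm_intensity")
}

#' @exportS3Method base::print
print.sfggm_intensity <- function(x, ...) {
  cat(sprintf("<sfggm_intensity> %d samples x %d aptamers (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Subset an intensity matrix by samples and/or aptamers
#' @param m an `sfggm_intensity`.
#' @param samples,seq_ids identifiers to keep (default all).
#' @return an `sfggm_intensity`.
#' @export
subset_intensity <- function(m, samples = m$sample_ids, seq_ids = m$seq_ids) {
  stopifnot(inherits(m, "sfggm_intensity"))
  missing_s <- setdiff(samples, m$sample_ids)
  missing_a <- setdiff(seq_ids, m$seq_ids)
  if (length(missing_s)) stop("unknown samples: ", paste(missing_s, collapse = ", "))
  if (length(missing_a)) stop("unknown aptamers: ", paste(missing_a, collapse = ", "))
  intensity_matrix(m$values[samples, seq_ids, drop = FALSE], scale = m$scale)
}

#' Log2-transform a linear-scale intensity matrix
#'
#' @param m a linear-scale [intensity_matrix()]; strictly positive.
#' @return the log2-scale matrix. Applying it to an already log2 matrix is
#'   refused (idempotence guard).
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "sfggm_intensity"))
  if (m$scale == "log2")
    stop("matrix is already on the log2 scale")
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("nonpositive values at (sample, aptamer): ",
         paste(sprintf("(%s, %s)", rownames(m$values)[bad[, 1]],
                       colnames(m$values)[bad[, 2]]), collapse = ", "))
  intensity_matrix(log2(m$values), scale = "log2")
}

# internal: coerce to log2 scale whichever scale the input carries
as_log2 <- function(m) if (m$scale == "log2") m else log2_transform(m)

#' Per-aptamer limit of detection from buffer wells
#'
#' LOD is computed on the log2 scale as the buffer mean plus five times the
#' buffer sample standard deviation (n-1 denominator). Linear-scale input is
#' log2-transformed internally.
#'
#' @param buffer_matrix an [intensity_matrix()] holding only buffer samples.
#' @param k multiplier on the buffer SD (default 5).
#' @return an object of class `sfggm_lod`: data frame with columns `seq_id`
#'   and `lod` (log2 scale), and attribute `n_buffer`.
#' @export
compute_lod <- function(buffer_matrix, k = 5) {
  stopifnot(inherits(buffer_matrix, "sfggm_intensity"))
  n_buf <- nrow(buffer_matrix$values)
  if (n_buf < 2)
    stop("at least 2 buffer samples required to compute the LOD for ",
         ncol(buffer_matrix$values), " aptamers (got ", n_buf, ")")
  lv <- as_log2(buffer_matrix)$values
  lod <- apply(lv, 2, mean) + k * apply(lv, 2, sd)
  out <- data.frame(seq_id = colnames(lv), lod = unname(lod),
                    stringsAsFactors = FALSE)
  attr(out, "n_buffer") <- n_buf
  class(out) <- c("sfggm_lod", "data.frame")
  out
}

#' Three-stage aptamer filtering
#'
#' Applies, sequentially: (1) remove aptamers not mapped to any UniProt ID;
#' (2) remove aptamers whose target organism is not in the allow-list;
#' (3) remove aptamers whose log2 value falls below the limit of detection in
#' any study sample. An aptamer failing several criteria is counted once, at
#' the first failing stage.
#'
#' @param matrix an [intensity_matrix()] of study samples only (no buffer).
#' @param annotations data frame with columns `seq_id`, `uniprot_ids`,
#'   `organism`, covering every aptamer in `matrix`.
#' @param lods an `sfggm_lod` from [compute_lod()]; pass `NULL` to skip the
#'   LOD stage.
#' @param organisms_allowed case-insensitive organism allow-list.
#' @return list with `matrix` (filtered, same scale as input) and `report`,
#'   an `sfggm_filter_report` with per-stage removal counts, removed
#'   identifier lists and retained aptamer/protein counts.
#' @export
filter_aptamers <- function(matrix, annotations, lods,
                            organisms_allowed = c("Human", "Homo sapiens")) {
  stopifnot(inherits(matrix, "sfggm_intensity"))
  ids <- matrix$seq_ids
  miss <- setdiff(ids, annotations$seq_id)
  if (length(miss))
    stop("missing annotation for: ", paste(miss, collapse = ", "))
  ann <- annotations[match(ids, annotations$seq_id), ]

  up <- ann$uniprot_ids
  up[is.na(up)] <- ""
  rm_unmapped <- ids[!nzchar(trimws(up))]
  keep <- setdiff(ids, rm_unmapped)

  org_ok <- tolower(trimws(ann$organism[match(keep, ann$seq_id)])) %in%
    tolower(organisms_allowed)
  rm_nonhuman <- keep[!org_ok]
  keep <- setdiff(keep, rm_nonhuman)

  rm_lod <- character(0)
  if (!is.null(lods)) {
    lv <- as_log2(matrix)$values[, keep, drop = FALSE]
    lod_vec <- lods$lod[match(keep, lods$seq_id)]
    if (anyNA(lod_vec))
      stop("no LOD for: ", paste(keep[is.na(lod_vec)], collapse = ", "))
    below <- vapply(seq_along(keep),
                    function(j) any(lv[, j] < lod_vec[j]), logical(1))
    rm_lod <- keep[below]
    keep <- setdiff(keep, rm_lod)
  }

  retained_proteins <- length(unique(
    ann$uniprot_ids[match(keep, ann$seq_id)]))
  report <- structure(list(
    n_input = length(ids),
    removed = c(unmapped = length(rm_unmapped),
                nonhuman = length(rm_nonhuman),
                below_lod = length(rm_lod)),
    removed_ids = list(unmapped = rm_unmapped, nonhuman = rm_nonhuman,
                       below_lod = rm_lod),
    n_retained = length(keep),
    n_retained_proteins = retained_proteins),
    class = "sfggm_filter_report")
  list(matrix = subset_intensity(matrix, seq_ids = keep), report = report)
}

#' @exportS3Method base::print
print.sfggm_filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<sfggm_filter_report> %d aptamers in\n",
    "  removed: %d unmapped, %d non-human, %d below LOD\n",
    "  retained: %d aptamers (%d proteins)\n"),
    x$n_input, x$removed["unmapped"], x$removed["nonhuman"],
    x$removed["below_lod"], x$n_retained, x$n_retained_proteins))
  invisible(x)
}

#' Repeatability coefficients from replicate sample pairs
#'
#' For each aptamer quantified above the limit of detection in every
#' replicate sample, the within-pair SD is
#' \eqn{s_w = \sqrt{\sum_i d_i^2 / (2m)}} over the m pairs, where
#' \eqn{d_i} is the within-pair log2 difference. The repeatability
#' coefficient on the log2 scale is \eqn{RC = 1.96 \sqrt{2} s_w}, reported
#' as a percentage on the fold scale, \eqn{100 (2^{RC} - 1)}.
#'
#' @param pairs two-column data frame or matrix of replicate sample-id pairs.
#' @param matrix a log2-scale [intensity_matrix()] containing all replicate
#'   samples.
#' @param lods an `sfggm_lod`; pass `NULL` to skip the eligibility filter.
#' @return data frame with columns `seq_id`, `s_w`, `rc_log2`, `rc_percent`
#'   for eligible aptamers only (ineligible aptamers are excluded, not set
#'   to zero). Zero eligible aptamers yields an empty result with a warning.
#' @export
repeatability_coefficients <- function(pairs, matrix, lods) {
  stopifnot(inherits(matrix, "sfggm_intensity"))
  if (matrix$scale != "log2")
    stop("repeatability coefficients are defined on the log2 scale")
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2, nrow(pairs) >= 1)
  rep_samples <- unique(as.vector(pairs))
  miss <- setdiff(rep_samples, matrix$sample_ids)
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  lv <- matrix$values[rep_samples, , drop = FALSE]
  eligible <- rep(TRUE, ncol(lv))
  if (!is.null(lods)) {
    lod_vec <- lods$lod[match(colnames(lv), lods$seq_id)]
    eligible <- !is.na(lod_vec) &
      vapply(seq_len(ncol(lv)), function(j) all(lv[, j] > lod_vec[j]),
             logical(1))
  }
  if (!any(eligible)) {
    warning("no aptamer above LOD in all replicate samples")
    return(data.frame(seq_id = character(0), s_w = numeric(0),
                      rc_log2 = numeric(0), rc_percent = numeric(0)))
  }
  m <- nrow(pairs)
  d <- matrix$values[pairs[, 1], eligible, drop = FALSE] -
    matrix$values[pairs[, 2], eligible, drop = FALSE]
  s_w <- sqrt(colSums(d^2) / (2 * m))
  rc <- 1.96 * sqrt(2) * s_w
  data.frame(seq_id = colnames(lv)[eligible], s_w = unname(s_w),
             rc_log2 = unname(rc), rc_percent = unname(100 * (2^rc - 1)),
             stringsAsFactors = FALSE)
}
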