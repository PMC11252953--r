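#' Randomized batch plan for iterative mixed-model fitting
#'
#' Fitting one mixed model to all aptamers at once is infeasible; a random
#' permutation of the aptamers is chunked into batches (default 50 per
#' batch) and one model is fitted per batch, retaining the shrinkage benefit
#' of a pooled residual variance within each batch.
#'
#' @param seq_ids aptamer identifiers to partition.
#' @param batch_size maximum aptamers per batch (default 50).
#' @param seed RNG seed; the plan is deterministic given the seed.
#' @return an `sfggm_batch_plan`: list with `batches` (list of character
#'   vectors partitioning `seq_ids`), `batch_size`, `seed`.
#' @export
plan_batches <- function(seq_ids, batch_size = 50, seed = 1L) {
  stopifnot(batch_size >= 1, length(seq_ids) >= 1)
  set.seed(seed)
  perm <- sample(seq_ids)
  n_batches <- ceiling(length(seq_ids) / batch_size)
  idx <- rep(seq_len(n_batches), each = batch_size)[seq_along(perm)]
  structure(list(batches = split(perm, idx), batch_size = batch_size,
                 seed = seed),
            class = "sfggm_batch_plan")
}

# long-format data for one batch: one row per (study sample, aptamer)
.batch_long <- function(matrix_log2, samples, batch, ref_group) {
  stopifnot(inherits(matrix_log2, "sfggm_intensity"))
  if (matrix_log2$scale != "log2")
    stop("differential abundance is fitted on log2 values")
  miss <- setdiff(batch, matrix_log2$seq_ids)
  if (length(miss)) stop("aptamers absent from matrix: ",
                         paste(miss, collapse = ", "))
  st <- samples[samples$sample_id %in% matrix_log2$sample_ids, ]
  if (!is.null(st$sample_type)) st <- st[st$sample_type == "study", ]
  if (!is.null(st$replicate_of)) st <- st[is.na(st$replicate_of), ]
  vals <- matrix_log2$values[st$sample_id, batch, drop = FALSE]
  grp_levels <- c(ref_group, setdiff(unique(st$group), ref_group))
  long <- data.frame(
    value = as.vector(vals),
    sample_id = rep(st$sample_id, times = length(batch)),
    subject_id = rep(st$subject_id, times = length(batch)),
    group = factor(rep(st$group, times = length(batch)), levels = grp_levels),
    sex = factor(rep(st$sex, times = length(batch))),
    age = rep(st$age, times = length(batch)),
    seq_id = factor(rep(batch, each = nrow(st)), levels = batch),
    stringsAsFactors = FALSE)
  long
}

#' Fit one batched linear mixed model
#'
#' One model per batch on long-format data (one row per sample x aptamer):
#' fixed effects are aptamer, group, sex, age and the aptamer interactions
#' with each; the study subject enters as a random intercept, accounting for
#' the clustering of aptamer measurements within a donor. Fitted by REML.
#' When the mixed fit is singular or fails (e.g. zero residual variance, or
#' a single-aptamer batch where the subject intercept is confounded with the
#' residual), a fixed-effects-only fit is returned and flagged; contrast
#' degrees of freedom then fall back to the residual df.
#'
#' @param matrix_log2 log2-scale [intensity_matrix()].
#' @param samples sample metadata with `sample_id`, `subject_id`, `group`,
#'   `sex`, `age` (buffer and replicate rows, if present, are dropped).
#' @param batch character vector of aptamer seq_ids.
#' @param ref_group reference group label for contrasts.
#' @param drop_na drop rows with missing values from the long-format data
#'   (used for protein-level tables with missingness).
#' @return an `sfggm_batch_fit`: list with the fitted `model`, the `batch`,
#'   `singular`/`fallback_lm` flags and the reference group.
#' @export
fit_batch <- function(matrix_log2, samples, batch, ref_group = "healthy",
                      drop_na = FALSE) {
  long <- .batch_long(matrix_log2, samples, batch, ref_group)
  if (drop_na) long <- long[!is.na(long$value), ]
  multi_apt <- length(batch) > 1
  use_sex <- nlevels(droplevels(long$sex)) > 1
  use_age <- length(unique(long$age)) > 1
  covars <- c("group", if (use_sex) "sex", if (use_age) "age")
  rhs <- if (multi_apt)
    paste0("seq_id * (", paste(covars, collapse = " + "), ")")
  else paste(covars, collapse = " + ")
  f_mixed <- stats::as.formula(paste("value ~", rhs, "+ (1 | subject_id)"))
  f_fixed <- stats::as.formula(paste("value ~", rhs))
  fallback <- FALSE
  singular <- FALSE
  model <- tryCatch(
    withCallingHandlers(
      lmerTest::lmer(f_mixed, data = long, REML = TRUE),
      message = function(m) invokeRestart("muffleMessage"),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (!is.null(model) && lme4::isSingular(model, tol = 1e-5)) singular <- TRUE
  if (is.null(model)) {
    model <- lm(f_fixed, data = long)
    fallback <- TRUE
    singular <- TRUE
  }
  structure(list(model = model, batch = batch, ref_group = ref_group,
                 singular = singular, fallback_lm = fallback,
                 n_samples = length(unique(long$sample_id))),
            class = "sfggm_batch_fit")
}

#' Group contrasts with confidence intervals for one batch fit
#'
#' Per aptamer in the batch, the linear contrasts of adjusted group means
#' (numeric covariates at their mean, factors averaged over levels) against
#' the reference group, with t-based confidence intervals. Degrees of
#' freedom use the Satterthwaite approximation by default; Kenward-Roger is
#' available when the pbkrtest package is installed.
#'
#' @param fit an `sfggm_batch_fit`.
#' @param level confidence level (default 0.95).
#' @param df_method `"satterthwaite"` or `"kenward-roger"`.
#' @param batch_id identifier recorded in the output rows.
#' @return data frame with columns `seq_id`, `contrast`, `log2fc`, `se`,
#'   `df`, `ci_low`, `ci_high`, `batch_id`, `singular`.
#' @export
batch_contrasts <- function(fit, level = 0.95,
                            df_method = c("satterthwaite", "kenward-roger"),
                            batch_id = NA_integer_) {
  stopifnot(inherits(fit, "sfggm_batch_fit"))
  df_method <- match.arg(df_method)
  mode <- if (df_method == "satterthwaite") "satterthwaite" else "kenward-roger"
  multi_apt <- length(fit$batch) > 1
  spec <- if (multi_apt) ~ group | seq_id else ~ group
  emm <- suppressMessages(emmeans::emmeans(
    fit$model, spec, lmer.df = mode,
    lmerTest.limit = 1e6, pbkrtest.limit = 1e6))
  ctr <- emmeans::contrast(emm, method = "trt.vs.ctrl",
                           ref = fit$ref_group)
  cs <- as.data.frame(stats::confint(ctr, level = level))
  lab <- gsub(" ", "", as.character(cs$contrast))
  lab <- gsub("[()]", "", lab)
  seq_id <- if (multi_apt) as.character(cs$seq_id) else fit$batch
  data.frame(seq_id = seq_id, contrast = lab,
             log2fc = cs$estimate, se = cs$SE, df = cs$df,
             ci_low = cs$lower.CL, ci_high = cs$upper.CL,
             batch_id = batch_id, singular = fit$singular,
             stringsAsFactors = FALSE)
}

#' Batched mixed-model differential abundance over all aptamers
#'
#' Plans random batches, fits one mixed model per batch and collects the
#' per-aptamer group contrasts into one table.
#'
#' @inheritParams fit_batch
#' @param annotations optional annotation table used to attach `uniprot` and
#'   `gene` columns.
#' @param batch_size,seed passed to [plan_batches()].
#' @param level confidence level.
#' @param df_method degrees-of-freedom approximation, see [batch_contrasts()].
#' @return an `sfggm_contrasts` data frame with columns `seq_id`, `uniprot`,
#'   `gene`, `contrast`, `log2fc`, `se`, `df`, `ci_low`, `ci_high`,
#'   `batch_id`, `singular`.
#' @export
diff_abundance <- function(matrix_log2, samples, annotations = NULL,
                           batch_size = 50, seed = 1L, level = 0.95,
                           df_method = "satterthwaite",
                           ref_group = "healthy") {
  plan <- plan_batches(matrix_log2$seq_ids, batch_size = batch_size,
                       seed = seed)
  out <- vector("list", length(plan$batches))
  for (b in seq_along(plan$batches)) {
    fit <- fit_batch(matrix_log2, samples, plan$batches[[b]],
                     ref_group = ref_group)
    out[[b]] <- batch_contrasts(fit, level = level, df_method = df_method,
                                batch_id = b)
  }
  tab <- do.call(rbind, out)
  if (!is.null(annotations)) {
    i <- match(tab$seq_id, annotations$seq_id)
    tab$uniprot <- annotations$uniprot_ids[i]
    tab$gene <- annotations$gene_symbol[i]
  } else {
    tab$uniprot <- NA_character_
    tab$gene <- NA_character_
  }
  tab <- tab[, c("seq_id", "uniprot", "gene", "contrast", "log2fc", "se",
                 "df", "ci_low", "ci_high", "batch_id", "singular")]
  rownames(tab) <- NULL
  class(tab) <- c("sfggm_contrasts", "data.frame")
  tab
}

#' Flag differentially abundant aptamers by their confidence interval
#'
#' An aptamer is flagged up-regulated when its CI lower bound exceeds zero
#' and down-regulated when its CI upper bound is below zero.
#'
#' @param table an `sfggm_contrasts` data frame.
#' @return the table with logical `up` and `down` columns added.
#' @export
flag_differential <- function(table) {
  stopifnot(all(c("ci_low", "ci_high") %in% names(table)))
  table$up <- table$ci_low > 0
  table$down <- table$ci_high < 0
  table
}

#' Protein-level counts of differential proteins per contrast
#'
#' Collapses aptamers by UniProt accession; a protein counts as up (down)
#' regulated in a contrast when any of its aptamers is flagged.
#'
#' @param table a flagged contrast table (see [flag_differential()]).
#' @return data frame with columns `contrast`, `n_up`, `n_down`,
#'   `n_proteins`.
#' @export
count_differential_proteins <- function(table) {
  if (!all(c("up", "down") %in% names(table))) table <- flag_differential(table)
  tab <- table[!is.na(table$uniprot) & nzchar(table$uniprot), ]
  out <- lapply(split(tab, tab$contrast), function(d) {
    data.frame(contrast = d$contrast[1],
               n_up = length(unique(d$uniprot[d$up])),
               n_down = length(unique(d$uniprot[d$down])),
               n_proteins = length(unique(d$uniprot)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
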