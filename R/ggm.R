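#' Select aptamers with the largest absolute fold changes
#'
#' Ranks aptamers by the absolute log2 fold change of the chosen contrast
#' (descending) and takes the top n for inclusion in the graphical models.
#' Ties are broken by smaller standard error, then lexicographic seq_id.
#'
#' @param contrasts an `sfggm_contrasts` table (see [diff_abundance()]).
#' @param n_aptamers number of aptamers to keep (default 800).
#' @param contrast contrast label used for ranking (default the
#'   mild-versus-healthy contrast, the two groups modelled jointly).
#' @return character vector of selected seq_ids in rank order, with
#'   attributes `n_proteins` (unique protein count among the selection) and
#'   `contrast`.
#' @export
select_features <- function(contrasts, n_aptamers = 800,
                            contrast = "mild-healthy") {
  tab <- contrasts[contrasts$contrast == contrast, ]
  if (nrow(tab) == 0)
    stop("no rows for contrast ", contrast)
  tab <- tab[!is.na(tab$log2fc), ]
  ord <- order(-abs(tab$log2fc), tab$se, tab$seq_id)
  tab <- tab[ord, ]
  if (n_aptamers > nrow(tab)) {
    warning("requested ", n_aptamers, " aptamers but only ", nrow(tab),
            " available; taking all")
    n_aptamers <- nrow(tab)
  }
  sel <- tab$seq_id[seq_len(n_aptamers)]
  n_prot <- length(unique(tab$uniprot[seq_len(n_aptamers)]))
  structure(sel, n_proteins = n_prot, contrast = contrast)
}

#' Standardize per-group data matrices
#'
#' Per group and per column: subtract the mean and divide by the sample SD,
#' as required for comparable penalization across variables.
#'
#' @param X_list named list of samples x variables matrices, one per group,
#'   all with the same column set.
#' @return list of standardized matrices.
#' @export
standardize_groups <- function(X_list) {
  stopifnot(is.list(X_list), length(X_list) >= 1)
  cols <- colnames(X_list[[1]])
  for (X in X_list) {
    stopifnot(is.matrix(X), nrow(X) >= 3)
    if (!identical(colnames(X), cols))
      stop("groups must share an identical variable set")
  }
  lapply(X_list, function(X) {
    sds <- apply(X, 2, sd)
    zero <- which(sds == 0)
    if (length(zero))
      stop("zero-variance columns: ", paste(cols[zero], collapse = ", "))
    scale(X, center = TRUE, scale = sds)[, , drop = FALSE]
  })
}

#' Joint node-wise group-lasso regression across groups
#'
#' Estimates group-specific conditional-dependence structure jointly by
#' minimizing
#' \deqn{\sum_k \frac{1}{2 n_k}\|X^{(k)} - X^{(k)}(\Omega + \Gamma^{(k)})\|_F^2
#'  + \lambda_1 \sum_{i<j}\|(\Omega_{ij},\Omega_{ji})\|_2
#'  + \lambda_2 \sum_k \sum_{i<j}\|(\Gamma^{(k)}_{ij},\Gamma^{(k)}_{ji})\|_2}
#' over coefficient matrices with zero diagonals, where \eqn{\Omega} carries
#' the structure common to all groups and \eqn{\Gamma^{(k)}} the
#' group-specific deviations. The group penalty on symmetric coefficient
#' pairs enforces symmetric edge activation. Solved by block coordinate
#' descent with group soft-thresholding, from zero initialization, cycling
#' common blocks in (i, j) lexicographic order then specific blocks per
#' group, until the largest coefficient change falls below `tol`.
#'
#' @param X_list named list of standardized samples x variables matrices.
#' @param lambda1 common-structure penalty (default 0.1).
#' @param lambda2 group-specific penalty (default 0.001).
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter maximum sweeps.
#' @param trace record the objective value after every sweep.
#' @return an object of class `jewel_fit`: list with `Omega`, `Gamma`
#'   (per-group list), `Theta` (per-group `Omega + Gamma`), `adjacency`
#'   (per-group symmetric logical matrices; an edge is present when either
#'   of its two coefficients is nonzero), `rss` (per-group per-column
#'   residual sums of squares), `n_per_group`, `iterations`, `converged`,
#'   `objective` (sweep trace if requested), `lambda1`, `lambda2`.
#' @export
fit_jewel <- function(X_list, lambda1 = 0.1, lambda2 = 0.001,
                      tol = 1e-4, max_iter = 3000, trace = FALSE) {
  stopifnot(is.list(X_list), length(X_list) >= 1, lambda1 >= 0, lambda2 >= 0)
  vars <- colnames(X_list[[1]])
  for (X in X_list)
    if (!identical(colnames(X), vars))
      stop("mismatched variable sets across groups")
  res <- jewel_cd(lapply(X_list, unname), lambda1, lambda2, tol,
                  as.integer(max_iter), isTRUE(trace))
  K <- length(X_list)
  gn <- names(X_list)
  if (is.null(gn)) gn <- paste0("group", seq_len(K))
  dimnames(res$Omega) <- list(vars, vars)
  Gamma <- setNames(res$Gamma, gn)
  Theta <- vector("list", K)
  adjacency <- vector("list", K)
  for (k in seq_len(K)) {
    dimnames(Gamma[[k]]) <- list(vars, vars)
    Theta[[k]] <- res$Omega + Gamma[[k]]
    A <- (Theta[[k]] != 0) | t(Theta[[k]] != 0)
    diag(A) <- FALSE
    adjacency[[k]] <- A
  }
  names(Theta) <- names(adjacency) <- gn
  if (!res$converged)
    warning("coordinate descent did not converge in ", max_iter, " sweeps")
  structure(list(Omega = res$Omega, Gamma = Gamma, Theta = Theta,
                 adjacency = adjacency,
                 rss = setNames(res$rss, gn),
                 n_per_group = vapply(X_list, nrow, integer(1)),
                 iterations = res$iterations, converged = res$converged,
                 objective = res$objective,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "jewel_fit")
}

#' Edge list of a fitted adjacency
#' @param fit a `jewel_fit`.
#' @param group group name or index.
#' @return two-column matrix of variable-index pairs (i < j).
#' @export
fit_edges <- function(fit, group = 1) {
  A <- fit$adjacency[[group]]
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- list(NULL, c("i", "j"))
  idx
}

#' Bayesian Information Criterion of a joint fit
#'
#' \deqn{BIC = \sum_k \left[\sum_j n_k \log(RSS_{jk}/n_k)\right]
#'  + \log(n_k) \cdot 2 E_k}
#' where \eqn{RSS_{jk}} is the residual sum of squares of column j in group
#' k and \eqn{E_k} the number of active symmetric coefficient blocks (edges)
#' in group k; each active block contributes its two free coefficients to
#' the model dimension.
#'
#' @param fit a `jewel_fit`.
#' @return the BIC value (numeric scalar).
#' @export
jewel_bic <- function(fit) {
  stopifnot(inherits(fit, "jewel_fit"))
  bic <- 0
  for (k in seq_along(fit$rss)) {
    n_k <- unname(fit$n_per_group[k])
    rss <- pmax(fit$rss[[k]], .Machine$double.eps)
    edges_k <- sum(fit$adjacency[[k]]) / 2
    bic <- bic + sum(n_k * log(rss / n_k)) + log(n_k) * 2 * edges_k
  }
  bic
}

#' Two-stage BIC search over the regularization pair
#'
#' Scans `grid1` for the common penalty with the specific penalty held at
#' `lambda2_fixed`, picks the BIC argmin, then scans `grid2` for the
#' specific penalty with the common penalty fixed at that choice. Stability
#' selection is not applied during the search. Edge counts of every
#' candidate are reported alongside the BIC path.
#'
#' @param X_list standardized per-group matrices.
#' @param grid1 candidate common penalties (default 8 values in [0.01, 0.25]).
#' @param grid2 candidate specific penalties (default 7 values in
#'   [0.0001, 0.1], log-spaced).
#' @param lambda2_fixed specific penalty held fixed during stage one.
#' @param tol,max_iter passed to [fit_jewel()].
#' @return list with `lambda1`, `lambda2` (the chosen pair) and `path`, a
#'   data frame with columns `stage`, `lambda1`, `lambda2`, `bic`, and the
#'   per-group edge counts.
#' @export
bic_select <- function(X_list,
                       grid1 = seq(0.01, 0.25, length.out = 8),
                       grid2 = 10^seq(-4, -1, length.out = 7),
                       lambda2_fixed = 0.001,
                       tol = 1e-4, max_iter = 3000) {
  stopifnot(length(grid1) >= 1, length(grid2) >= 1)
  eval_pair <- function(l1, l2, stage) {
    fit <- fit_jewel(X_list, lambda1 = l1, lambda2 = l2, tol = tol,
                     max_iter = max_iter)
    if (!fit$converged) return(NULL)
    edges <- vapply(fit$adjacency, function(A) sum(A) / 2, numeric(1))
    cbind(data.frame(stage = stage, lambda1 = l1, lambda2 = l2,
                     bic = jewel_bic(fit)),
          as.data.frame(as.list(setNames(edges,
                                         paste0("edges_", names(edges))))))
  }
  path1 <- do.call(rbind, lapply(grid1, eval_pair, l2 = lambda2_fixed,
                                 stage = 1L))
  if (is.null(path1)) stop("no candidate fit converged in stage 1")
  best1 <- path1$lambda1[which.min(path1$bic)]
  path2 <- do.call(rbind, lapply(grid2, function(l2)
    eval_pair(best1, l2, stage = 2L)))
  if (is.null(path2)) stop("no candidate fit converged in stage 2")
  best2 <- path2$lambda2[which.min(path2$bic)]
  list(lambda1 = best1, lambda2 = best2, path = rbind(path1, path2))
}

#' Stability selection over variable subsets
#'
#' Repeatedly refits the joint model on random subsets of the variables and
#' retains only edges appearing in a high fraction of the refits in which
#' both endpoints were present. For each of B resamples, a uniform random
#' subset of `ceiling(subset_fraction * p)` variables is drawn and the joint
#' fit run on the restricted matrices; an edge's stability frequency is its
#' presence count divided by its endpoint co-occurrence count. Edges with
#' frequency at least `pi_thr` are retained per group; the final node set is
#' every variable with at least one retained edge in either group.
#'
#' @param X_list standardized per-group matrices (shared column set).
#' @param lambda1,lambda2 the fixed regularization pair.
#' @param B number of resamples (default 1000).
#' @param pi_thr retention threshold on the stability frequency (default
#'   0.8).
#' @param subset_fraction fraction of variables per resample (default 0.8).
#' @param seed RNG seed.
#' @param tol,max_iter passed to [fit_jewel()].
#' @return an object of class `joint_graph`: list with per-group `adjacency`
#'   (retained edges, symmetric logical over all p variables), `frequency`
#'   (per-group matrices, NA where endpoints never co-occurred),
#'   `cooccurrence` (integer matrix of times both endpoints were sampled),
#'   `n_never_cooccurred` diagnostics count, `nodes` (retained node names),
#'   parameters, and `seed`.
#' @export
stability_selection <- function(X_list, lambda1 = 0.1, lambda2 = 0.001,
                                B = 1000, pi_thr = 0.8,
                                subset_fraction = 0.8, seed = 1L,
                                tol = 1e-4, max_iter = 3000) {
  stopifnot(B >= 1, pi_thr > 0, pi_thr <= 1,
            subset_fraction > 0, subset_fraction <= 1)
  vars <- colnames(X_list[[1]])
  p <- length(vars)
  K <- length(X_list)
  gn <- names(X_list)
  if (is.null(gn)) gn <- paste0("group", seq_len(K))
  m <- ceiling(subset_fraction * p)
  present <- replicate(K, matrix(0L, p, p), simplify = FALSE)
  cooc <- matrix(0L, p, p)
  set.seed(seed)
  for (b in seq_len(B)) {
    sub <- sort(sample(p, m))
    Xi <- lapply(X_list, function(X) X[, sub, drop = FALSE])
    fit <- fit_jewel(Xi, lambda1 = lambda1, lambda2 = lambda2, tol = tol,
                     max_iter = max_iter)
    cooc[sub, sub] <- cooc[sub, sub] + 1L
    for (k in seq_len(K))
      present[[k]][sub, sub] <- present[[k]][sub, sub] +
        fit$adjacency[[k]]
  }
  diag(cooc) <- 0L
  frequency <- vector("list", K)
  adjacency <- vector("list", K)
  for (k in seq_len(K)) {
    f <- ifelse(cooc > 0, present[[k]] / pmax(cooc, 1L), NA_real_)
    dimnames(f) <- list(vars, vars)
    frequency[[k]] <- f
    A <- !is.na(f) & f >= pi_thr
    diag(A) <- FALSE
    adjacency[[k]] <- A
  }
  names(frequency) <- names(adjacency) <- gn
  keep <- vars[Reduce(`|`, lapply(adjacency, function(A) rowSums(A) > 0))]
  dimnames(cooc) <- list(vars, vars)
  structure(list(adjacency = adjacency, frequency = frequency,
                 cooccurrence = cooc,
                 n_never_cooccurred = sum(cooc[upper.tri(cooc)] == 0),
                 nodes = keep, lambda1 = lambda1, lambda2 = lambda2,
                 B = B, pi_thr = pi_thr, subset_fraction = subset_fraction,
                 seed = seed),
            class = "joint_graph")
}

#' Convert retained per-group edges to igraph objects
#'
#' @param est a `joint_graph` from [stability_selection()], or a
#'   `jewel_fit`.
#' @param nodes restrict to these node names (default: nodes with at least
#'   one retained edge in either group for a `joint_graph`, all variables
#'   for a `jewel_fit`).
#' @return named list of undirected igraph objects, one per group.
#' @export
graphs_from_estimate <- function(est, nodes = NULL) {
  adj <- est$adjacency
  if (is.null(nodes))
    nodes <- if (inherits(est, "joint_graph")) est$nodes else
      colnames(adj[[1]])
  lapply(adj, function(A) {
    A <- A[nodes, nodes, drop = FALSE]
    igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  })
}

#' Relabel aptamer-level graphs at the protein level
#'
#' Maps each aptamer node to its protein (UniProt accession or gene symbol)
#' and merges nodes mapping to the same protein by taking the union of
#' their edges. Self-loops arising from merged duplicate aptamers are
#' dropped.
#'
#' @param graphs named list of igraph objects with aptamer seq_id names.
#' @param annotations annotation table with `seq_id`, `uniprot_ids`,
#'   `gene_symbol`.
#' @param label `"gene_symbol"` (default) or `"uniprot_ids"`.
#' @return named list of protein-level igraph objects.
#' @export
collapse_to_proteins <- function(graphs, annotations,
                                 label = c("gene_symbol", "uniprot_ids")) {
  label <- match.arg(label)
  lapply(graphs, function(g) {
    ids <- igraph::V(g)$name
    prot <- annotations[[label]][match(ids, annotations$seq_id)]
    prot[is.na(prot) | !nzchar(prot)] <- ids[is.na(prot) | !nzchar(prot)]
    groups <- match(prot, unique(prot))
    gc <- igraph::contract(g, groups, vertex.attr.comb = "first")
    igraph::V(gc)$name <- unique(prot)
    igraph::simplify(gc, remove.multiple = TRUE, remove.loops = TRUE)
  })
}

#' Write per-group graphs as an edge-list TSV and GraphML
#'
#' @param est a `joint_graph`.
#' @param tsv_path path for the edge list (columns `node_a`, `node_b`,
#'   `group`, `frequency`); pass `NULL` to skip.
#' @param graphml_prefix prefix for per-group GraphML files; pass `NULL` to
#'   skip.
#' @return invisibly, the edge-list data frame.
#' @export
write_graphs <- function(est, tsv_path = NULL, graphml_prefix = NULL) {
  stopifnot(inherits(est, "joint_graph"))
  rows <- list()
  for (gname in names(est$adjacency)) {
    A <- est$adjacency[[gname]]
    idx <- which(A & upper.tri(A), arr.ind = TRUE)
    if (nrow(idx))
      rows[[gname]] <- data.frame(
        node_a = rownames(A)[idx[, 1]], node_b = colnames(A)[idx[, 2]],
        group = gname,
        frequency = est$frequency[[gname]][idx],
        stringsAsFactors = FALSE)
  }
  el <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_a = character(0), node_b = character(0),
               group = character(0), frequency = numeric(0))
  rownames(el) <- NULL
  if (!is.null(tsv_path))
    write.table(el, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(graphml_prefix)) {
    gs <- graphs_from_estimate(est)
    for (gname in names(gs))
      igraph::write_graph(gs[[gname]],
                          paste0(graphml_prefix, "_", gname, ".graphml"),
                          format = "graphml")
  }
  invisible(el)
}
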