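#' Partition two group graphs into shared and unique edges
#'
#' Takes the union of the two node sets, classifies every edge as shared
#' (present in both groups) or unique to one group, and builds the
#' unique-edge subgraphs in which only nodes incident to at least one unique
#' edge are kept.
#'
#' @param g1,g2 undirected igraph objects with named vertices.
#' @param names labels for the two groups (defaults to `"g1"`, `"g2"`).
#' @return an object of class `diff_network`: list with `full` (both input
#'   graphs on the union node set), `shared` (graph of shared edges),
#'   `unique` (per-group unique-edge subgraphs, isolated nodes dropped) and
#'   `counts` (node/edge counts per category).
#' @export
partition_edges <- function(g1, g2, names = c("g1", "g2")) {
  stopifnot(length(names) == 2)
  all_nodes <- union(igraph::V(g1)$name, igraph::V(g2)$name)
  expand <- function(g) {
    add <- setdiff(all_nodes, igraph::V(g)$name)
    if (length(add)) g <- igraph::add_vertices(g, length(add), name = add)
    g
  }
  g1 <- expand(g1); g2 <- expand(g2)
  e1 <- .edge_set(g1); e2 <- .edge_set(g2)
  shared_keys <- intersect(e1, e2)
  u1 <- setdiff(e1, e2); u2 <- setdiff(e2, e1)
  mk <- function(keys) {
    if (!length(keys))
      return(igraph::make_empty_graph(n = 0, directed = FALSE))
    em <- do.call(rbind, strsplit(keys, "\u001f", fixed = TRUE))
    igraph::graph_from_edgelist(em, directed = FALSE)
  }
  shared_g <- mk(shared_keys)
  uniq <- list(mk(u1), mk(u2))
  names(uniq) <- names
  full <- list(g1, g2)
  names(full) <- names
  counts <- data.frame(
    category = c("shared", paste0("unique_", names)),
    n_edges = c(length(shared_keys), length(u1), length(u2)),
    n_nodes = c(igraph::vcount(shared_g), igraph::vcount(uniq[[1]]),
                igraph::vcount(uniq[[2]])),
    stringsAsFactors = FALSE)
  structure(list(full = full, shared = shared_g, unique = uniq,
                 counts = counts),
            class = "diff_network")
}

# canonical per-edge keys "a<US>b" with a < b lexicographically
.edge_set <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  em <- igraph::as_edgelist(g)
  a <- pmin(em[, 1], em[, 2]); b <- pmax(em[, 1], em[, 2])
  unique(paste(a, b, sep = "\u001f"))
}

#' Degree centrality
#'
#' Number of edges incident to each node of a simple undirected graph.
#'
#' @param g igraph object.
#' @return named integer vector.
#' @export
node_degree <- function(g) {
  igraph::degree(g, loops = FALSE)
}

#' Betweenness centrality
#'
#' For each node v, the sum over pairs of other nodes (s, t) of the fraction
#' of shortest s-t paths passing through v. Unnormalized, unweighted,
#' endpoints excluded; disconnected pairs contribute zero.
#'
#' @param g igraph object (simple, undirected, unweighted).
#' @return named numeric vector.
#' @export
node_betweenness <- function(g) {
  igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
}

#' Consensus Louvain community detection
#'
#' Runs Louvain modularity optimization `runs` times under distinct
#' sub-seeds, canonicalizes each partition as a label-free set of node sets
#' and reports the most frequent partition; ties are broken by higher
#' modularity, then by canonical ordering. Communities with three or more
#' members are labeled alphabetically, ordered by decreasing size and then
#' by their lexicographically smallest member.
#'
#' @param g igraph object.
#' @param runs number of independent runs (default 20).
#' @param seed base RNG seed; run r uses `seed + r`.
#' @return an object of class `community_partition`: list with `membership`
#'   (named community-id vector), `communities` (list of member vectors),
#'   `labels` (letters for communities of size >= 3, NA otherwise),
#'   `modularity`, `run_frequency` (runs that produced the reported
#'   partition) and `runs`.
#' @export
louvain_consensus <- function(g, runs = 20, seed = 1L) {
  stopifnot(runs >= 1)
  if (igraph::vcount(g) == 0) {
    return(structure(list(membership = integer(0), communities = list(),
                          labels = character(0), modularity = NA_real_,
                          run_frequency = runs, runs = runs),
                     class = "community_partition"))
  }
  results <- vector("list", runs)
  sigs <- character(runs)
  mods <- numeric(runs)
  for (r in seq_len(runs)) {
    set.seed(seed + r)
    cl <- igraph::cluster_louvain(g)
    comm <- .canonical_partition(igraph::membership(cl))
    results[[r]] <- comm
    sigs[r] <- paste(vapply(comm, paste, "", collapse = ","), collapse = ";")
    mods[r] <- igraph::modularity(cl)
  }
  freq <- table(sigs)
  best_n <- max(freq)
  cand <- names(freq)[freq == best_n]
  if (length(cand) > 1) {
    best_mod <- vapply(cand, function(s) max(mods[sigs == s]), numeric(1))
    cand <- cand[best_mod == max(best_mod)]
    cand <- sort(cand)[1]
  }
  pick <- which(sigs == cand)[1]
  comm <- results[[pick]]
  sizes <- lengths(comm)
  ord <- order(-sizes, vapply(comm, `[`, "", 1))
  comm <- comm[ord]
  labels <- rep(NA_character_, length(comm))
  big <- lengths(comm) >= 3
  labels[big] <- LETTERS[seq_len(sum(big))]
  membership <- integer(0)
  for (i in seq_along(comm))
    membership[comm[[i]]] <- i
  structure(list(membership = membership, communities = comm,
                 labels = labels, modularity = mods[pick],
                 run_frequency = as.integer(best_n), runs = runs),
            class = "community_partition")
}

# sorted list of sorted member vectors; identity is label-free
.canonical_partition <- function(membership) {
  comm <- split(names(membership), membership)
  comm <- lapply(comm, sort)
  comm[order(vapply(comm, `[`, "", 1))]
}

#' Join protein-class annotations onto network nodes
#'
#' Left join of a protein-class table (e.g. a local PANTHER protein-class
#' export) onto node identifiers, with per-class counts and a rollup flag
#' for extracellular-matrix-related classes.
#'
#' @param nodes character vector of node identifiers (gene symbols or
#'   UniProt accessions).
#' @param class_table data frame with columns `id` and `class`; keys must be
#'   unique.
#' @param ecm_classes classes counted in the ECM rollup.
#' @return list with `table` (node, class, is_ecm; class NA when unmapped)
#'   and `class_counts`.
#' @export
annotate_nodes <- function(nodes, class_table,
                           ecm_classes = c(
                             "extracellular matrix structural protein",
                             "extracellular matrix protein",
                             "extracellular matrix glycoprotein")) {
  stopifnot(all(c("id", "class") %in% names(class_table)))
  if (anyDuplicated(class_table$id))
    stop("duplicate keys in class_table: ",
         paste(unique(class_table$id[duplicated(class_table$id)]),
               collapse = ", "))
  cls <- class_table$class[match(nodes, class_table$id)]
  tab <- data.frame(node = nodes, class = cls,
                    is_ecm = !is.na(cls) & tolower(cls) %in%
                      tolower(ecm_classes),
                    stringsAsFactors = FALSE)
  counts <- table(tab$class, useNA = "no")
  list(table = tab,
       class_counts = as.data.frame(counts, stringsAsFactors = FALSE))
}

#' Per-node centrality table for one group view
#'
#' Mirrors the reporting layout of the differential-network result tables:
#' community label, node, protein class, degree, betweenness, log2 fold
#' change with CI.
#'
#' @param g igraph object (e.g. a unique-edge subgraph).
#' @param partition optional `community_partition` on `g`.
#' @param contrasts optional contrast table; matched on `gene` (or `seq_id`
#'   when gene is absent) for the given `contrast`.
#' @param class_table optional protein-class table (see [annotate_nodes()]).
#' @param contrast contrast label to pull fold changes from.
#' @return data frame sorted by decreasing betweenness.
#' @export
centrality_table <- function(g, partition = NULL, contrasts = NULL,
                             class_table = NULL,
                             contrast = "mild-healthy") {
  nodes <- igraph::V(g)$name
  out <- data.frame(node = nodes,
                    degree = as.integer(node_degree(g)[nodes]),
                    betweenness = node_betweenness(g)[nodes],
                    stringsAsFactors = FALSE)
  out$community <- NA_character_
  if (!is.null(partition)) {
    ids <- partition$membership[nodes]
    out$community <- partition$labels[ids]
  }
  out$class <- NA_character_
  if (!is.null(class_table))
    out$class <- annotate_nodes(nodes, class_table)$table$class
  out$log2fc <- out$ci_low <- out$ci_high <- NA_real_
  if (!is.null(contrasts)) {
    ct <- contrasts[contrasts$contrast == contrast, ]
    key <- if (!is.null(ct$gene) && any(nodes %in% ct$gene)) ct$gene else
      ct$seq_id
    i <- match(nodes, key)
    out$log2fc <- ct$log2fc[i]
    out$ci_low <- ct$ci_low[i]
    out$ci_high <- ct$ci_high[i]
  }
  out <- out[order(-out$betweenness, out$node),
             c("community", "node", "class", "degree", "betweenness",
               "log2fc", "ci_low", "ci_high")]
  rownames(out) <- NULL
  out
}
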