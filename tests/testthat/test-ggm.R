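std_data <- function(p, n, precision_list, seed) {
  set.seed(seed)
  Xs <- lapply(precision_list, function(P) {
    S <- chol2inv(chol(P))
    X <- matrix(rnorm(n * p), n, p) %*% chol(S)
    colnames(X) <- sprintf("v%02d", seq_len(p))
    X
  })
  standardize_groups(Xs)
}

chain_precision <- function(p, rho = 0.45) {
  P <- diag(p)
  for (i in seq_len(p - 1)) P[i, i + 1] <- P[i + 1, i] <- -rho
  P
}

test_that("standardize_groups centers and scales, and validates", {
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  Y <- matrix(rnorm(30, 5, 2), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  Zs <- standardize_groups(list(g1 = X, g2 = Y))
  for (Z in Zs) {
    expect_equal(unname(colMeans(Z)), rep(0, 3), tolerance = 1e-12)
    expect_equal(unname(apply(Z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  }
  Y2 <- Y; colnames(Y2) <- c("a", "b", "d")
  expect_error(standardize_groups(list(X, Y2)), "identical variable set")
  X2 <- X; X2[, 2] <- 1
  expect_error(standardize_groups(list(X2)), "zero-variance")
})

test_that("coefficients vanish under a large penalty and stay symmetric", {
  Xs <- std_data(6, 40, list(g1 = chain_precision(6), g2 = chain_precision(6)),
                 seed = 1)
  fit <- fit_jewel(Xs, lambda1 = 5, lambda2 = 5)
  expect_true(all(fit$Omega == 0))
  for (k in 1:2) {
    expect_true(all(fit$Gamma[[k]] == 0))
    expect_true(all(!fit$adjacency[[k]]))
  }
  fit2 <- fit_jewel(Xs, lambda1 = 0.3, lambda2 = 0.2)
  for (k in 1:2) {
    A <- fit2$adjacency[[k]]
    expect_true(isSymmetric(A))
    expect_true(all(!diag(A)))
    expect_equal(unname(diag(fit2$Theta[[k]])), rep(0, 6))
  }
})

test_that("a chain graph is recovered exactly at moderate penalty", {
  P <- chain_precision(3, 0.5)
  Xs <- std_data(3, 400, list(g1 = P, g2 = P), seed = 2)
  fit <- fit_jewel(Xs, lambda1 = 0.1, lambda2 = 0.05)
  want <- matrix(c(FALSE, TRUE, FALSE,
                   TRUE, FALSE, TRUE,
                   FALSE, TRUE, FALSE), 3, 3,
                 dimnames = list(colnames(Xs[[1]]), colnames(Xs[[1]])))
  for (k in 1:2) expect_equal(fit$adjacency[[k]], want)
})

test_that("the objective trace is monotone non-increasing", {
  Xs <- std_data(8, 60, list(g1 = chain_precision(8),
                             g2 = chain_precision(8)), seed = 3)
  fit <- fit_jewel(Xs, lambda1 = 0.1, lambda2 = 0.05, trace = TRUE,
                   max_iter = 5000)
  expect_gte(length(fit$objective), 2)
  expect_true(all(diff(fit$objective) <= 1e-10))
  expect_true(fit$converged)
})

test_that("jewel_bic matches its formula computed by hand", {
  Xs <- std_data(5, 50, list(g1 = chain_precision(5),
                             g2 = chain_precision(5)), seed = 4)
  fit <- fit_jewel(Xs, lambda1 = 0.2, lambda2 = 0.1)
  by_hand <- 0
  for (k in 1:2) {
    n_k <- nrow(Xs[[k]])
    resid <- Xs[[k]] - Xs[[k]] %*% fit$Theta[[k]]
    rss <- colSums(resid^2)
    expect_equal(unname(fit$rss[[k]]), unname(rss), tolerance = 1e-8)
    e_k <- sum(fit$adjacency[[k]][upper.tri(fit$adjacency[[k]])])
    by_hand <- by_hand + sum(n_k * log(rss / n_k)) + log(n_k) * 2 * e_k
  }
  expect_equal(jewel_bic(fit), by_hand, tolerance = 1e-8)
})

test_that("bic_select returns a grid point with the path attached", {
  P <- chain_precision(5, 0.5)
  Xs <- std_data(5, 150, list(g1 = P, g2 = P), seed = 5)
  sel <- bic_select(Xs, grid1 = c(0.1, 0.3, 0.6), grid2 = c(0.05, 0.2),
                    lambda2_fixed = 0.2, max_iter = 3000)
  expect_true(sel$lambda1 %in% c(0.1, 0.3, 0.6))
  expect_true(sel$lambda2 %in% c(0.05, 0.2))
  expect_true(all(c("stage", "lambda1", "lambda2", "bic",
                    "edges_g1", "edges_g2") %in% names(sel$path)))
  p1 <- sel$path[sel$path$stage == 1, ]
  expect_equal(sel$lambda1, p1$lambda1[which.min(p1$bic)])
  # the chosen pair has minimal stage-2 BIC
  p2 <- sel$path[sel$path$stage == 2, ]
  expect_equal(sel$lambda2, p2$lambda2[which.min(p2$bic)])
})

test_that("stability selection with full subsets reproduces the single fit", {
  P <- chain_precision(4, 0.5)
  Xs <- std_data(4, 100, list(g1 = P, g2 = P), seed = 6)
  fit <- fit_jewel(Xs, lambda1 = 0.15, lambda2 = 0.1)
  st <- stability_selection(Xs, lambda1 = 0.15, lambda2 = 0.1, B = 3,
                            subset_fraction = 1, seed = 1)
  for (k in 1:2) {
    expect_equal(st$adjacency[[k]], fit$adjacency[[k]])
    offdiag <- upper.tri(st$cooccurrence)
    expect_true(all(st$cooccurrence[offdiag] == 3))
    f <- st$frequency[[k]][offdiag]
    expect_true(all(f %in% c(0, 1)))
  }
  expect_equal(st$n_never_cooccurred, 0)
})

test_that("stability frequencies are valid and subsets are honored", {
  P <- chain_precision(6, 0.5)
  Xs <- std_data(6, 80, list(g1 = P, g2 = P), seed = 7)
  st <- stability_selection(Xs, lambda1 = 0.2, lambda2 = 0.1, B = 20,
                            subset_fraction = 0.5, seed = 3)
  # ceiling(0.5 * 6) = 3 variables per resample
  expect_true(all(st$cooccurrence <= 20))
  f <- st$frequency[[1]][upper.tri(st$frequency[[1]])]
  expect_true(all(is.na(f) | (f >= 0 & f <= 1)))
  # retained nodes are exactly those with a retained edge somewhere
  got <- st$nodes
  want <- colnames(Xs[[1]])[Reduce(`|`, lapply(st$adjacency, function(A)
    rowSums(A) > 0))]
  expect_equal(got, want)
})

test_that("select_features ranks by absolute fold change with tie-breaks", {
  ct <- data.frame(
    seq_id = c("a1", "a2", "a3", "a4", "a5"),
    uniprot = c("P1", "P2", "P2", "P3", "P4"),
    contrast = "mild-healthy",
    log2fc = c(2, -3, 1, -1, NA),
    se = c(0.1, 0.2, 0.3, 0.2, 0.1),
    stringsAsFactors = FALSE)
  class(ct) <- c("sfggm_contrasts", "data.frame")
  sel <- select_features(ct, n_aptamers = 3)
  expect_equal(as.character(sel)[1:2], c("a2", "a1"))
  # |1| tie between a3 and a4: smaller se wins
  expect_equal(as.character(sel)[3], "a4")
  expect_equal(attr(sel, "n_proteins"), 3)
  expect_warning(sel_all <- select_features(ct, n_aptamers = 10), "only 4")
  expect_equal(length(sel_all), 4)
  expect_error(select_features(ct, contrast = "none"), "no rows")
})

test_that("graphs_from_estimate and write_graphs export consistent edges", {
  P <- chain_precision(4, 0.5)
  Xs <- std_data(4, 150, list(healthy = P, mild = P), seed = 8)
  st <- stability_selection(Xs, lambda1 = 0.1, lambda2 = 0.05, B = 10,
                            subset_fraction = 1, seed = 2)
  gs <- graphs_from_estimate(st)
  expect_named(gs, c("healthy", "mild"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile()
  el <- write_graphs(st, tsv_path = tsv, graphml_prefix = gp)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(back$node_a, el$node_a)
  expect_equal(nrow(el[el$group == "healthy", ]),
               igraph::ecount(gs$healthy))
  expect_true(all(el$frequency >= st$pi_thr))
  expect_true(file.exists(paste0(gp, "_healthy.graphml")))
})

test_that("collapse_to_proteins merges same-protein aptamers", {
  g <- igraph::graph_from_edgelist(
    rbind(c("a1", "a2"), c("a2", "a3"), c("a1", "a3")), directed = FALSE)
  ann <- data.frame(seq_id = c("a1", "a2", "a3"),
                    uniprot_ids = c("P1", "P1", "P2"),
                    gene_symbol = c("G1", "G1", "G2"),
                    stringsAsFactors = FALSE)
  out <- collapse_to_proteins(list(g = g), ann)$g
  expect_setequal(igraph::V(out)$name, c("G1", "G2"))
  # the a1-a2 edge collapses to a dropped self-loop; one G1-G2 edge remains
  expect_equal(igraph::ecount(out), 1)
  expect_true(igraph::are_adjacent(out, "G1", "G2"))
})
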