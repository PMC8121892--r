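test_that("Canberra distance matches the naive double loop and its hand cases", {
  x <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_equal(canberra_matrix(x)["a", "b"], 2)   # 1/1 + 1/1
  expect_equal(canberra_matrix(x)["a", "a"], 0)
  set.seed(14)
  X <- matrix(rpois(60, 4), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  expect_equal(canberra_matrix(X), naive_canberra(X), tolerance = 1e-14)
  # zero-zero taxa contribute nothing: appending an all-zero column is a no-op
  X0 <- cbind(X, zz = 0)
  expect_equal(canberra_matrix(X0), canberra_matrix(X))
})

test_that("ward.D2 merge heights equal a naive re-scan agglomeration", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(8:20, 1)
    pts <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(pts))
    tree <- hclust_ward2(d)
    expect_equal(sort(tree$height), naive_ward2_heights(d),
                 tolerance = 1e-10)
    expect_equal(max(cutree(tree, n)), n)     # n singletons
    expect_equal(max(cutree(tree, 1)), 1)     # one group
    expect_true(all(diff(tree$height) >= -1e-10))
  }
  expect_error(hclust_ward2(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(hclust_ward2(matrix(c(0, -1, -1, 0), 2)), "negative")
})

test_that("all four methods recover two well-separated blobs", {
  X <- blob_matrix(n_per = 5, sep = 100, seed = 2)
  truth <- rep(1:2, each = 5)
  for (method in c("hierarchical", "kmeans", "pam", "diana")) {
    cl <- cluster_sites(X, method, k = 2, distance = "euclidean", seed = 1)
    expect_equal(adjusted_rand_index(cl$labels, truth), 1)
  }
  tree <- hclust_ward2(as.matrix(dist(X)))
  # the first merges happen inside the blobs, far below the final join
  expect_lt(tree$height[1], tree$height[length(tree$height)] / 10)
  expect_error(cluster_sites(X, "pam", k = 1), "k must be")
  expect_error(cluster_sites(X, "pam", k = 10), "k must be")
})

test_that("PAM attains the exhaustive-search optimum on small instances", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(6:8, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    cl <- cluster_sites(matrix(0, n, 2,
                               dimnames = list(paste0("s", 1:n), NULL)),
                        "pam", k = 2, d = d)
    expect_equal(cl$objective / n, naive_pam_best(d, 2) / n,
                 tolerance = 1e-10)
  }
})

test_that("a converged k-means solution is a Lloyd fixed point", {
  set.seed(3)
  X <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 6), 10))
  rownames(X) <- paste0("s", 1:20)
  cl <- cluster_sites(X, "kmeans", k = 2, seed = 7)
  centres <- rowsum(X, cl$labels) / as.vector(table(cl$labels))
  reassigned <- apply(X, 1, function(r)
    which.min(colSums((t(centres) - r)^2)))
  expect_equal(unname(reassigned), unname(cl$labels))
})

test_that("internal measures equal their naive references on random labelings", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(8:12, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    L <- 4
    got <- internal_measures(d, labels, L)
    expect_equal(got[["connectivity"]], naive_connectivity(d, labels, L),
                 tolerance = 1e-12)
    expect_equal(got[["dunn"]], naive_dunn(d, labels), tolerance = 1e-12)
    expect_equal(got[["silhouette"]], naive_silhouette(d, labels),
                 tolerance = 1e-12)
    expect_gte(got[["silhouette"]], -1)
    expect_lte(got[["silhouette"]], 1)
  }
  d <- as.matrix(dist(blob_matrix(4, sep = 1000, seed = 1)))
  sep <- internal_measures(d, rep(1:2, each = 4), L = 3)
  expect_equal(sep[["connectivity"]], 0)
  expect_gt(sep[["silhouette"]], 0.99)
  expect_error(internal_measures(d, rep(1, 8), L = 3), "single cluster")
})

test_that("stability measures equal an independent reference on a toy matrix", {
  set.seed(10)
  X <- matrix(rpois(24, 8), 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:4)))
  got <- stability_measures(X, "hierarchical", k = 2)
  # rebuild the leave-one-column-out labelings exactly as specified
  d_full <- naive_canberra(X)
  labels0 <- cutree(hclust_ward2(d_full), 2)
  red <- sapply(1:4, function(l)
    cutree(hclust_ward2(naive_canberra(X[, -l, drop = FALSE])), 2))
  ref <- naive_stability(X, d_full, labels0, red, k = 2)
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("deleting a duplicated column cannot change a redundant clustering (APN = 0)", {
  # cluster signal present in every column: dropping one copy leaves the
  # partition untouched, so the non-overlap measure must be exactly zero
  set.seed(11)
  base <- rbind(matrix(rpois(12, 3), 4, 3), matrix(rpois(12, 60), 4, 3))
  X <- cbind(base, base)
  dimnames(X) <- list(paste0("s", 1:8), paste0("t", 1:6))
  st <- stability_measures(X, "hierarchical", k = 2)
  expect_equal(st[["APN"]], 0, tolerance = 1e-12)
})

test_that("stability scores stay in range on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rpois(48, 5), 8, 6,
                dimnames = list(paste0("s", 1:8), paste0("t", 1:6)))
    st <- stability_measures(X, "pam", k = 2)
    expect_gte(st[["APN"]], 0); expect_lte(st[["APN"]], 1)
    expect_gte(st[["AD"]], 0)
    expect_gte(st[["ADM"]], 0)
    expect_gte(st[["FOM"]], 0)
  }
})

test_that("k-means stability barely moves when only the seed changes", {
  X <- blob_matrix(n_per = 8, sep = 50, seed = 4)
  colnames(X) <- paste0("t", 1:3)
  a <- stability_measures(X, "kmeans", k = 2, seed = 1)
  b <- stability_measures(X, "kmeans", k = 2, seed = 2)
  for (ms in c("AD", "ADM", "FOM"))
    expect_lt(abs(a[[ms]] - b[[ms]]), 0.1 * max(a[[ms]], 1e-12))
  expect_lt(abs(a[["APN"]] - b[["APN"]]), 0.1)
})

test_that("Hopkins statistic separates uniform from clustered data", {
  hs <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(runif(400), 200, 2)
    hopkins_statistic(X, seed = s)
  }, numeric(1))
  expect_gt(mean(hs), 0.45)
  expect_lt(mean(hs), 0.55)
  blobs <- blob_matrix(n_per = 20, sep = 200, seed = 6)
  expect_gt(hopkins_statistic(blobs, seed = 1), 0.8)
  expect_true(all(hs > 0 & hs < 1))
  expect_error(hopkins_statistic(matrix(1, 6, 2)), "degenerate")
})

test_that("the validation grid has the right shape, optima and determinism", {
  set.seed(20)
  X <- blob_matrix(n_per = 6, sep = 40, seed = 20) + 20
  colnames(X) <- paste0("t", 1:3)
  vg <- validate_grid(X, methods = c("hierarchical", "pam"),
                      k_range = 2:4, seed = 5)
  expect_equal(dim(vg$scores), c(7L, 2L, 3L))
  # every optimum is consistent with its measure's declared direction
  for (i in seq_len(nrow(vg$optima))) {
    row <- vg$optima[i, ]
    all_scores <- vg$scores[row$measure, , ]
    target <- if (row$direction == "min") min(all_scores, na.rm = TRUE)
              else max(all_scores, na.rm = TRUE)
    expect_equal(row$score, target)
  }
  vg2 <- validate_grid(X, methods = c("hierarchical", "pam"),
                       k_range = 2:4, seed = 5)
  expect_identical(vg$scores, vg2$scores)
  # planted two-blob structure: most measures choose k = 2
  expect_gte(sum(vg$optima$k == 2), 4)
})

test_that("cluster projection counts coherent adjacent pairs on the network", {
  net <- chain_network(5)
  labs <- setNames(rep(1L, 5), paste0("n", 1:5))
  pr <- project_clusters(labs, net)
  expect_equal(pr$n_adjacent_total, 4)
  expect_equal(sum(pr$coherence$n_adjacent_pairs), 4)
  alt <- setNames(rep(c(1L, 2L), length.out = 5), paste0("n", 1:5))
  expect_equal(sum(project_clusters(alt, net)$coherence$n_adjacent_pairs), 0)
  expect_error(project_clusters(labs[-1], net), "unlabeled")
  # junctions do not break adjacency
  y <- y_network()
  labs_y <- setNames(c(1L, 1L, 2L), c("A", "B", "O"))
  pry <- project_clusters(labs_y, y)
  expect_equal(pry$n_adjacent_total, 3)       # A-B, A-O, B-O all via J only
  expect_equal(sum(pry$coherence$n_adjacent_pairs), 1)
})

test_that("adjusted Rand index matches mclust and behaves at the extremes", {
  a <- rep(1:3, each = 4)
  expect_equal(adjusted_rand_index(a, a), 1)
  skip_if_not_installed("mclust")
  for (seed in 1:10) {
    set.seed(seed)
    x <- sample(1:3, 20, replace = TRUE)
    y <- sample(1:4, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("dendrograms export as readable Newick trees", {
  d <- as.matrix(dist(blob_matrix(3, sep = 10, seed = 9)))
  tree <- hclust_ward2(d)
  p <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(tree, p)
  ph <- ape::read.tree(p)
  expect_equal(sort(ph$tip.label), sort(tree$labels))
})
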