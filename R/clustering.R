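#' Canberra distance matrix between sites
#'
#' d(x, y) = sum over taxa with x_j + y_j > 0 of |x_j - y_j| / (x_j + y_j).
#' Taxa absent from both sites contribute 0 and are simply excluded from the
#' sum — no rescaling by the number of contributing terms is applied (a
#' dialect difference from [stats::dist()], which scales the sum up
#' proportionally to the columns used). Canberra weighs proportional
#' differences, so rare taxa with modest read counts influence the distance
#' as much as dominant ones.
#'
#' @param m A count-mode [community_matrix()] or a non-negative matrix.
#' @return Symmetric site x site distance matrix with zero diagonal.
#' @export
canberra_matrix <- function(m) {
  X <- if (inherits(m, "community_matrix")) m$values else as.matrix(m)
  if (any(X < 0)) stop("Canberra distance requires non-negative values",
                       call. = FALSE)
  canberra_terms(X)$total
}

# Per-column decomposition of the Canberra sum. `contrib[, , j]` holds
# column j's term for every site pair, so leave-one-column-out distances
# (needed by the stability measures) are a single subtraction.
canberra_terms <- function(X) {
  n <- nrow(X); p <- ncol(X)
  contrib <- array(0, dim = c(n, n, p))
  total <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (j in seq_len(p)) {
    v <- X[, j]
    s <- outer(v, v, "+")
    term <- abs(outer(v, v, "-"))
    term[s > 0] <- term[s > 0] / s[s > 0]
    term[s == 0] <- 0
    contrib[, , j] <- term
    total <- total + term
  }
  list(total = total, contrib = contrib)
}

#' Hierarchical clustering with Ward's criterion on squared dissimilarities
#'
#' Agglomerative clustering via the Lance-Williams ward.D2 update (merge
#' heights on the original dissimilarity scale). Cut the returned tree with
#' [stats::cutree()].
#'
#' @param d Symmetric distance matrix (or `dist`) with zero diagonal.
#' @return An [stats::hclust] object.
#' @export
hclust_ward2 <- function(d) {
  dm <- check_square_sym(as.matrix(d), "d")
  if (any(dm < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (nrow(dm) < 2) stop("need at least 2 sites", call. = FALSE)
  stats::hclust(stats::as.dist(dm), method = "ward.D2")
}

#' Cluster sites with one of the compared algorithms
#'
#' Runs one clustering method on a site x taxon count matrix:
#' `"hierarchical"` (Ward on squared dissimilarities, cut at k),
#' `"kmeans"` (Lloyd iterations, best of `nstart` seeded starts on the raw
#' rows), `"pam"` (partitioning around medoids, BUILD + SWAP on the distance
#' matrix) and `"diana"` (Macnaughton-Smith divisive analysis on the
#' distance matrix). Distance-based methods use the Canberra distance by
#' default, matching the hierarchical clustering of read-count profiles.
#'
#' @param x A count-mode [community_matrix()] or numeric matrix.
#' @param method One of `"hierarchical"`, `"kmeans"`, `"pam"`, `"diana"`.
#' @param k Number of clusters, in \[2, n-1\].
#' @param distance `"canberra"` (default) or `"euclidean"` for the
#'   distance-based methods; k-means always operates on the raw rows.
#' @param seed Seed for the k-means starts (ignored by the deterministic
#'   methods).
#' @param nstart,iter_max k-means control.
#' @param d Optional precomputed distance matrix (overrides `distance`).
#' @return Object of class `cluster_result`: list with `method`, `k`,
#'   `labels` (named integer vector in 1..k), `tree` (hclust or NULL) and
#'   `objective` (k-means within-SS / PAM total dissimilarity, else NA).
#' @export
cluster_sites <- function(x, method = c("hierarchical", "kmeans", "pam", "diana"),
                          k, distance = c("canberra", "euclidean"),
                          seed = 1, nstart = 25, iter_max = 100, d = NULL) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  X <- if (inherits(x, "community_matrix")) x$values else as.matrix(x)
  n <- nrow(X)
  if (k < 2 || k > n - 1)
    stop(sprintf("k must be in [2, %d]", n - 1), call. = FALSE)
  if (method != "kmeans" && is.null(d)) {
    d <- if (distance == "canberra") canberra_matrix(X)
         else as.matrix(stats::dist(X))
  }
  tree <- NULL; objective <- NA_real_
  labels <- switch(method,
    hierarchical = {
      tree <- hclust_ward2(d)
      stats::cutree(tree, k)
    },
    diana = {
      di <- cluster::diana(stats::as.dist(as.matrix(d)), diss = TRUE)
      tree <- stats::as.hclust(di)
      stats::cutree(tree, k)
    },
    pam = {
      # BUILD + SWAP, plus a few seeded random medoid starts: SWAP is a
      # local search and can stick even on small instances
      dd <- stats::as.dist(as.matrix(d))
      fit <- cluster::pam(dd, k = k, do.swap = TRUE)
      starts <- with_seed(stage_seed(seed, 50L + k),
                          lapply(1:5, function(i) sample.int(n, k)))
      for (st in starts) {
        alt <- cluster::pam(dd, k = k, medoids = st, do.swap = TRUE)
        if (alt$objective["swap"] < fit$objective["swap"]) fit <- alt
      }
      objective <- unname(fit$objective["swap"]) * n  # total dissimilarity
      fit$clustering
    },
    kmeans = {
      fit <- with_seed(seed,
        stats::kmeans(X, centers = k, nstart = nstart,
                      iter.max = iter_max, algorithm = "Lloyd"))
      objective <- fit$tot.withinss
      fit$cluster
    })
  labels <- stats::setNames(as.integer(labels), rownames(X))
  structure(list(method = method, k = k, labels = labels, tree = tree,
                 objective = objective, distance = distance),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %s, k = %d (sizes: %s)\n", x$method, x$k,
              paste(table(x$labels), collapse = ", ")))
  invisible(x)
}

#' Internal cluster-validation measures
#'
#' Connectivity (degree to which nearest neighbours land in the same
#' cluster; minimise), Dunn index (minimum between-cluster distance over
#' maximum cluster diameter; maximise) and mean silhouette width (maximise).
#' Singleton clusters get silhouette 0 for their member.
#'
#' @param d Symmetric distance matrix.
#' @param labels Integer cluster labels (>= 2 clusters).
#' @param L Neighbourhood size for connectivity (default 10).
#' @return Named numeric vector `connectivity`, `dunn`, `silhouette`.
#' @export
internal_measures <- function(d, labels, L = 10) {
  d <- check_square_sym(as.matrix(d), "d")
  n <- nrow(d)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length must match d", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("internal measures undefined for a single cluster", call. = FALSE)
  if (L >= n) stop("neighbourhood L must be smaller than n", call. = FALSE)

  conn <- 0
  for (i in seq_len(n)) {
    nb <- order(d[i, -i])            # neighbours among the other points
    others <- seq_len(n)[-i]
    for (j in seq_len(L))
      if (labels[others[nb[j]]] != labels[i]) conn <- conn + 1 / j
  }

  same <- outer(labels, labels, "==")
  off <- !diag(n)
  inter <- d[!same]
  intra <- d[same & off]
  dunn <- if (length(intra) == 0 || max(intra) == 0) Inf
          else min(inter) / max(intra)

  sil <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))

  c(connectivity = conn, dunn = dunn, silhouette = mean(sil))
}

# APN / AD / ADM / FOM given the full-data labels and an n x p matrix of
# leave-one-column-out labels (NA column = clustering failed, skipped).
stability_from_labels <- function(X, d_full, labels0, red_labels, k) {
  n <- nrow(X); p <- ncol(X)
  size0 <- table(labels0)
  cols <- which(!apply(is.na(red_labels), 2, any))
  apn_i <- ad_i <- adm_i <- numeric(0)
  fom <- numeric(0)
  cent0 <- rowsum(X, labels0) / as.vector(size0)   # full-data centroids
  for (l in cols) {
    ll <- red_labels[, l]
    tab <- table(factor(labels0, levels = sort(unique(labels0))),
                 factor(ll, levels = sort(unique(ll))))
    # overlap of i's two co-cluster sets, via the contingency table
    inter <- tab[cbind(match(labels0, rownames(tab)),
                       match(ll, colnames(tab)))]
    apn_i <- c(apn_i, 1 - inter / as.vector(size0[as.character(labels0)]))
    # mean full-data distance between members of the two clusters
    grp_mean <- function(r, s)
      mean(d_full[labels0 == r, ll == s, drop = FALSE])
    Mpairs <- outer(as.integer(rownames(tab)), as.integer(colnames(tab)),
                    Vectorize(grp_mean))
    ad_i <- c(ad_i, Mpairs[cbind(match(labels0, rownames(tab)),
                                 match(ll, colnames(tab)))])
    centl <- rowsum(X, ll) / as.vector(table(ll))
    dcent <- sqrt(rowSums((centl[match(ll, sort(unique(ll))), , drop = FALSE] -
                           cent0[match(labels0, sort(unique(labels0))), ,
                                 drop = FALSE])^2))
    adm_i <- c(adm_i, dcent)
    # figure of merit: predictive power for the held-out column
    mu <- stats::ave(X[, l], ll)
    fom <- c(fom, sqrt(mean((X[, l] - mu)^2)) * sqrt(n / (n - k)))
  }
  c(APN = mean(apn_i), AD = mean(ad_i), ADM = mean(adm_i), FOM = mean(fom))
}

#' Stability cluster-validation measures
#'
#' Robustness of a clustering to deleting one taxon (column) at a time:
#' average proportion of non-overlap (APN), average distance (AD), average
#' distance between means (ADM) and figure of merit (FOM). All four are
#' minimised. Reclustering reuses the full run's method, k and seed so the
#' only perturbation is the column deletion.
#'
#' @inheritParams cluster_sites
#' @return Named numeric vector `APN`, `AD`, `ADM`, `FOM`.
#' @export
stability_measures <- function(x, method, k, distance = "canberra",
                               seed = 1, nstart = 25) {
  X <- if (inherits(x, "community_matrix")) x$values else as.matrix(x)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 taxa", call. = FALSE)
  ct <- canberra_terms(X)
  full <- cluster_sites(X, method, k, distance = distance, seed = seed,
                        nstart = nstart,
                        d = if (method != "kmeans") ct$total else NULL)
  red <- matrix(NA_integer_, nrow(X), p)
  for (l in seq_len(p)) {
    labs <- tryCatch({
      if (method == "kmeans") {
        cluster_sites(X[, -l, drop = FALSE], "kmeans", k, seed = seed,
                      nstart = nstart)$labels
      } else {
        d_red <- ct$total - ct$contrib[, , l]
        cluster_sites(X, method, k, seed = seed, d = d_red)$labels
      }
    }, error = function(e) {
      warning(sprintf("clustering failed with column %d deleted: %s",
                      l, conditionMessage(e)))
      NULL
    })
    if (!is.null(labs)) red[, l] <- labs
  }
  stability_from_labels(X, ct$total, full$labels, red, k)
}

#' Hopkins clustering-tendency statistic
#'
#' Compares nearest-neighbour distances of m sampled data rows with those of
#' m uniform pseudo-points drawn in the data's per-column bounding box:
#' H = sum(u) / (sum(u) + sum(w)), where u are pseudo-point-to-data and w are
#' data-to-other-data nearest-neighbour distances (Euclidean). H near 0.5
#' indicates spatial randomness; values toward 1 indicate clustered data.
#'
#' @param x Numeric matrix (rows = sites) or count [community_matrix()].
#' @param m Number of sampled rows / pseudo-points;
#'   default `max(2, floor(0.1 * n))`.
#' @param seed Integer seed.
#' @return A single numeric in (0, 1).
#' @export
hopkins_statistic <- function(x, m = NULL, seed = 1) {
  X <- if (inherits(x, "community_matrix")) x$values else as.matrix(x)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 rows", call. = FALSE)
  if (all(apply(X, 2, function(v) length(unique(v)) == 1)))
    stop("degenerate data: all rows identical", call. = FALSE)
  if (is.null(m)) m <- max(2, floor(0.1 * n))
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  with_seed(seed, {
    idx <- sample.int(n, m)
    U <- matrix(stats::runif(m * ncol(X), rep(lo, each = m),
                             rep(hi, each = m)), nrow = m)
    u <- vapply(seq_len(m), function(i)
      sqrt(min(colSums((t(X) - U[i, ])^2))), numeric(1))
    w <- vapply(idx, function(i)
      sqrt(min(colSums((t(X[-i, , drop = FALSE]) - X[i, ])^2))), numeric(1))
    sum(u) / (sum(u) + sum(w))
  })
}

validation_measures <- c("connectivity", "dunn", "silhouette",
                         "APN", "AD", "ADM", "FOM")
measure_direction <- c(connectivity = "min", dunn = "max", silhouette = "max",
                       APN = "min", AD = "min", ADM = "min", FOM = "min")

#' Cluster-validation grid over methods and cluster numbers
#'
#' Scores every (method, k) combination with the three internal measures
#' (computed on the configured distance) and the four stability measures
#' (leave-one-taxon-out reclustering), and reports each measure's optimal
#' method and k — the machinery behind choosing biogeographical units. Ties
#' are broken toward the smallest k, then the method order as supplied.
#'
#' @inheritParams cluster_sites
#' @param methods Methods to compare.
#' @param k_range Candidate cluster numbers (default 2:10).
#' @param measures Subset of
#'   `c("connectivity","dunn","silhouette","APN","AD","ADM","FOM")`.
#' @param L Connectivity neighbourhood size.
#' @return Object of class `cluster_validation`: list with `scores`
#'   (measure x method x k array), `optima` (data frame: measure, type,
#'   direction, method, k, score), `hopkins`, and the call parameters.
#' @export
validate_grid <- function(x, methods = c("hierarchical", "kmeans", "pam", "diana"),
                          k_range = 2:10, measures = validation_measures,
                          distance = "canberra", L = 10, seed = 1,
                          nstart = 25) {
  X <- if (inherits(x, "community_matrix")) x$values else as.matrix(x)
  n <- nrow(X)
  measures <- match.arg(measures, validation_measures, several.ok = TRUE)
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop(sprintf("k_range must lie within [2, %d]", n - 1), call. = FALSE)
  ct <- canberra_terms(X)
  d_int <- if (distance == "canberra") ct$total else as.matrix(stats::dist(X))
  scores <- array(NA_real_,
                  dim = c(length(measures), length(methods), length(k_range)),
                  dimnames = list(measures, methods, as.character(k_range)))
  internal_wanted <- intersect(measures, c("connectivity", "dunn", "silhouette"))
  stability_wanted <- intersect(measures, c("APN", "AD", "ADM", "FOM"))

  for (method in methods) {
    # full-data labels for every k (hierarchies: one tree, all cuts)
    full_labels <- matrix(NA_integer_, n, length(k_range))
    if (method %in% c("hierarchical", "diana")) {
      tree <- cluster_sites(X, method, k = 2, d = d_int)$tree
      for (ki in seq_along(k_range))
        full_labels[, ki] <- stats::cutree(tree, k_range[ki])
    } else {
      for (ki in seq_along(k_range))
        full_labels[, ki] <- cluster_sites(X, method, k_range[ki],
                                           seed = seed, nstart = nstart,
                                           d = if (method == "pam") d_int)$labels
    }
    for (ki in seq_along(k_range))
      if (length(internal_wanted))
        scores[internal_wanted, method, ki] <-
          internal_measures(d_int, full_labels[, ki], L)[internal_wanted]

    if (length(stability_wanted)) {
      # leave-one-column-out labels for every k
      red <- array(NA_integer_, dim = c(n, ncol(X), length(k_range)))
      for (l in seq_len(ncol(X))) {
        ok <- tryCatch({
          if (method %in% c("hierarchical", "diana")) {
            d_red <- ct$total - ct$contrib[, , l]
            tr <- cluster_sites(X, method, k = 2, d = d_red)$tree
            for (ki in seq_along(k_range))
              red[, l, ki] <- stats::cutree(tr, k_range[ki])
          } else if (method == "pam") {
            d_red <- ct$total - ct$contrib[, , l]
            for (ki in seq_along(k_range))
              red[, l, ki] <- cluster_sites(X, "pam", k_range[ki],
                                            d = d_red)$labels
          } else {
            Xl <- X[, -l, drop = FALSE]
            for (ki in seq_along(k_range))
              red[, l, ki] <- cluster_sites(Xl, "kmeans", k_range[ki],
                                            seed = seed,
                                            nstart = nstart)$labels
          }
          TRUE
        }, error = function(e) {
          warning(sprintf("%s failed with column %d deleted: %s",
                          method, l, conditionMessage(e)))
          FALSE
        })
        if (!ok) red[, l, ] <- NA_integer_
      }
      for (ki in seq_along(k_range)) {
        st <- stability_from_labels(X, ct$total, full_labels[, ki],
                                    red[, , ki], k_range[ki])
        scores[stability_wanted, method, ki] <- st[stability_wanted]
      }
    }
  }

  optima <- do.call(rbind, lapply(measures, function(ms) {
    dir <- measure_direction[[ms]]
    best <- if (dir == "min") Inf else -Inf
    bm <- NA_character_; bk <- NA_integer_
    for (ki in seq_along(k_range)) for (method in methods) {
      v <- scores[ms, method, ki]
      if (is.na(v)) next
      better <- if (dir == "min") v < best else v > best
      if (better) { best <- v; bm <- method; bk <- k_range[ki] }
    }
    data.frame(measure = ms,
               type = if (ms %in% c("connectivity", "dunn", "silhouette"))
                 "internal" else "stability",
               direction = dir, method = bm, k = bk, score = best)
  }))
  structure(list(scores = scores, optima = optima,
                 hopkins = hopkins_statistic(X, seed = stage_seed(seed, 99)),
                 methods = methods, k_range = k_range, distance = distance,
                 L = L, seed = seed),
            class = "cluster_validation")
}

#' @export
print.cluster_validation <- function(x, ...) {
  cat("Optimal cluster validation measures\n")
  cat(sprintf("  Hopkins clustering tendency: %.2f\n", x$hopkins))
  opt <- x$optima
  cat(sprintf("  %-10s %-13s %-13s %s\n", "Type", "Measure",
              "Optimal method", "Optimal k"))
  for (i in seq_len(nrow(opt)))
    cat(sprintf("  %-10s %-13s %-13s %d\n", opt$type[i], opt$measure[i],
                opt$method[i], opt$k[i]))
  invisible(x)
}

#' Project cluster labels onto the river network
#'
#' Produces the site-to-cluster table and a spatial-coherence summary: for
#' each cluster, how many network-adjacent site pairs (sites joined by a
#' channel path passing through no other site) fall in the same cluster.
#'
#' @param labels Named integer vector of cluster labels covering all
#'   network sites.
#' @param net A [river_network()].
#' @return Object of class `cluster_projection`: list with `table`
#'   (data frame site, cluster), `coherence` (data frame cluster,
#'   n_adjacent_pairs), `n_adjacent_total`.
#' @export
project_clusters <- function(labels, net) {
  stopifnot(inherits(net, "river_network"))
  sites <- net$site_ids
  missing <- setdiff(sites, names(labels))
  if (length(missing))
    stop(sprintf("unlabeled sites: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  labels <- labels[sites]
  # site adjacency: channel path between the two sites contains no third site
  adj <- matrix(FALSE, length(sites), length(sites),
                dimnames = list(sites, sites))
  for (i in seq_along(sites)) {
    paths <- igraph::shortest_paths(net$graph, from = sites[i], to = sites,
                                    weights = igraph::E(net$graph)$weight)
    for (j in seq_along(sites)) {
      if (j <= i) next
      mid <- setdiff(names(paths$vpath[[j]]), c(sites[i], sites[j]))
      adj[i, j] <- !any(mid %in% sites)
    }
  }
  pairs <- which(adj, arr.ind = TRUE)
  same <- labels[pairs[, 1]] == labels[pairs[, 2]]
  coh <- as.data.frame(table(factor(labels[pairs[same, 1]],
                                    levels = sort(unique(labels)))))
  names(coh) <- c("cluster", "n_adjacent_pairs")
  structure(list(table = data.frame(site = sites,
                                    cluster = as.integer(labels)),
                 coherence = coh,
                 n_adjacent_total = nrow(pairs)),
            class = "cluster_projection")
}

#' @export
print.cluster_projection <- function(x, ...) {
  cat(sprintf("cluster projection: %d sites, %d adjacent site pairs\n",
              nrow(x$table), x$n_adjacent_total))
  same <- sum(x$coherence$n_adjacent_pairs)
  cat(sprintf("  same-cluster adjacent pairs: %d (%.0f%%)\n", same,
              100 * same / max(1, x$n_adjacent_total)))
  invisible(x)
}

#' Write a dendrogram as a Newick tree
#'
#' Merge heights become branch lengths, so the tree can be inspected in any
#' phylogenetics viewer.
#'
#' @param tree An [stats::hclust] object (e.g. from [hclust_ward2()]).
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
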