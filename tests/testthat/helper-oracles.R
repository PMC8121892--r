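# Independent naive reference implementations used as oracles. These are
# deliberately written as direct transcriptions of the definitions (double
# loops, exhaustive enumeration) and share no code with the package.

naive_canberra <- function(X) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (m in seq_len(ncol(X))) {
      den <- X[i, m] + X[j, m]
      if (den > 0) s <- s + abs(X[i, m] - X[j, m]) / den
    }
    d[i, j] <- s
  }
  dimnames(d) <- list(rownames(X), rownames(X))
  d
}

# O(n^3) re-scan agglomeration under the ward.D2 Lance-Williams update;
# returns the sorted merge heights.
naive_ward2_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  repeat {
    if (length(active) == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bestd)
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- sqrt(
        ((size[i] + size[k]) * d[i, k]^2 +
         (size[j] + size[k]) * d[j, k]^2 -
         size[k] * d[i, j]^2) / (size[i] + size[j] + size[k]))
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

naive_connectivity <- function(d, labels, L) {
  n <- nrow(d)
  total <- 0
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nn <- others[order(d[i, others])]
    for (j in seq_len(L))
      if (labels[nn[j]] != labels[i]) total <- total + 1 / j
  }
  total
}

naive_dunn <- function(d, labels) {
  inter <- Inf; intra <- 0
  n <- nrow(d)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (labels[i] == labels[j]) intra <- max(intra, d[i, j])
    else inter <- min(inter, d[i, j])
  }
  inter / intra
}

naive_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == g]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

naive_pam_best <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    obj <- sum(apply(d[, med, drop = FALSE], 1, min))
    best <- min(best, obj)
  }
  best
}

# APN/AD/ADM/FOM from first principles given full-data labels and the
# leave-one-column-out label matrix.
naive_stability <- function(X, d, labels0, red_labels, k) {
  n <- nrow(X); p <- ncol(X)
  apn <- ad <- adm <- c()
  fom <- c()
  for (l in seq_len(p)) {
    ll <- red_labels[, l]
    for (i in seq_len(n)) {
      C0 <- which(labels0 == labels0[i])
      Cl <- which(ll == ll[i])
      apn <- c(apn, 1 - length(intersect(C0, Cl)) / length(C0))
      ad <- c(ad, mean(d[C0, Cl]))
      adm <- c(adm, sqrt(sum((colMeans(X[Cl, , drop = FALSE]) -
                              colMeans(X[C0, , drop = FALSE]))^2)))
    }
    sq <- 0
    for (i in seq_len(n))
      sq <- sq + (X[i, l] - mean(X[ll == ll[i], l]))^2
    fom <- c(fom, sqrt(sq / n) * sqrt(n / (n - k)))
  }
  c(APN = mean(apn), AD = mean(ad), ADM = mean(adm), FOM = mean(fom))
}

# Poisson log-linear fit by straight Newton-Raphson on the log-likelihood.
newton_poisson <- function(y, x, tol = 1e-12, maxit = 200) {
  beta <- c(log(mean(y) + 0.1), 0)
  X <- cbind(1, x)
  for (it in seq_len(maxit)) {
    mu <- exp(X %*% beta)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * as.vector(mu))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.vector(beta)
}

# exact Mantel p over all n! simultaneous row/column permutations of d2
exact_mantel_p <- function(d1, d2) {
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  r_obs <- cor(v1, d2[lt])
  perms <- gtools_permutations(n)
  r_all <- apply(perms, 1, function(p) cor(v1, d2[p, p][lt]))
  mean(r_all >= r_obs - 1e-12)
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

# mean cumulative richness over every ordering of the sites
exhaustive_accumulation <- function(pres) {
  n <- nrow(pres)
  perms <- gtools_permutations(n)
  acc <- matrix(0, nrow(perms), n)
  for (r in seq_len(nrow(perms))) {
    seen <- rep(FALSE, ncol(pres))
    for (k in seq_len(n)) {
      seen <- seen | pres[perms[r, k], ] > 0
      acc[r, k] <- sum(seen)
    }
  }
  colMeans(acc)
}

# shortest site-to-site distance by exhaustive DFS path enumeration over the
# raw edge list (no graph library)
bruteforce_distance <- function(edges, from, to) {
  best <- Inf
  walk <- function(node, visited, len) {
    if (node == to) { best <<- min(best, len); return() }
    hit <- which((edges$from == node & !(edges$to %in% visited)) |
                 (edges$to == node & !(edges$from %in% visited)))
    for (e in hit) {
      nxt <- if (edges$from[e] == node) edges$to[e] else edges$from[e]
      walk(nxt, c(visited, nxt), len + edges$length_km[e])
    }
  }
  walk(from, from, 0)
  best
}
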