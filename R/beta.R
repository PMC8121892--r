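#' Jaccard dissimilarity partitioned into turnover and nestedness
#'
#' For every pair of sites with a = shared taxa and b, c = taxa unique to
#' each site, computes the incidence-based Jaccard dissimilarity and its
#' additive partition into species replacement (turnover) and richness
#' difference (nestedness):
#' \deqn{\beta_{jac} = (b+c)/(a+b+c)}
#' \deqn{\beta_{jtu} = 2\min(b,c) / (a + 2\min(b,c))}
#' \deqn{\beta_{jne} = \beta_{jac} - \beta_{jtu}}
#' Pairs of two empty communities are defined as dissimilarity 0 (with a
#' warning), avoiding 0/0.
#'
#' @param m A presence-mode [community_matrix()] with at least 2 sites.
#' @return An object of class `beta_partition`: list of three symmetric
#'   site x site matrices `jaccard`, `turnover`, `nestedness`, all in
#'   \[0, 1\] with zero diagonals and `jaccard = turnover + nestedness`.
#' @export
jaccard_partition <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  if (m$mode != "presence")
    stop("jaccard_partition expects a presence matrix", call. = FALSE)
  x <- m$values
  if (nrow(x) < 2) stop("need at least 2 sites", call. = FALSE)
  a <- x %*% t(x)                       # shared taxa
  ri <- rowSums(x)
  b <- matrix(ri, nrow(x), nrow(x)) - a # unique to row site
  cc <- t(b)                            # unique to column site
  tot <- a + b + cc
  minbc <- pmin(b, cc)
  jac <- ifelse(tot > 0, (b + cc) / tot, 0)
  jtu <- ifelse(a + 2 * minbc > 0, 2 * minbc / (a + 2 * minbc), 0)
  if (any(tot == 0 & upper.tri(tot)))
    warning("site pairs with two empty communities set to dissimilarity 0")
  jne <- jac - jtu
  diag(jac) <- diag(jtu) <- diag(jne) <- 0
  dn <- list(rownames(x), rownames(x))
  dimnames(jac) <- dimnames(jtu) <- dimnames(jne) <- dn
  structure(list(jaccard = jac, turnover = jtu, nestedness = jne),
            class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, ...) {
  lt <- lower.tri(x$jaccard)
  cat(sprintf("beta_partition over %d sites\n", nrow(x$jaccard)))
  cat(sprintf("  mean Jaccard %.3f = turnover %.3f + nestedness %.3f\n",
              mean(x$jaccard[lt]), mean(x$turnover[lt]),
              mean(x$nestedness[lt])))
  invisible(x)
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance from
#' a permutation null built by simultaneously permuting rows and columns of
#' the second matrix. The p-value uses the +1 correction
#' p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm) (for `alternative =
#' "greater"`), so p is never exactly 0.
#'
#' @param d1,d2 Symmetric matrices (or `dist`) with zero diagonal, same size
#'   (n >= 4), in the same site order.
#' @param n_perm Number of permutations (default 999).
#' @param alternative `"greater"` (ecological default: dissimilarity rises
#'   with distance), `"less"`, or `"two.sided"`.
#' @param seed Integer seed for the permutations.
#' @return Object of class `mantel_result`: list with `statistic` (r),
#'   `p_value`, `n_perm`, `alternative`, `seed`, `n`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999,
                        alternative = c("greater", "less", "two.sided"),
                        seed = 1) {
  alternative <- match.arg(alternative)
  d1 <- check_square_sym(as.matrix(d1), "d1")
  d2 <- check_square_sym(as.matrix(d2), "d2")
  n <- nrow(d1)
  if (!all(dim(d1) == dim(d2))) stop("matrix sizes differ", call. = FALSE)
  if (n < 4) stop("need at least 4 sites", call. = FALSE)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (stats::sd(v1) == 0 || stats::sd(d2[lt]) == 0)
    stop("constant lower triangle: Mantel correlation undefined",
         call. = FALSE)
  r_obs <- stats::cor(v1, d2[lt])
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(v1, d2[p, p][lt])
    }, numeric(1))
  })
  p <- switch(alternative,
    greater   = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
    less      = (1 + sum(r_perm <= r_obs)) / (1 + n_perm),
    two.sided = (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm))
  structure(list(statistic = r_obs, p_value = p, n_perm = n_perm,
                 alternative = alternative, seed = seed, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (n = %d, %d permutations, %s)\n",
              x$n, x$n_perm, x$alternative))
  cat(sprintf("  r = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}
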