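#' Local taxon richness per site
#'
#' @param m A presence-mode [community_matrix()].
#' @return Named integer vector of per-site richness (row sums).
#' @export
local_richness <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  if (m$mode != "presence")
    stop("local_richness expects a presence/absence matrix; see to_presence_absence()",
         call. = FALSE)
  r <- rowSums(m$values)
  storage.mode(r) <- "integer"
  r
}

#' Poisson regression of richness on river distance
#'
#' Fits the distance-decay model log E(richness) = b0 + b1 * distance by
#' Poisson GLM (log link, iteratively reweighted least squares). The slope's
#' Wald z statistic tests whether richness changes systematically with
#' along-network distance from the outlet.
#'
#' @param richness Non-negative integer vector of per-site richness.
#' @param distance Numeric vector of distances (km), same length.
#' @return An object of class `richness_glm` with fields `intercept`,
#'   `slope`, `se` (length 2), `z` (length 2), `loglik`, `aic`, `deviance`,
#'   `n`, and the underlying `glm` fit.
#' @export
fit_richness_glm <- function(richness, distance) {
  if (length(richness) != length(distance))
    stop("richness and distance lengths differ", call. = FALSE)
  if (length(richness) < 3)
    stop("need at least 3 sites", call. = FALSE)
  if (any(richness < 0) || any(richness != round(richness)))
    stop("richness must be non-negative integers", call. = FALSE)
  df <- data.frame(richness = richness, distance = distance)
  fit <- stats::glm(richness ~ distance, family = stats::poisson(),
                    data = df,
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged)
    stop(sprintf("IRLS did not converge in 100 iterations (deviance %.4g)",
                 fit$deviance), call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
                 se = stats::setNames(co[, 2], c("intercept", "slope")),
                 z = stats::setNames(co[, 3], c("intercept", "slope")),
                 p = stats::setNames(co[, 4], c("intercept", "slope")),
                 loglik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit),
                 deviance = stats::deviance(fit),
                 n = length(richness),
                 fit = fit),
            class = "richness_glm")
}

#' @export
print.richness_glm <- function(x, ...) {
  cat("Poisson GLM: log E(richness) = b0 + b1 * distance\n")
  cat(sprintf("  b0 = %.4f (SE %.4f)\n", x$intercept, x$se["intercept"]))
  cat(sprintf("  b1 = %.6f per km (SE %.6f), z = %.3f, p = %.3g\n",
              x$slope, x$se["slope"], x$z["slope"], x$p["slope"]))
  cat(sprintf("  logLik = %.2f, AIC = %.2f, deviance = %.2f, n = %d\n",
              x$loglik, x$aic, x$deviance, x$n))
  invisible(x)
}

#' @export
coef.richness_glm <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.richness_glm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  stats::predict(object$fit, newdata = newdata, type = "response")
}

# Exact expected richness after k sites: S_obs - sum_i C(N-n_i, k) / C(N, k),
# with n_i the number of sites occupied by taxon i. Computed on log scale to
# stay stable for large N.
accum_exact_mean <- function(pres, k) {
  N <- nrow(pres)
  n_i <- colSums(pres > 0)
  n_i <- n_i[n_i > 0]
  vapply(k, function(kk) {
    lp <- lchoose(N - n_i, kk) - lchoose(N, kk)
    miss <- ifelse(N - n_i >= kk, exp(lp), 0)
    length(n_i) - sum(miss)
  }, numeric(1))
}

#' Species accumulation curve
#'
#' Expected taxon richness as a function of the number of sites sampled,
#' optionally per group of sites (e.g. per river). The exact method uses the
#' hypergeometric (sample-based rarefaction) formula; the permutation method
#' averages over random site orderings. The standard deviation always comes
#' from seeded permutations of the site order.
#'
#' @param m A presence-mode [community_matrix()].
#' @param groups Optional factor/character vector (one entry per site) to
#'   compute one curve per group; default a single curve for all sites.
#' @param method `"exact"` or `"permutation"` for the mean curve.
#' @param n_perm Number of random site orderings for the SD (and for the
#'   mean when `method = "permutation"`).
#' @param seed Integer seed for the permutations.
#' @return An object of class `accum_curve`: a data frame with columns
#'   `group`, `k`, `mean`, `sd`.
#' @export
accumulation_curve <- function(m, groups = NULL, method = c("exact", "permutation"),
                               n_perm = 1000, seed = 1) {
  stopifnot(inherits(m, "community_matrix"))
  if (m$mode != "presence")
    stop("accumulation_curve expects a presence matrix", call. = FALSE)
  method <- match.arg(method)
  pres <- m$values
  if (is.null(groups)) groups <- rep("all", nrow(pres))
  if (length(groups) != nrow(pres))
    stop("groups must have one entry per site", call. = FALSE)
  res <- list()
  for (g in unique(groups)) {
    sub <- pres[groups == g, , drop = FALSE]
    N <- nrow(sub)
    k <- seq_len(N)
    richness_along <- function(ord) {
      cum <- apply(sub[ord, , drop = FALSE], 2, cummax)
      if (N == 1) sum(cum) else rowSums(cum)
    }
    perms <- with_seed(stage_seed(seed, match(g, unique(groups))), {
      vapply(seq_len(n_perm), function(i) richness_along(sample.int(N)),
             numeric(N))
    })
    perms <- matrix(perms, nrow = N)
    mu <- if (method == "exact") accum_exact_mean(sub, k) else rowMeans(perms)
    sdv <- apply(perms, 1, stats::sd)
    res[[g]] <- data.frame(group = g, k = k, mean = mu, sd = sdv)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("accum_curve", "data.frame")
  out
}

#' @export
print.accum_curve <- function(x, ...) {
  cat("species accumulation curve\n")
  for (g in unique(x$group)) {
    sub <- x[x$group == g, ]
    cat(sprintf("  %s: %d sites, richness %.1f -> %.1f\n",
                g, max(sub$k), sub$mean[1], sub$mean[nrow(sub)]))
  }
  invisible(x)
}

#' PCA of site environmental variables
#'
#' Principal component analysis of per-site environmental measurements
#' (river width, pH, conductivity, dissolved solids, altitude, ...).
#' Variables are centred and scaled to unit variance (the correlation
#' matrix), since they mix units. Component signs are fixed by forcing each
#' loading vector's largest-magnitude entry positive.
#'
#' @param env Numeric site x variable matrix or data frame, no missing values.
#' @return An object of class `env_pca`: list with `scores` (sites x PCs),
#'   `loadings` (variables x PCs), `explained` (variance fractions, sums
#'   to 1), `sdev`.
#' @export
env_pca <- function(env) {
  env <- as.matrix(env)
  if (nrow(env) < 2 || ncol(env) < 2)
    stop("need at least 2 sites and 2 variables", call. = FALSE)
  if (any(is.na(env)))
    stop("environmental matrix has missing values", call. = FALSE)
  vars <- apply(env, 2, stats::var)
  if (any(vars == 0))
    stop(sprintf("zero-variance column: %s",
                 paste(colnames(env)[vars == 0], collapse = ", ")),
         call. = FALSE)
  z <- scale(env, center = TRUE, scale = TRUE)
  eg <- eigen(stats::cor(env), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  load <- eg$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(env), paste0("PC", seq_len(ncol(load))))
  scores <- z %*% load
  structure(list(scores = scores, loadings = load,
                 explained = ev / sum(ev), sdev = sqrt(ev)),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat("PCA of environmental variables (correlation matrix)\n")
  cat("  explained variance: ",
      paste(sprintf("%s %.1f%%", colnames(x$loadings),
                    100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}
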