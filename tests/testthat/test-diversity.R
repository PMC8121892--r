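test_that("local richness is the presence row sum", {
  m <- community_matrix(matrix(c(1, 0, 1, 1,
                                 0, 0, 0, 0), 2, byrow = TRUE,
                               dimnames = list(c("A", "B"),
                                               paste0("t", 1:4))),
                        "presence")
  expect_equal(unname(local_richness(m)), c(3L, 0L))
  eye <- community_matrix(matrix(diag(4), 4,
                                 dimnames = list(paste0("s", 1:4),
                                                 paste0("t", 1:4))),
                          "presence")
  expect_equal(unname(local_richness(eye)), rep(1L, 4))
  expect_error(local_richness(community_matrix(
    matrix(2, 1, 1, dimnames = list("s", "t")), "count")), "presence")
})

test_that("a flat richness profile fits a zero slope and log-mean intercept", {
  fit <- fit_richness_glm(rep(20L, 8), seq(0, 700, 100))
  expect_equal(fit$slope, 0, tolerance = 1e-9)
  expect_equal(fit$intercept, log(20), tolerance = 1e-9)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
})

test_that("the Poisson GLM recovers a known distance-decay slope", {
  d <- seq(0, 900, 100)
  y <- round(exp(2 - 0.001 * d) * 10)   # exact log-linear signal, scaled up
  fit <- fit_richness_glm(as.integer(y), d)
  expect_equal(fit$slope, -0.001, tolerance = 2e-3)
  expect_lt(fit$z["slope"], 0)
})

test_that("the GLM matches an independent Newton-Raphson optimiser to 6 decimals", {
  y <- c(31L, 25L, 18L, 12L, 9L)
  d <- c(0, 150, 320, 500, 640)
  fit <- fit_richness_glm(y, d)
  ref <- newton_poisson(y, d)
  expect_equal(fit$intercept, ref[1], tolerance = 1e-6)
  expect_equal(fit$slope, ref[2], tolerance = 1e-6)
  # log-likelihood consistency with the closed form
  ll <- sum(stats::dpois(y, exp(ref[1] + ref[2] * d), log = TRUE))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
})

test_that("exact accumulation equals the average over all site orderings", {
  m <- random_presence(3, 12, seed = 9, p = 0.5)
  curve <- accumulation_curve(m, method = "exact", n_perm = 50, seed = 1)
  expect_equal(curve$mean, exhaustive_accumulation(m$values),
               tolerance = 1e-12)
  # full accumulation reaches the observed pooled richness
  expect_equal(curve$mean[3], sum(colSums(m$values) > 0))
})

test_that("accumulation handles degenerate and grouped input", {
  one <- community_matrix(matrix(1, 4, 1, dimnames = list(paste0("s", 1:4),
                                                          "t1")),
                          "presence")
  curve <- accumulation_curve(one, n_perm = 10, seed = 1)
  expect_equal(curve$mean, rep(1, 4))
  expect_equal(curve$sd, rep(0, 4))
  m <- random_presence(8, 15, seed = 2)
  grouped <- accumulation_curve(m, groups = rep(c("r1", "r2"), each = 4),
                                n_perm = 20, seed = 1)
  expect_equal(unique(grouped$group), c("r1", "r2"))
  expect_equal(max(grouped$k), 4)
  # means are non-decreasing within each group
  for (g in c("r1", "r2"))
    expect_true(all(diff(grouped$mean[grouped$group == g]) >= -1e-12))
})

test_that("permutation mean converges to the exact curve", {
  m <- random_presence(10, 30, seed = 4, p = 0.3)
  ex <- accumulation_curve(m, method = "exact", n_perm = 100, seed = 1)
  pm <- accumulation_curve(m, method = "permutation", n_perm = 2000, seed = 2)
  se <- pm$sd / sqrt(2000)
  expect_true(all(abs(ex$mean - pm$mean) <= 3 * se + 1e-9))
})

test_that("exact accumulation agrees with vegan's sample-based rarefaction", {
  skip_if_not_installed("vegan")
  m <- random_presence(9, 25, seed = 6, p = 0.35)
  ours <- accumulation_curve(m, method = "exact", n_perm = 10, seed = 1)
  ref <- vegan::specaccum(m$values, method = "exact")
  expect_equal(ours$mean, as.numeric(ref$richness), tolerance = 1e-8)
})

test_that("environmental PCA works on the correlation matrix with fixed signs", {
  # two perfectly correlated variables: one component carries everything
  x <- cbind(a = 1:6, b = 2 * (1:6) + 3)
  p <- env_pca(x)
  expect_equal(p$explained[1], 1, tolerance = 1e-12)
  set.seed(8)
  env <- matrix(rnorm(12 * 4), 12, dimnames = list(NULL, c("w", "x", "y", "z")))
  p2 <- env_pca(env)
  expect_equal(sum(p2$explained), 1, tolerance = 1e-12)
  # matches prcomp on scaled data up to component sign
  ref <- stats::prcomp(env, center = TRUE, scale. = TRUE)
  expect_equal(p2$explained, ref$sdev^2 / sum(ref$sdev^2), tolerance = 1e-9)
  expect_equal(abs(p2$loadings), abs(unclass(ref$rotation)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # the largest loading of each component is positive
  for (j in 1:4) expect_gt(p2$loadings[which.max(abs(p2$loadings[, j])), j], 0)
  expect_error(env_pca(cbind(a = rep(1, 5), b = 1:5)), "zero-variance.*a")
})
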