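#' Evaluate code with a temporary RNG seed
#'
#' Sets the random seed, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded operations never perturb the global random
#' stream. All stochastic functions in the package route their randomness
#' through this helper.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage substream seed from a master seed; fixed offsets keep
# stages independent while the whole run stays reproducible from one integer.
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483647L
}

# shared argument checks ------------------------------------------------

check_square_sym <- function(d, name = deparse(substitute(d))) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE)))
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions, about 0 for independent ones. Used to score
#' recovery of planted zones by the clustering stage.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return A single numeric.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length",
                                   call. = FALSE)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(length(a))
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
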