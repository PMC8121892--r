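# small in-code fixtures shared across test files

toy_table <- function() {
  counts <- matrix(c(5L, 0L, 100L,
                     0L, 8L, 40L,
                     2L, 1L, 0L),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("a1", "a2", "neg1"),
                                   c("t1", "t2", "t3")))
  meta <- data.frame(sample_id = c("a1", "a2", "neg1"),
                     site_id = c("A", "A", NA),
                     replicate = c(1L, 2L, 1L),
                     bank = c("left", "left", NA),
                     primer = "kelly",
                     is_negative = c(FALSE, FALSE, TRUE))
  count_table(counts, meta)
}

random_count_table <- function(n_samples = 6, n_taxa = 8, n_sites = 2,
                               seed = 1, lambda = 30) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_taxa, lambda), n_samples,
                   dimnames = list(paste0("s", seq_len(n_samples)),
                                   paste0("t", seq_len(n_taxa))))
  neg <- c(rep(FALSE, n_samples - 1), TRUE)
  meta <- data.frame(sample_id = rownames(counts),
                     site_id = ifelse(neg, NA,
                                      paste0("site",
                                             rep_len(seq_len(n_sites),
                                                     n_samples))),
                     replicate = seq_len(n_samples),
                     is_negative = neg)
  count_table(counts, meta)
}

random_presence <- function(n_sites = 8, n_taxa = 20, seed = 1, p = 0.4) {
  set.seed(seed)
  m <- matrix(rbinom(n_sites * n_taxa, 1, p), n_sites,
              dimnames = list(paste0("s", seq_len(n_sites)),
                              paste0("t", seq_len(n_taxa))))
  community_matrix(m, "presence")
}

# Y-shaped network: A and B on different branches above a confluence J,
# outlet O below J.
y_network <- function() {
  river_network(data.frame(from = c("A", "B", "J"),
                           to = c("J", "J", "O"),
                           length_km = c(10, 5, 3)),
                outlet = "O", site_ids = c("A", "B", "O"))
}

chain_network <- function(n = 4, len = 1) {
  nodes <- paste0("n", seq_len(n))
  river_network(data.frame(from = nodes[-n], to = nodes[-1],
                           length_km = len),
                outlet = nodes[1])
}

random_tree_network <- function(n, seed) {
  set.seed(seed)
  # random recursive tree: node i attaches to a uniform earlier node
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  edges <- data.frame(from = paste0("n", parent[-1]),
                      to = paste0("n", 2:n),
                      length_km = round(runif(n - 1, 0.5, 20), 3))
  river_network(edges, outlet = "n1")
}

# two tight, well-separated groups of points (rows), for separable-case tests
blob_matrix <- function(n_per = 5, sep = 100, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 3, 10, 0.5), n_per),
             matrix(rnorm(n_per * 3, 10 + sep, 0.5), n_per))
  rownames(X) <- paste0("s", seq_len(2 * n_per))
  X
}
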