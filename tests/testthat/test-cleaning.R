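make_single_sample <- function(counts) {
  m <- matrix(as.integer(counts), 1,
              dimnames = list("s1", paste0("t", seq_along(counts))))
  count_table(m, data.frame(sample_id = "s1", site_id = "A",
                            replicate = 1L, is_negative = FALSE))
}

test_that("low-frequency filter uses a strict per-sample threshold", {
  # total 10,000 reads; 0.1% threshold = 10 reads
  tb <- make_single_sample(c(9, 10, 9981))
  out <- filter_low_frequency(tb, 0.001)
  expect_equal(unname(out$counts[1, ]), c(0L, 10L, 9981L))
  # fraction 0 keeps everything
  expect_identical(filter_low_frequency(tb, 0)$counts, tb$counts)
  # threshold computed on the pre-filter total, single pass: t2 with 12
  # reads survives even though removing t1 lowers the total
  tb2 <- make_single_sample(c(5, 12, 9983))
  out2 <- filter_low_frequency(tb2, 0.001)
  expect_equal(unname(out2$counts[1, ]), c(0L, 12L, 9983L))
  expect_error(filter_low_frequency(tb, 1), "fraction")
})

test_that("negative-control subtraction removes the per-taxon maximum and floors at zero", {
  counts <- matrix(c(7L, 3L, 10L,
                     5L, 0L, 10L,
                     2L, 5L, 0L),
                   3, byrow = TRUE,
                   dimnames = list(c("a", "b", "n1"), c("t1", "t2", "t3")))
  meta <- data.frame(sample_id = c("a", "b", "n1"),
                     site_id = c("A", "B", NA), replicate = 1L,
                     is_negative = c(FALSE, FALSE, TRUE))
  out <- subtract_negative_controls(count_table(counts, meta))
  expect_equal(nrow(out$counts), 2)           # negative rows dropped
  expect_equal(unname(out$counts["a", ]), c(5L, 0L, 10L))  # 7-2, 3-5->0, t3 untouched
  expect_equal(unname(out$counts["b", ]), c(3L, 0L, 10L))
  # no negatives: identity
  tb <- random_count_table(seed = 5)
  tb$meta$is_negative[] <- FALSE
  expect_identical(subtract_negative_controls(tb)$counts, tb$counts)
})

test_that("replicate merging takes union presence or per-taxon maxima", {
  counts <- matrix(c(0L, 4L,
                     0L, 9L,
                     3L, 0L),
                   3, byrow = TRUE,
                   dimnames = list(c("r1", "r2", "r3"), c("t1", "t2")))
  meta <- data.frame(sample_id = c("r1", "r2", "r3"),
                     site_id = c("A", "A", "A"), replicate = 1:3,
                     is_negative = FALSE)
  tb <- count_table(counts, meta)
  up <- merge_replicates(tb, "union_presence")
  expect_equal(unname(up$values["A", ]), c(1, 1))
  mx <- merge_replicates(tb, "max_count")
  expect_equal(unname(mx$values["A", ]), c(3, 9))
  # a single-replicate site passes through unchanged
  single <- count_table(counts[1, , drop = FALSE], meta[1, ])
  expect_equal(unname(merge_replicates(single, "max_count")$values["A", ]),
               c(0, 4))
})

test_that("primer merging is a union-aligned maximum: commutative and idempotent", {
  a <- community_matrix(matrix(c(10, 0, 50), 1,
                               dimnames = list("A", c("t1", "t2", "t3"))),
                        "count")
  b <- community_matrix(matrix(c(25, 7), 1,
                               dimnames = list("A", c("t1", "t2"))),
                        "count")
  m <- merge_primers(a, b, "max_count")
  expect_equal(m$values["A", "t1"], 25)       # max wins
  expect_equal(m$values["A", "t2"], 7)
  expect_equal(m$values["A", "t3"], 50)       # implicit zero in b
  m2 <- merge_primers(b, a, "max_count")
  expect_equal(m$values[, colnames(m$values), drop = FALSE],
               m2$values[, colnames(m$values), drop = FALSE])
  self <- merge_primers(a, a, "max_count")
  expect_equal(self$values[, colnames(a$values), drop = FALSE], a$values)
  bad <- community_matrix(matrix(1, 1, 1, dimnames = list("B", "t1")),
                          "count")
  expect_error(merge_primers(a, bad), "site sets differ")
})

test_that("presence conversion thresholds at zero and is idempotent", {
  m <- community_matrix(matrix(c(0, 1, 37, 0, 0, 0), 2, byrow = TRUE,
                               dimnames = list(c("A", "B"),
                                               c("t1", "t2", "t3"))),
                        "count")
  p <- to_presence_absence(m)
  expect_equal(unname(p$values["A", ]), c(0, 1, 1))
  expect_equal(unname(p$values["B", ]), c(0, 0, 0))
  expect_identical(to_presence_absence(p), p)
})

test_that("cleaning never increases a count and keeps integers non-negative", {
  for (seed in 1:10) {
    tb <- random_count_table(n_samples = 8, n_taxa = 12, seed = seed)
    f <- filter_low_frequency(tb, 0.02)
    expect_true(all(f$counts <= tb$counts))
    s <- subtract_negative_controls(f)
    keep <- !tb$meta$is_negative
    expect_true(all(s$counts <= f$counts[keep, ]))
    expect_true(all(s$counts >= 0))
    expect_type(s$counts[1], "integer")
  }
})

test_that("presence of the max-count merge equals the union-presence merge", {
  for (seed in 1:5) {
    ta <- random_count_table(n_samples = 6, n_taxa = 10, seed = seed)
    tb <- random_count_table(n_samples = 6, n_taxa = 10, seed = seed + 100)
    a <- merge_replicates(ta, "max_count")
    b <- merge_replicates(tb, "max_count")
    lhs <- to_presence_absence(merge_primers(a, b, "max_count"))
    rhs <- merge_primers(to_presence_absence(a), to_presence_absence(b),
                         "union_presence")
    expect_equal(lhs$values[, colnames(lhs$values)],
                 rhs$values[, colnames(lhs$values)])
  }
})

test_that("default cleaning keeps false detection rates low on simulated surveys", {
  cfg <- scenario_config("four_zone", seed = 11)
  ds <- generate_dataset(cfg)
  pres <- to_presence_absence(clean_pipeline(ds$kelly, ds$mifish))
  truth <- ds$truth$presence
  pv <- pres$values[rownames(truth), colnames(truth)]
  fpr <- sum(pv == 1 & truth == 0) / sum(truth == 0)
  fnr <- sum(pv == 0 & truth == 1) / sum(truth == 1)
  expect_lt(fpr, 0.05)
  expect_lt(fnr, 0.10)
})
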