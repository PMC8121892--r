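#' Remove low-frequency reads per sample
#'
#' Standard metabarcoding contamination control: within each sample, any
#' taxon whose read count falls strictly below `fraction` of that sample's
#' total reads (totals taken before filtering) is set to zero. The filter is
#' a single pass; totals are not recomputed iteratively.
#'
#' @param table A [count_table()] object.
#' @param fraction Proportion of the per-sample total used as the threshold;
#'   default 0.001 (i.e. 0.1% of total reads).
#' @return A filtered `read_count_table`.
#' @export
filter_low_frequency <- function(table, fraction = 0.001) {
  stopifnot(inherits(table, "read_count_table"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction < 0 || fraction >= 1)
    stop("fraction must be a single value in [0, 1)", call. = FALSE)
  counts <- table$counts
  thresh <- fraction * rowSums(counts)          # per-sample, pre-filter totals
  keep <- counts >= matrix(thresh, nrow(counts), ncol(counts))
  counts[!keep] <- 0L
  count_table(counts, table$meta)
}

#' Subtract the negative-control maximum from every sample
#'
#' For each taxon, the greatest read count observed in any negative control
#' is removed from every field sample (floored at zero). Negative-control
#' rows are dropped from the output. With no negative controls the table is
#' returned with counts unchanged.
#'
#' @param table A [count_table()] object.
#' @return A `read_count_table` containing only non-control samples.
#' @export
subtract_negative_controls <- function(table) {
  stopifnot(inherits(table, "read_count_table"))
  neg <- table$meta$is_negative
  m <- if (any(neg)) {
    apply(table$counts[neg, , drop = FALSE], 2, max)
  } else {
    rep(0L, ncol(table$counts))
  }
  counts <- table$counts[!neg, , drop = FALSE]
  counts <- pmax(sweep(counts, 2, m), 0L)
  storage.mode(counts) <- "integer"
  count_table(counts, table$meta[!neg, , drop = FALSE])
}

#' Merge field replicates into one row per site
#'
#' @param table A [count_table()] object with no negative-control rows (or
#'   with negatives already removed); every sample must carry a `site_id`.
#' @param mode `"union_presence"`: a taxon is present at a site if any
#'   replicate detected it; `"max_count"`: per-taxon maximum read count over
#'   the site's replicates.
#' @return A [community_matrix()], mode `"presence"` or `"count"`.
#' @export
merge_replicates <- function(table, mode = c("union_presence", "max_count")) {
  stopifnot(inherits(table, "read_count_table"))
  mode <- match.arg(mode)
  meta <- table$meta[!table$meta$is_negative, , drop = FALSE]
  counts <- table$counts[!table$meta$is_negative, , drop = FALSE]
  if (is.null(meta$site_id) || any(is.na(meta$site_id)) ||
      any(meta$site_id == ""))
    stop("every non-control sample must have a site_id", call. = FALSE)
  sites <- unique(meta$site_id)
  out <- matrix(0, length(sites), ncol(counts),
                dimnames = list(sites, colnames(counts)))
  for (s in sites) {
    rows <- counts[meta$site_id == s, , drop = FALSE]
    if (nrow(rows) == 0)
      stop(sprintf("site '%s' has no samples after cleaning", s),
           call. = FALSE)
    out[s, ] <- apply(rows, 2, max)
  }
  if (mode == "union_presence") {
    out <- (out > 0) + 0
    community_matrix(out, "presence")
  } else {
    community_matrix(out, "count")
  }
}

#' Combine two primer sets' community matrices
#'
#' Aligns the two taxon universes by their union (taxa absent from one
#' matrix become explicit zero columns) and combines per site and taxon by
#' the maximum count (`"max_count"`) or logical OR (`"union_presence"`),
#' reflecting that each primer set detects an overlapping but unequal subset
#' of the community.
#'
#' @param a,b [community_matrix()] objects over the same site set.
#' @param mode `"max_count"` (requires count mode) or `"union_presence"`.
#' @return A combined `community_matrix`.
#' @export
merge_primers <- function(a, b, mode = c("max_count", "union_presence")) {
  stopifnot(inherits(a, "community_matrix"), inherits(b, "community_matrix"))
  mode <- match.arg(mode)
  if (!setequal(rownames(a$values), rownames(b$values))) {
    only_a <- setdiff(rownames(a$values), rownames(b$values))
    only_b <- setdiff(rownames(b$values), rownames(a$values))
    stop(sprintf("site sets differ (only in a: %s; only in b: %s)",
                 paste(only_a, collapse = ",") ,
                 paste(only_b, collapse = ",")), call. = FALSE)
  }
  sites <- rownames(a$values)
  taxa <- union(colnames(a$values), colnames(b$values))
  expand <- function(m) {
    out <- matrix(0, length(sites), length(taxa),
                  dimnames = list(sites, taxa))
    out[, colnames(m$values)] <- m$values[sites, , drop = FALSE]
    out
  }
  va <- expand(a); vb <- expand(b)
  merged <- pmax(va, vb)
  if (mode == "union_presence") {
    community_matrix((merged > 0) + 0, "presence")
  } else {
    if (a$mode != "count" || b$mode != "count")
      stop("max_count merge requires count-mode matrices", call. = FALSE)
    community_matrix(merged, "count")
  }
}

#' Convert a count community matrix to presence/absence
#'
#' @param m A [community_matrix()]. Presence input is returned unchanged.
#' @return A `community_matrix` in presence mode.
#' @export
to_presence_absence <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  if (m$mode == "presence") return(m)
  community_matrix((m$values > 0) + 0, "presence")
}

#' Run the full cleaning chain on a pair of primer tables
#'
#' Convenience wrapper applying, in order: the per-sample low-frequency
#' filter, negative-control subtraction, replicate merging (max count per
#' site), and the cross-primer maximum merge. The presence/absence view used
#' for alpha/beta diversity is obtained with [to_presence_absence()].
#'
#' @param kelly,mifish [count_table()] objects, one per primer set.
#' @param fraction Low-frequency threshold, see [filter_low_frequency()].
#' @return A count-mode [community_matrix()] (sites x union of taxa).
#' @export
clean_pipeline <- function(kelly, mifish, fraction = 0.001) {
  step <- function(tb) {
    tb <- filter_low_frequency(tb, fraction)
    tb <- subtract_negative_controls(tb)
    merge_replicates(tb, "max_count")
  }
  merge_primers(step(kelly), step(mifish), "max_count")
}
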