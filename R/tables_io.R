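#' Construct a per-sample read-count table
#'
#' The raw input of the pipeline: one row per water sample (field replicate
#' or negative control), one column per taxon, holding non-negative integer
#' read counts, plus per-sample metadata.
#'
#' @param counts Integer matrix, rows = samples, columns = taxa. Row names
#'   (or `sample_meta$sample_id`) identify samples; column names are taxon ids.
#' @param sample_meta Data frame with one row per sample. Recognised columns:
#'   `sample_id`, `site_id`, `replicate` (1-based index within site),
#'   `bank` (`"left"`, `"centre"`, `"right"`), `primer` and `is_negative`
#'   (logical). Unrecognised columns are carried through untouched.
#' @return An object of class `read_count_table`: a list with elements
#'   `counts` (integer matrix) and `meta` (data frame).
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("taxA", "taxB")))
#' meta <- data.frame(sample_id = c("s1", "s2"), site_id = "site1",
#'                    replicate = 1:2, is_negative = FALSE)
#' count_table(m, meta)
#' @export
count_table <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(is.na(counts)))
    stop("counts contain missing values", call. = FALSE)
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1]] %||% bad[1],
                 colnames(counts)[bad[2]] %||% bad[2]), call. = FALSE)
  }
  if (any(counts != round(counts)))
    stop("counts must be integral", call. = FALSE)
  storage.mode(counts) <- "integer"
  sample_meta <- as.data.frame(sample_meta)
  if (is.null(sample_meta$sample_id)) {
    if (is.null(rownames(counts)))
      stop("sample ids missing: provide rownames or sample_meta$sample_id",
           call. = FALSE)
    sample_meta$sample_id <- rownames(counts)
  }
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  if (anyDuplicated(sample_meta$sample_id))
    stop(sprintf("duplicate sample_id: %s",
                 paste(unique(sample_meta$sample_id[
                   duplicated(sample_meta$sample_id)]), collapse = ", ")),
         call. = FALSE)
  if (nrow(sample_meta) != nrow(counts))
    stop("sample_meta rows do not match count rows", call. = FALSE)
  rownames(counts) <- sample_meta$sample_id
  if (is.null(colnames(counts)))
    stop("counts must have taxon ids as column names", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids", call. = FALSE)
  if (is.null(sample_meta$is_negative)) sample_meta$is_negative <- FALSE
  sample_meta$is_negative <- as.logical(sample_meta$is_negative)
  if (!is.null(sample_meta$bank)) {
    ok <- is.na(sample_meta$bank) |
      sample_meta$bank %in% c("left", "centre", "right")
    if (!all(ok))
      stop("bank must be one of left/centre/right", call. = FALSE)
  }
  structure(list(counts = counts, meta = sample_meta),
            class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  cat(sprintf("read_count_table: %d samples x %d taxa (%d negative controls)\n",
              nrow(x$counts), ncol(x$counts), sum(x$meta$is_negative)))
  cat(sprintf("  total reads: %s\n", format(sum(as.numeric(x$counts)),
                                            big.mark = ",")))
  invisible(x)
}

#' @export
dim.read_count_table <- function(x) dim(x$counts)

#' Read a read-count table and its sample metadata from TSV files
#'
#' Both files are UTF-8, tab-separated with a header row. The counts file has
#' `sample_id` as its first column and one column per taxon; the metadata
#' file has one row per sample keyed by `sample_id`.
#'
#' @param path Path to the counts TSV.
#' @param meta_path Path to the metadata TSV.
#' @return A [count_table()] object.
#' @export
read_count_table <- function(path, meta_path) {
  if (!file.exists(path)) stop(sprintf("counts file not found: %s", path),
                               call. = FALSE)
  if (!file.exists(meta_path)) stop(sprintf("metadata file not found: %s",
                                            meta_path), call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (names(raw)[1] != "sample_id")
    stop("first column of the counts TSV must be 'sample_id'", call. = FALSE)
  ids <- raw[[1]]
  num <- raw[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    if (any(is.na(v) & !is.na(num[[j]]))) {
      i <- which(is.na(v) & !is.na(num[[j]]))[1]
      stop(sprintf("malformed count at sample '%s', taxon '%s': '%s'",
                   ids[i], names(num)[j], num[[j]][i]), call. = FALSE)
    }
    num[[j]] <- v
  }
  counts <- as.matrix(num)
  rownames(counts) <- ids
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.null(meta$sample_id))
    stop("metadata TSV must contain a 'sample_id' column", call. = FALSE)
  missing <- setdiff(ids, meta$sample_id)
  if (length(missing))
    stop(sprintf("samples missing from metadata: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  count_table(counts, meta)
}

#' Write a read-count table (and its metadata) as TSV
#'
#' @param x A `read_count_table`.
#' @param path Counts TSV destination.
#' @param meta_path Metadata TSV destination.
#' @return `x`, invisibly.
#' @export
write_count_table <- function(x, path, meta_path) {
  stopifnot(inherits(x, "read_count_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(x$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(x)
}

#' Construct a site-by-taxon community matrix
#'
#' The analysis-ready container behind all diversity and clustering stages:
#' one row per site, either read counts (`mode = "count"`) or incidence
#' (`mode = "presence"`, values 0/1).
#'
#' @param values Numeric matrix, rows = sites (named), columns = taxa (named).
#' @param mode `"count"` or `"presence"`.
#' @return An object of class `community_matrix`.
#' @export
community_matrix <- function(values, mode = c("count", "presence")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("site ids must be unique row names", call. = FALSE)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("taxon ids must be unique column names", call. = FALSE)
  if (any(is.na(values)) || any(values < 0))
    stop("community values must be non-negative and complete", call. = FALSE)
  if (mode == "presence" && !all(values %in% c(0, 1)))
    stop("presence mode requires 0/1 values", call. = FALSE)
  structure(list(values = values, mode = mode), class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix (%s): %d sites x %d taxa\n",
              x$mode, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$values)

#' @rdname community_matrix
#' @param path TSV path (first column `site_id`, then one column per taxon).
#' @export
read_community_matrix <- function(path, mode = c("count", "presence")) {
  mode <- match.arg(mode)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (names(raw)[1] != "site_id")
    stop("first column must be 'site_id'", call. = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  community_matrix(m, mode)
}

#' @rdname community_matrix
#' @param x A `community_matrix`.
#' @export
write_community_matrix <- function(x, path) {
  stopifnot(inherits(x, "community_matrix"))
  df <- data.frame(site_id = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(x)
}

#' Overlap bookkeeping between two taxon inventories
#'
#' Exact set arithmetic for comparing the taxa recovered by two primer sets
#' (or any two surveys): shared and primer-exclusive counts, per-inventory
#' totals, the union, and each category's percentage of the union. Percentages
#' are stored at full precision; `print()` rounds them to the nearest integer.
#'
#' @param taxa_a,taxa_b Character vectors of taxon ids (duplicates ignored).
#' @return An object of class `overlap_summary`: a list with integer fields
#'   `n_shared`, `n_unique_a`, `n_unique_b`, `n_total_a`, `n_total_b`,
#'   `n_union` and numeric percentages `pct_shared`, `pct_unique_a`,
#'   `pct_unique_b` (of the union).
#' @examples
#' inventory_overlap(c("x", "y"), c("y", "z"))
#' @export
inventory_overlap <- function(taxa_a, taxa_b) {
  a <- unique(as.character(taxa_a))
  b <- unique(as.character(taxa_b))
  shared <- length(intersect(a, b))
  ua <- length(setdiff(a, b))
  ub <- length(setdiff(b, a))
  un <- shared + ua + ub
  pct <- function(x) if (un == 0) 0 else 100 * x / un
  structure(list(n_shared = shared, n_unique_a = ua, n_unique_b = ub,
                 n_total_a = shared + ua, n_total_b = shared + ub,
                 n_union = un,
                 pct_shared = pct(shared), pct_unique_a = pct(ua),
                 pct_unique_b = pct(ub)),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("taxon inventory overlap: %d taxa in union\n", x$n_union))
  cat(sprintf("  shared:    %3d (%d%%)\n", x$n_shared, round(x$pct_shared)))
  cat(sprintf("  unique A:  %3d (%d%%)  [total A: %d]\n",
              x$n_unique_a, round(x$pct_unique_a), x$n_total_a))
  cat(sprintf("  unique B:  %3d (%d%%)  [total B: %d]\n",
              x$n_unique_b, round(x$pct_unique_b), x$n_total_b))
  invisible(x)
}
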