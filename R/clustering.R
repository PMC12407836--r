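#' Cluster nominated cut sites by greedy proximity
#'
#' Cut positions reported for the same genomic site jitter by a few bases
#' between assays and prediction tools. Records are sorted by
#' `(chrom, position)` and swept once: a record joins the open cluster iff it
#' is on the same contig and within `window` bp of the cluster's *seed* (its
#' first record); otherwise a new cluster opens. Anchoring membership to the
#' seed rather than the last member bounds the cluster diameter at
#' `2 * window` and prevents chaining across a dense region.
#'
#' The cluster representative is the member position with the greatest
#' support, where support at a position is the number of records there plus
#' their summed dsODN abundance; ties resolve to the smallest coordinate.
#'
#' @param records tibble of cut-site records as returned by
#'   [read_nomination_table()].
#' @param window non-negative clustering radius in bp (default 15).
#' @return a tibble with one row per cluster: `cluster_id`, `chrom`,
#'   `representative` (0-based cut coordinate), `n_members`, `n_sources`,
#'   `n_samples`, and list-columns `members` (the record tibble),
#'   `source_support` and `sample_support` (named counts).
#' @export
cluster_cut_sites <- function(records, window = 15) {
  if (!is.numeric(window) || length(window) != 1 || is.na(window) ||
      window < 0) {
    stop("window must be a non-negative number", call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(tibble(
      cluster_id = integer(), chrom = character(), representative = integer(),
      n_members = integer(), n_sources = integer(), n_samples = integer(),
      members = list(), source_support = list(), sample_support = list()
    ))
  }
  rec <- records[order(records$chrom, records$start, records$source,
                       records$sample), , drop = FALSE]
  n <- nrow(rec)
  cluster_id <- integer(n)
  cur <- 0L
  seed_chrom <- ""
  seed_pos <- -Inf
  for (i in seq_len(n)) {
    if (rec$chrom[i] != seed_chrom ||
        abs(rec$start[i] - seed_pos) > window) {
      cur <- cur + 1L
      seed_chrom <- rec$chrom[i]
      seed_pos <- rec$start[i]
    }
    cluster_id[i] <- cur
  }
  rec$cluster_id <- cluster_id
  split_rec <- split(rec, rec$cluster_id)
  rows <- lapply(split_rec, function(m) {
    support <- tapply(
      ifelse(is.na(m$abundance), 0, m$abundance) + 1,
      m$start, sum
    )
    pos <- as.integer(names(support))
    best <- pos[support == max(support)]
    tibble(
      cluster_id = m$cluster_id[1],
      chrom = m$chrom[1],
      representative = min(best),
      n_members = nrow(m),
      n_sources = length(unique(m$source)),
      n_samples = length(unique(m$sample)),
      members = list(m[setdiff(names(m), "cluster_id")]),
      source_support = list(table_to_counts(m$source)),
      sample_support = list(table_to_counts(m$sample))
    )
  })
  bind_rows(rows)
}

table_to_counts <- function(x) {
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a cluster summary table
#'
#' @param clusters output of [cluster_cut_sites()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  out <- tibble(
    cluster_id = clusters$cluster_id,
    chrom = clusters$chrom,
    representative = clusters$representative,
    n_members = clusters$n_members,
    n_sources = clusters$n_sources,
    n_samples = clusters$n_samples,
    member_sources = vapply(
      clusters$source_support,
      function(s) paste(names(s), collapse = ","), character(1)
    )
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
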