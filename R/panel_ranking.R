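#' Z-standardize per-source scores across clusters
#'
#' Nomination tools report scores on incommensurate scales, so each source's
#' raw scores are Z-standardized across all clusters (sample standard
#' deviation, n - 1). Sources that report no scores, or whose scores are
#' constant (sd = 0), contribute Z = 0 so rank-less tools call all their
#' sites equally. Each cluster's `mean_z` averages the Z-scores of its
#' member records; `minmax` rescales `mean_z` across clusters to `[0, 1]`
#' and `rank_by_z` orders clusters by decreasing `mean_z`.
#'
#' @param clusters output of [cluster_cut_sites()].
#' @return tibble with one row per cluster: `cluster_id`, `mean_z`,
#'   `minmax`, `rank_by_z`, and a list-column `per_source_z` of named
#'   per-source mean Z-scores.
#' @export
standardize_scores <- function(clusters) {
  if (nrow(clusters) == 0) stop("no clusters supplied", call. = FALSE)
  members <- bind_rows(lapply(seq_len(nrow(clusters)), function(i) {
    m <- clusters$members[[i]]
    m$cluster_id <- clusters$cluster_id[i]
    m
  }))
  members <- members |>
    group_by(.data$source) |>
    mutate(z = z_standardize(.data$score)) |>
    ungroup()
  per_cluster <- members |>
    group_by(.data$cluster_id) |>
    summarise(
      mean_z = mean(.data$z),
      per_source_z = list(tapply(.data$z, .data$source, mean)),
      .groups = "drop"
    )
  per_cluster |>
    mutate(
      minmax = minmax_scale(.data$mean_z),
      rank_by_z = rank(-.data$mean_z, ties.method = "first")
    )
}

z_standardize <- function(score) {
  obs <- score[!is.na(score)]
  if (length(obs) < 2) return(rep(0, length(score)))
  s <- sd(obs)
  if (is.na(s) || s == 0) return(rep(0, length(score)))
  z <- (score - mean(obs)) / s
  ifelse(is.na(z), 0, z)
}

#' Min-max rescale values to \[0, 1\]
#'
#' `v -> (v - min) / (max - min)`. A constant vector maps to 0.5 everywhere:
#' a source with no dynamic range should neither boost nor bury sites.
#'
#' @param values non-empty numeric vector of finite values.
#' @return numeric vector in `[0, 1]`.
#' @export
minmax_scale <- function(values) {
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0.5, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Annotate aligned clusters with feature overlaps
#'
#' A cluster carries a feature label iff its protospacer interval overlaps
#' any interval of that label (half-open overlap, strand-ignorant). Feature
#' intervals are used as supplied; they are not merged.
#'
#' @param alignments output of [align_clusters()].
#' @param features tibble of feature intervals (`label`, `chrom`, `start`,
#'   `end`), e.g. rows bound from [read_feature_intervals()] calls.
#' @return tibble `cluster_id`, list-column `annotations` (character vector
#'   of labels per cluster).
#' @export
annotate_clusters <- function(alignments, features) {
  if (is.null(features) || nrow(features) == 0) {
    return(tibble(cluster_id = alignments$cluster_id,
                  annotations = rep(list(character(0)),
                                    nrow(alignments))))
  }
  q <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(alignments$start + 1L, alignments$end)
  )
  s <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start + 1L, features$end)
  )
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  ann <- rep(list(character(0)), nrow(alignments))
  if (length(hits) > 0) {
    by_q <- split(features$label[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
    for (nm in names(by_q)) {
      ann[[as.integer(nm)]] <- sort(unique(by_q[[nm]]))
    }
  }
  tibble(cluster_id = alignments$cluster_id, annotations = ann)
}

#' Build the editable criterion weight table
#'
#' One row per ranking criterion. Default weights encode the panel-design
#' priorities: empirical detection first (each empirical source `+3`), then
#' multi-tool in-silico support (each source `+1`, each additional sample
#' `+1`), then genotoxicity-relevant genomic context (exon `+2`, oncogene
#' `+2`, other features `+1`) and sequence similarity (Levenshtein distance
#' at most `lev_threshold` gives `+1`). The table round-trips through TSV so
#' users can edit weights before ranking.
#'
#' @param records nomination records (to enumerate sources, their evidence
#'   kinds and samples).
#' @param feature_labels character vector of feature labels in use.
#' @param lev_threshold Levenshtein rule threshold (default 4).
#' @param empirical_weight,insilico_weight,sample_weight,exon_weight,oncogene_weight,other_feature_weight,lev_weight
#'   default weights per criterion class.
#' @return tibble with columns `criterion`, `weight`.
#' @export
build_weight_table <- function(records, feature_labels = character(0),
                               lev_threshold = 4,
                               empirical_weight = 3, insilico_weight = 1,
                               sample_weight = 1, exon_weight = 2,
                               oncogene_weight = 2, other_feature_weight = 1,
                               lev_weight = 1) {
  src <- records |> distinct(.data$source, .data$evidence)
  if (any(duplicated(src$source))) {
    stop("a source may not mix evidence kinds", call. = FALSE)
  }
  rows <- tibble(
    criterion = paste0("source:", src$source),
    weight = ifelse(grepl("^empirical", src$evidence),
                    empirical_weight, insilico_weight)
  )
  samples <- sort(unique(records$sample))
  rows <- bind_rows(rows, tibble(
    criterion = paste0("sample:", samples),
    weight = sample_weight
  ))
  if (length(feature_labels) > 0) {
    fw <- ifelse(feature_labels == "exon", exon_weight,
                 ifelse(feature_labels == "oncogene", oncogene_weight,
                        other_feature_weight))
    rows <- bind_rows(rows, tibble(
      criterion = paste0("feature:", feature_labels), weight = fw
    ))
  }
  rows <- bind_rows(rows, tibble(
    criterion = paste0("levenshtein<=", lev_threshold), weight = lev_weight
  ))
  if (any(duplicated(rows$criterion))) {
    stop("duplicate criterion in weight table", call. = FALSE)
  }
  rows
}

#' @rdname build_weight_table
#' @param path TSV path (`criterion` and `weight` columns).
#' @param reference_table optional table whose criterion set the edited file
#'   must match (unknown criteria are a config error).
#' @export
read_weight_table <- function(path, reference_table = NULL) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(criterion = readr::col_character(),
                            weight = readr::col_double()),
    progress = FALSE
  )
  if (any(duplicated(tab$criterion))) {
    stop("duplicate criterion in weight table", call. = FALSE)
  }
  if (any(!is.finite(tab$weight))) {
    stop("weights must be finite", call. = FALSE)
  }
  if (!is.null(reference_table)) {
    unknown <- setdiff(tab$criterion, reference_table$criterion)
    if (length(unknown) > 0) {
      stop("unknown criterion in weight table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  tab
}

#' @rdname build_weight_table
#' @param weights weight table to write.
#' @export
write_weight_table <- function(weights, path) {
  readr::write_tsv(weights, path, progress = FALSE)
  invisible(path)
}

#' Rank candidate sites by summed criterion weights
#'
#' Each cluster's `weight_sum` adds the weights of all satisfied criteria:
#' detection by a source, detection in a sample, each feature annotation,
#' and the Levenshtein rule. Sites are ordered by decreasing `weight_sum`
#' with deterministic tie-breaking (higher `mean_z`, lower Levenshtein
#' distance, then chromosome and coordinate) and given dense ranks from 1.
#'
#' @param alignments output of [align_clusters()].
#' @param annotations output of [annotate_clusters()].
#' @param scores output of [standardize_scores()].
#' @param clusters output of [cluster_cut_sites()].
#' @param weights weight table (see [build_weight_table()]).
#' @return tibble of ranked sites: `final_rank`, `cluster_id`, coordinates,
#'   `levenshtein`, `mean_z`, `minmax`, `annotations`, `weight_sum`,
#'   `evidence` (list of member evidence kinds), `n_insilico_sources`.
#' @export
rank_sites <- function(alignments, annotations, scores, clusters, weights) {
  lev_rows <- grep("^levenshtein<=", weights$criterion, value = TRUE)
  lev_thresholds <- as.numeric(sub("^levenshtein<=", "", lev_rows))
  wmap <- stats::setNames(weights$weight, weights$criterion)
  tab <- alignments |>
    select("cluster_id", "chrom", "start", "end", "strand",
           "levenshtein") |>
    left_join(annotations, by = "cluster_id") |>
    left_join(select(scores, "cluster_id", "mean_z", "minmax"),
              by = "cluster_id") |>
    left_join(select(clusters, "cluster_id", "source_support",
                     "sample_support", "members"),
              by = "cluster_id")
  weight_of <- function(key) {
    if (!key %in% names(wmap)) {
      stop("no weight defined for criterion: ", key, call. = FALSE)
    }
    unname(wmap[key])
  }
  tab$weight_sum <- vapply(seq_len(nrow(tab)), function(i) {
    w <- 0
    for (s in names(tab$source_support[[i]])) {
      w <- w + weight_of(paste0("source:", s))
    }
    for (s in names(tab$sample_support[[i]])) {
      w <- w + weight_of(paste0("sample:", s))
    }
    for (f in tab$annotations[[i]]) {
      w <- w + weight_of(paste0("feature:", f))
    }
    for (j in seq_along(lev_thresholds)) {
      if (tab$levenshtein[i] <= lev_thresholds[j]) {
        w <- w + unname(wmap[lev_rows[j]])
      }
    }
    w
  }, numeric(1))
  tab$evidence <- lapply(tab$members, function(m) unique(m$evidence))
  tab$n_insilico_sources <- vapply(tab$members, function(m) {
    length(unique(m$source[grepl("^insilico", m$evidence)]))
  }, integer(1))
  tab <- tab[order(-tab$weight_sum, -tab$mean_z, tab$levenshtein,
                   tab$chrom, tab$start), , drop = FALSE]
  tab$final_rank <- seq_len(nrow(tab))
  tab |>
    select("final_rank", "cluster_id", "chrom", "start", "end", "strand",
           "levenshtein", "mean_z", "minmax", "annotations", "weight_sum",
           "evidence", "n_insilico_sources")
}

#' Select the tiered amplicon panel
#'
#' Panel construction mirrors the design logic of empirical-first tiering:
#' tier 1 takes every site with any empirical evidence; tier 2 adds
#' remaining sites supported by at least `min_tools` in-silico sources, in
#' rank order, until `panel_size` sites are selected. Exclusion-listed sites
#' (e.g. multiplex-primer incompatibilities) are removed and replaced by the
#' next-ranked eligible site.
#'
#' @param ranked output of [rank_sites()].
#' @param panel_size number of sites to select.
#' @param min_tools minimum in-silico sources for tier-2 membership
#'   (default 6).
#' @param exclusions cluster ids to exclude.
#' @return `ranked` with a `panel_tier` column
#'   (`empirical`/`multi_tool`/`excluded`/`unselected`), panel members
#'   first.
#' @export
select_panel <- function(ranked, panel_size, min_tools = 6,
                         exclusions = integer(0)) {
  if (panel_size <= 0) stop("panel_size must be positive", call. = FALSE)
  if (min_tools < 1) stop("min_tools must be >= 1", call. = FALSE)
  ranked <- ranked[order(ranked$final_rank), , drop = FALSE]
  is_emp <- vapply(ranked$evidence,
                   function(e) any(grepl("^empirical", e)), logical(1))
  excluded <- ranked$cluster_id %in% exclusions
  tier <- rep("unselected", nrow(ranked))
  tier[excluded] <- "excluded"
  sel_emp <- which(is_emp & !excluded)
  if (length(sel_emp) > panel_size) {
    warning("more empirical-evidence sites than panel_size; ",
            "lowest-ranked empirical sites dropped")
    sel_emp <- sel_emp[seq_len(panel_size)]
  }
  tier[sel_emp] <- "empirical"
  room <- panel_size - length(sel_emp)
  cand <- which(!is_emp & !excluded &
                  ranked$n_insilico_sources >= min_tools)
  sel_tool <- head(cand, room)
  tier[sel_tool] <- "multi_tool"
  n_sel <- length(sel_emp) + length(sel_tool)
  if (n_sel < panel_size) {
    warning("only ", n_sel, " sites available for a panel of ", panel_size)
  }
  ranked$panel_tier <- tier
  ranked[order(tier %in% c("unselected", "excluded"), ranked$final_rank), ,
         drop = FALSE]
}

#' Write the ranked-site table
#'
#' @param ranked output of [rank_sites()] or [select_panel()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranked_table <- function(ranked, path) {
  out <- ranked |>
    mutate(annotations = vapply(.data$annotations, function(a) {
      if (length(a) == 0) "." else paste(a, collapse = ",")
    }, character(1))) |>
    select(rank = "final_rank", "cluster_id", "chrom", "start", "end",
           "strand", "levenshtein", "mean_z", "minmax", "annotations",
           "weight_sum", dplyr::any_of("panel_tier"))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
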