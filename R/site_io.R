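#' Read a standardized cut-site nomination table
#'
#' Nomination tables collect candidate cut positions emitted by empirical
#' assays (e.g. dsODN-marking) and in-silico prediction tools, one row per
#' nominated position per source and sample. The file is tab-separated with a
#' header declaring at least `source`, `sample`, `chrom` and `position`;
#' optional columns are `strand`, `score` (`.` for missing), `evidence`
#' (one of `empirical_cleavage`, `empirical_editing`, `insilico_cleavage`,
#' `insilico_editing`) and `abundance` (unique adaptor-position counts for
#' dsODN assays).
#'
#' @param path path to a tab-separated nomination table.
#' @param dialect coordinate convention of the `position` column. All
#'   positions are normalized to the internal 0-based convention, where a cut
#'   position `p` denotes the blunt-cut boundary before base `p` and is stored
#'   as the point interval `[p, p+1)`.
#' @return a tibble with columns `source`, `sample`, `chrom`, `start`, `end`,
#'   `strand`, `score`, `evidence`, `abundance`; one row per record.
#' @export
read_nomination_table <- function(path, dialect = c("1-based", "0-based")) {
  if (!is.character(dialect) || !all(dialect %in% c("1-based", "0-based"))) {
    stop("unknown coordinate dialect: ", paste(dialect, collapse = ", "),
         call. = FALSE)
  }
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  required <- c("source", "sample", "chrom", "position")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("nomination table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(empty_records())
  }
  pos <- suppressWarnings(as.numeric(raw$position))
  bad <- which(is.na(pos) | pos != floor(pos))
  if (length(bad) > 0) {
    stop("non-integer position in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  start <- if (dialect == "1-based") as.integer(pos) - 1L else as.integer(pos)
  score <- if ("score" %in% names(raw)) {
    suppressWarnings(as.numeric(ifelse(raw$score == ".", NA, raw$score)))
  } else {
    rep(NA_real_, nrow(raw))
  }
  strand <- if ("strand" %in% names(raw)) raw$strand else rep("*", nrow(raw))
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  evidence <- if ("evidence" %in% names(raw)) raw$evidence else
    rep("insilico_cleavage", nrow(raw))
  known <- c("empirical_cleavage", "empirical_editing",
             "insilico_cleavage", "insilico_editing")
  bad_ev <- which(!evidence %in% known)
  if (length(bad_ev) > 0) {
    stop("unknown evidence kind in row(s): ", paste(bad_ev, collapse = ", "),
         call. = FALSE)
  }
  abundance <- if ("abundance" %in% names(raw)) {
    suppressWarnings(as.integer(ifelse(raw$abundance == ".", NA,
                                       raw$abundance)))
  } else {
    rep(NA_integer_, nrow(raw))
  }
  if (any(!is.na(abundance) & evidence != "empirical_cleavage")) {
    stop("abundance is only meaningful for empirical_cleavage records",
         call. = FALSE)
  }
  tibble(
    source = raw$source, sample = raw$sample, chrom = raw$chrom,
    start = start, end = start + 1L, strand = strand,
    score = score, evidence = evidence, abundance = abundance
  )
}

empty_records <- function() {
  tibble(
    source = character(), sample = character(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    score = double(), evidence = character(), abundance = integer()
  )
}

#' Write a nomination table
#'
#' Inverse of [read_nomination_table()]: positions are emitted in the
#' requested dialect and missing scores/abundances as `.`, so that a
#' write/read round trip reproduces the records exactly.
#'
#' @param records tibble of cut-site records.
#' @param path output path.
#' @inheritParams read_nomination_table
#' @return `path`, invisibly.
#' @export
write_nomination_table <- function(records, path,
                                   dialect = c("1-based", "0-based")) {
  dialect <- match.arg(dialect)
  pos <- if (dialect == "1-based") records$start + 1L else records$start
  out <- tibble(
    source = records$source, sample = records$sample, chrom = records$chrom,
    position = pos, strand = records$strand,
    score = ifelse(is.na(records$score), ".",
                   formatC(records$score, format = "g", digits = 15)),
    evidence = records$evidence,
    abundance = ifelse(is.na(records$abundance), ".",
                       as.character(records$abundance))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read feature intervals from BED or GFF3
#'
#' Feature sets (exons, introns, oncogenes, arbitrary user features) are used
#' to annotate candidate sites. BED input is consumed natively (0-based
#' half-open); GFF3 features (1-based inclusive) are shifted into the internal
#' convention on read. Overlapping intervals are deliberately kept unmerged.
#'
#' @param path BED or GFF3 file; format taken from the extension unless
#'   `format` is given.
#' @param label feature label attached to every interval (e.g. `"exon"`,
#'   `"oncogene"`).
#' @param format `"bed"`, `"gff3"` or `NULL` to infer from the file name.
#' @return a tibble with columns `label`, `chrom`, `start`, `end`, sorted by
#'   `(chrom, start)`.
#' @export
read_feature_intervals <- function(path, label, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
      "gff3"
    } else {
      "bed"
    }
  }
  format <- match.arg(format, c("bed", "gff3"))
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) {
      stop("cannot parse ", path, " as ", format, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  # GRanges is 1-based inclusive for either input format; shift down to the
  # internal 0-based half-open convention.
  tibble(
    label = label,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) |>
    arrange(.data$chrom, .data$start)
}

#' dsODN relative abundances for one sample
#'
#' For dsODN-marking assays the number of independent adaptor (shear)
#' positions counts the cells sampled at each integration site. Site usage is
#' expressed relative to the on-target site: each distinct site's summed
#' abundance divided by the on-target site's summed abundance, so the
#' on-target site maps to exactly 1.
#'
#' @param records cut-site records for a single sample; every record must
#'   carry an `abundance`.
#' @param on_target a [genomic_interval()] covering the on-target cut site.
#' @return a tibble with one row per distinct site: `chrom`, `start`, `end`,
#'   `abundance`, `rel_abundance`, flagged `is_on_target`.
#' @export
relative_abundance <- function(records, on_target) {
  if (nrow(records) == 0) stop("no records supplied", call. = FALSE)
  if (any(is.na(records$abundance))) {
    stop("all records must carry an abundance", call. = FALSE)
  }
  sites <- records |>
    group_by(.data$chrom, .data$start, .data$end) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    mutate(is_on_target = .data$chrom == on_target$chrom &
             .data$start < on_target$end & .data$end > on_target$start)
  if (!any(sites$is_on_target)) {
    stop("no record overlaps the on-target site", call. = FALSE)
  }
  on_ab <- sum(sites$abundance[sites$is_on_target])
  if (on_ab == 0) {
    stop("on-target abundance is zero; relative abundance undefined",
         call. = FALSE)
  }
  sites |>
    mutate(rel_abundance = .data$abundance / on_ab) |>
    arrange(desc(.data$rel_abundance))
}
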