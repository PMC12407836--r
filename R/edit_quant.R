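#' Read a per-position pileup table
#'
#' The pileup TSV (`chrom pos ref A C G T`, tab-separated, `pos` 1-based as
#' in samtools) is accepted as a first-class alternative to BAM input so edit
#' quantification is testable without alignment tooling.
#'
#' @param path pileup TSV path.
#' @return tibble with columns `chrom`, `pos` (1-based), `ref`, `A`, `C`,
#'   `G`, `T`.
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), A = readr::col_integer(),
      C = readr::col_integer(), G = readr::col_integer(),
      T = readr::col_integer()
    ),
    progress = FALSE
  )
}

#' @rdname read_pileup
#' @param pileup pileup tibble.
#' @export
write_pileup <- function(pileup, path) {
  readr::write_tsv(pileup, path, progress = FALSE)
  invisible(path)
}

#' Per-position base frequencies at a protospacer
#'
#' Counts A/C/G/T at every protospacer position from either a pileup tibble
#' (see [read_pileup()]) or a coordinate-sorted, indexed BAM file. Positions
#' are reported in spacer orientation (position 0 = 5' end of the spacer);
#' reverse-strand sites are complemented so the profile reads 5'->3' along
#' the spacer. For BAM input, bases below `min_base_quality` are excluded,
#' deletions are skipped and insertions ignored, and a `reference` is
#' required to supply per-position reference bases.
#'
#' @param x pileup tibble or path to a BAM file.
#' @param site a [genomic_interval()] for the protospacer (strand `+`/`-`).
#' @param min_base_quality minimum base quality for BAM input (default 20).
#' @param reference `DNAStringSet` or FASTA path (BAM input only).
#' @return an object of class `base_edit_profile`: tibble with `position`
#'   (0-based spacer index), `gpos` (0-based genomic), `ref`, `A`, `C`, `G`,
#'   `T`, `coverage`; the site is attached as attribute `site`.
#' @export
base_frequencies <- function(x, site, min_base_quality = 20,
                             reference = NULL) {
  stopifnot(inherits(site, "genomic_interval"))
  if (!site$strand %in% c("+", "-")) {
    stop("site strand must be '+' or '-'", call. = FALSE)
  }
  if (is.character(x) && length(x) == 1) {
    pile <- pileup_from_bam(x, site, min_base_quality, reference)
  } else {
    pile <- x
    if (!all(c("chrom", "pos", "ref", DNA_BASES) %in% names(pile))) {
      stop("pileup must have columns chrom pos ref A C G T", call. = FALSE)
    }
    if (!site$chrom %in% pile$chrom) {
      stop("contig not covered by pileup: ", site$chrom, call. = FALSE)
    }
  }
  L <- site$end - site$start
  gpos <- if (site$strand == "+") {
    site$start + seq_len(L) - 1L
  } else {
    site$end - seq_len(L)
  }
  idx <- match(paste(site$chrom, gpos + 1L), paste(pile$chrom, pile$pos))
  counts <- matrix(0L, nrow = L, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
  ref <- rep(NA_character_, L)
  hit <- !is.na(idx)
  if (any(hit)) {
    counts[hit, ] <- as.matrix(pile[idx[hit], DNA_BASES])
    ref[hit] <- toupper(pile$ref[idx[hit]])
  }
  if (site$strand == "-") {
    counts <- counts[, c("T", "G", "C", "A"), drop = FALSE]
    colnames(counts) <- DNA_BASES
    ref <- ifelse(is.na(ref), NA, complement_base(ref))
  }
  prof <- tibble(
    position = seq_len(L) - 1L, gpos = gpos, ref = ref,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
    T = counts[, "T"]
  ) |>
    mutate(coverage = .data$A + .data$C + .data$G + .data$T)
  structure(prof, site = site, class = c("base_edit_profile",
                                         class(prof)))
}

pileup_from_bam <- function(bam, site, min_base_quality, reference) {
  if (is.null(reference)) {
    stop("BAM input requires a reference to supply reference bases",
         call. = FALSE)
  }
  ref <- load_reference(reference)
  bf <- Rsamtools::BamFile(bam)
  hdr_contigs <- names(Rsamtools::scanBamHeader(bf)$targets)
  if (!site$chrom %in% hdr_contigs) {
    stop("contig not present in BAM: ", site$chrom, call. = FALSE)
  }
  which <- GenomicRanges::GRanges(
    site$chrom, IRanges::IRanges(site$start + 1L, site$end)
  )
  res <- Rsamtools::pileup(
    bf,
    scanBamParam = Rsamtools::ScanBamParam(which = which),
    pileupParam = Rsamtools::PileupParam(
      max_depth = 1e6, min_base_quality = min_base_quality,
      min_mapq = 0, min_nucleotide_depth = 0,
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      include_deletions = FALSE, include_insertions = FALSE
    )
  )
  pos <- (site$start + 1L):site$end
  refseq <- strsplit(toupper(as.character(
    Biostrings::subseq(ref[[site$chrom]], site$start + 1L, site$end)
  )), "")[[1]]
  out <- tibble(chrom = site$chrom, pos = pos, ref = refseq,
                A = 0L, C = 0L, G = 0L, T = 0L)
  for (b in DNA_BASES) {
    sel <- res$nucleotide == b
    if (any(sel)) {
      i <- match(res$pos[sel], out$pos)
      keep <- !is.na(i)
      out[[b]][i[keep]] <- as.integer(res$count[sel][keep])
    }
  }
  out
}

parse_edit <- function(edit) {
  if (is.character(edit) && length(edit) == 1) {
    edit <- toupper(strsplit(edit, ">", fixed = TRUE)[[1]])
  }
  edit <- toupper(edit)
  if (length(edit) != 2 || !all(edit %in% DNA_BASES) || edit[1] == edit[2]) {
    stop("expected edit must be two distinct bases, e.g. \"A>G\"",
         call. = FALSE)
  }
  edit
}

#' Call the expected base edit on a profile
#'
#' Eligible positions are those whose reference base (in spacer orientation)
#' equals the edit's source base, with coverage at or above `min_coverage`
#' and not SNP-masked. The per-position edit frequency is the destination
#' base count over coverage, and the site is called edited iff any eligible
#' frequency reaches `threshold` (inclusive, i.e. exactly 5% counts at the
#' default threshold).
#'
#' @param profile a [base_frequencies()] profile.
#' @param expected_edit the programmed conversion, e.g. `"A>G"` for ABE8e.
#' @param threshold edit-frequency call threshold in (0, 1] (default 0.05).
#' @param min_coverage minimum per-position coverage (default 20).
#' @param masked integer vector of 0-based positions excluded as SNPs.
#' @return an object of class `edit_call`: list with the per-position
#'   `table` (`position`, `ref`, `coverage`, `masked`, `eligible`,
#'   `edit_freq`), `site_edited`, `no_eligible`, and the parameters used.
#' @export
call_edits <- function(profile, expected_edit, threshold = 0.05,
                       min_coverage = 20, masked = integer(0)) {
  edit <- parse_edit(expected_edit)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  tab <- tibble(
    position = profile$position,
    ref = profile$ref,
    coverage = profile$coverage,
    masked = profile$position %in% masked,
    dest_count = profile[[edit[2]]]
  ) |>
    mutate(
      eligible = !is.na(.data$ref) & .data$ref == edit[1] &
        .data$coverage >= min_coverage & !.data$masked,
      edit_freq = ifelse(.data$eligible,
                         .data$dest_count / .data$coverage, NA_real_)
    ) |>
    select(-"dest_count")
  no_eligible <- !any(tab$eligible)
  structure(
    list(
      site = attr(profile, "site"), table = tab,
      site_edited = !no_eligible &&
        any(tab$edit_freq[tab$eligible] >= threshold),
      no_eligible = no_eligible,
      expected_edit = paste(edit, collapse = ">"),
      threshold = threshold, min_coverage = min_coverage
    ),
    class = "edit_call"
  )
}

#' @export
print.edit_call <- function(x, ...) {
  s <- x$site
  cat(sprintf("<edit_call %s:%d-%d(%s) %s %s>\n", s$chrom, s$start, s$end,
              s$strand, x$expected_edit,
              if (x$site_edited) "EDITED" else "not edited"))
  invisible(x)
}

#' Identify SNP-masked positions from no-editor controls
#'
#' Germline variants that coincide with the programmed conversion would be
#' miscalled as edits. A position is masked iff any control (no-editor)
#' sample shows the expected destination base at `snp_threshold` frequency
#' or higher with adequate coverage.
#'
#' @param control_profiles list of [base_frequencies()] profiles of the same
#'   site from no-editor control samples.
#' @param expected_edit programmed conversion, e.g. `"A>G"`.
#' @param snp_threshold control destination-base frequency at or above which
#'   a position is masked (default 0.05).
#' @param min_coverage minimum control coverage for masking (default 20).
#' @return sorted integer vector of masked 0-based positions.
#' @export
mask_snps <- function(control_profiles, expected_edit, snp_threshold = 0.05,
                      min_coverage = 20) {
  edit <- parse_edit(expected_edit)
  if (length(control_profiles) == 0) {
    warning("no control profiles supplied; site processed unmasked")
    return(integer(0))
  }
  masked <- integer(0)
  for (prof in control_profiles) {
    freq <- ifelse(prof$coverage > 0, prof[[edit[2]]] / prof$coverage, 0)
    hit <- !is.na(prof$ref) & prof$ref == edit[1] &
      prof$coverage >= min_coverage & freq >= snp_threshold
    masked <- union(masked, prof$position[hit])
  }
  sort(masked)
}

#' Build a replicate-supported truth set of edited loci
#'
#' A locus enters the truth set iff the expected edit was called (at
#' `min_freq`, after SNP masking) in at least `min_replicates` replicate
#' samples.
#'
#' @param calls tidy tibble with one row per (site, replicate): columns
#'   `site`, `replicate`, `edited` (logical). Convenient to build with
#'   [call_edits()] over per-replicate profiles.
#' @param min_freq edit-frequency rule recorded on the truth set
#'   (default 0.05); calls are assumed to have been made at this threshold.
#' @param min_replicates minimum supporting replicates (default 3).
#' @return an object of class `truth_set`: list with `loci` (character
#'   vector), `support` (tibble site/n_edited), and rule parameters.
#' @export
build_truth_set <- function(calls, min_freq = 0.05, min_replicates = 3) {
  stopifnot(all(c("site", "replicate", "edited") %in% names(calls)))
  n_rep <- length(unique(calls$replicate))
  if (n_rep < min_replicates) {
    stop("need at least ", min_replicates, " replicates, got ", n_rep,
         call. = FALSE)
  }
  support <- calls |>
    group_by(.data$site) |>
    summarise(n_edited = sum(.data$edited), .groups = "drop")
  structure(
    list(
      loci = sort(support$site[support$n_edited >= min_replicates]),
      support = support,
      min_freq = min_freq, min_replicates = min_replicates,
      replicates = sort(unique(calls$replicate))
    ),
    class = "truth_set"
  )
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "<truth_set: %d locus/loci (>=%.0f%% edit in >=%d of %d replicates)>\n",
    length(x$loci), 100 * x$min_freq, x$min_replicates,
    length(x$replicates)))
  invisible(x)
}

#' Write a per-site edit table
#'
#' @param calls list of `edit_call` objects named by site id.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edit_table <- function(calls, path) {
  rows <- lapply(names(calls), function(id) {
    x <- calls[[id]]
    s <- x$site
    x$table |>
      mutate(site = id, chrom = s$chrom, start = s$start, end = s$end,
             strand = s$strand, site_edited = x$site_edited) |>
      select("site", "chrom", "start", "end", "strand", "position",
             ref_base = "ref", "edit_freq", "coverage", "masked",
             "site_edited")
  })
  readr::write_tsv(bind_rows(rows), path, progress = FALSE)
  invisible(path)
}
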