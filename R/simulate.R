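#' Simulation configuration with planted ground truth
#'
#' Defines a seeded synthetic study: a random reference, planted on/off-target
#' protospacers with known mismatch/bulge structure, a panel of heterogeneous
#' nomination tools (empirical dsODN-marking plus in-silico cleavage and
#' base-editing predictors, three of them rank-less), and per-replicate
#' aligned-read pileups with planted edit frequencies and germline SNPs.
#'
#' The default study emulates a single-guide adenine-base-editor experiment:
#' one on-target site with strong editing concentrated in the activity window
#' (the targeted A at protospacer position 6, detectable conversion at A4 and
#' A10), two hot off-target sites, and a tail of weaker sites with mixed
#' empirical/in-silico support. dsODN abundances follow the steep on-target
#' dominance seen in marking assays, and in-silico tools differ in detection
#' probability, positional jitter and false-positive load.
#'
#' @param seed integer seed; fully determines all simulated outputs.
#' @param contig_length length of the single simulated contig (default
#'   20000 bp).
#' @param contig contig name.
#' @param spacer,pam guide used for planting (defaults: a 20-nt spacer with
#'   adenines at positions 4, 6 and 10; NGG).
#' @param sites tibble of planted sites (`site_id`, `strand`, `mismatches`,
#'   `dna_bulges`, `rna_bulges`, `abundance`, `is_on_target`, list-column
#'   `edit_freq` of per-spacer-position frequencies); `NULL` for the default
#'   eight-site layout.
#' @param tools tibble of nomination sources (`source_id`, `evidence`,
#'   `detection_prob`, `jitter_sd`, `fp_rate`, `score_noise`,
#'   `reports_scores`); `NULL` for the default thirteen-source panel.
#' @param mean_depth mean per-position sequencing depth (default 400).
#' @param n_replicates,n_controls editor-treated replicates and no-editor
#'   controls (defaults 5 and 2).
#' @param snp_sites tibble (`site_id`, `position`, `freq`) of germline SNP
#'   positions carrying the destination base in cases *and* controls.
#' @param expected_edit programmed conversion (default `"A>G"`).
#' @param flank alignment window flank; planted sites are separated by more
#'   than `2 * flank` so windows never overlap.
#' @param noise_free if `TRUE`, all detection probabilities become 1 and all
#'   jitter, false-positive and score-noise terms 0 (closed-loop testing).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       contig_length = 20000,
                       contig = "chr_sim",
                       spacer = "GCTGACAGTCAGCTGCTGCT",
                       pam = "NGG",
                       sites = NULL,
                       tools = NULL,
                       mean_depth = 400,
                       n_replicates = 5,
                       n_controls = 2,
                       snp_sites = NULL,
                       expected_edit = "A>G",
                       flank = 50,
                       noise_free = FALSE) {
  spacer <- assert_dna(spacer, "spacer")
  m <- nchar(spacer)
  if (is.null(sites)) sites <- default_sites(m)
  if (is.null(tools)) tools <- default_tools()
  if (is.null(snp_sites)) {
    # heterozygous germline A>G at the targeted position of an unedited
    # site: looks like a strong edit in cases until control-masked
    snp_sites <- tibble(site_id = "off_rare", position = 6L, freq = 0.5)
  }
  if (noise_free) {
    tools$detection_prob <- 1
    tools$jitter_sd <- 0
    tools$fp_rate <- 0
    tools$score_noise <- 0
    snp_sites <- snp_sites[0, , drop = FALSE]
  }
  bad <- vapply(seq_len(nrow(sites)), function(i) {
    (sites$dna_bulges[i] > 0 || sites$rna_bulges[i] > 0) &&
      any(sites$edit_freq[[i]] > 0)
  }, logical(1))
  if (any(bad)) {
    stop("bulged planted sites must carry zero edit frequency ",
         "(per-position bookkeeping assumes a colinear protospacer)",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), contig_length = as.integer(contig_length),
         contig = contig, spacer = spacer, pam = pam, sites = sites,
         tools = tools, mean_depth = mean_depth,
         n_replicates = as.integer(n_replicates),
         n_controls = as.integer(n_controls), snp_sites = snp_sites,
         expected_edit = expected_edit, flank = as.integer(flank),
         noise_free = noise_free),
    class = "sim_config"
  )
}

default_sites <- function(m) {
  freq <- function(...) {
    v <- numeric(m)
    args <- list(...)
    for (nm in names(args)) v[as.integer(nm) + 1L] <- args[[nm]]
    list(v)
  }
  tibble(
    site_id = c("on_target", "off_hot1", "off_hot2", "off_multi1",
                "off_multi2", "off_bulge", "off_rare", "off_silent"),
    strand = c("+", "+", "-", "+", "-", "+", "-", "+"),
    mismatches = c(0L, 1L, 2L, 3L, 3L, 2L, 4L, 4L),
    dna_bulges = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L),
    rna_bulges = c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
    abundance = c(500L, 180L, 60L, 0L, 0L, 10L, 2L, 0L),
    is_on_target = c(TRUE, rep(FALSE, 7)),
    edit_freq = c(freq(`6` = 0.80, `4` = 0.15, `10` = 0.10),
                  freq(`6` = 0.56, `4` = 0.08),
                  freq(`6` = 0.21),
                  freq(`6` = 0.08),
                  freq(), freq(), freq(), freq())
  )
}

default_tools <- function() {
  bind_rows(
    tibble(source_id = "dsodn", evidence = "empirical_cleavage",
           detection_prob = 1, jitter_sd = 1, fp_rate = 1,
           score_noise = 0, reports_scores = FALSE),
    tibble(
      source_id = paste0("cut_tool_", 1:10),
      evidence = "insilico_cleavage",
      detection_prob = c(1, 1, 1, 0.9, 0.9, 0.8, 0.8, 0.7, 0.6, 0.5),
      jitter_sd = c(0, 0, 1, 1, 2, 2, 2, 3, 3, 3),
      fp_rate = c(2, 3, 5, 8, 10, 12, 15, 20, 30, 40),
      score_noise = 0.1,
      # the first three tools emit no relative ranking
      reports_scores = c(FALSE, FALSE, FALSE, rep(TRUE, 7))
    ),
    tibble(source_id = c("edit_tool_1", "edit_tool_2"),
           evidence = "insilico_editing",
           detection_prob = c(0.9, 0.8), jitter_sd = c(1, 1),
           fp_rate = c(3, 12), score_noise = 0.1, reports_scores = TRUE)
  )
}

#' Simulate the reference and planted ground-truth sites
#'
#' Generates a uniform-i.i.d. background contig and writes each planted
#' protospacer into it with exactly the configured number of mismatches, DNA
#' bulges (extra genomic base) and RNA bulges (missing genomic base) relative
#' to the spacer, followed by a concrete PAM. Sites are evenly spaced so
#' alignment windows never overlap.
#'
#' @param config a [sim_config()].
#' @return list with `reference` (`DNAStringSet`) and `truth` (tibble:
#'   `site_id`, `chrom`, `start`, `end`, `strand`, `cut`, `mismatches`,
#'   `dna_bulges`, `rna_bulges`, `abundance`, `is_on_target`, list-columns
#'   `edit_freq` and `proto_seq`).
#' @export
simulate_reference_and_sites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- nchar(config$spacer)
  n_sites <- nrow(config$sites)
  spacing <- config$contig_length %/% (n_sites + 1)
  min_space <- 2 * config$flank + m + nchar(config$pam) + 10
  if (spacing < min_space) {
    stop("contig too short to fit ", n_sites, " non-overlapping sites",
         call. = FALSE)
  }
  background <- sample(DNA_BASES, config$contig_length, replace = TRUE)
  spacer_chars <- strsplit(config$spacer, "")[[1]]
  query <- spacer_query(config$spacer, config$pam)
  rows <- list()
  for (i in seq_len(n_sites)) {
    st <- config$sites[i, ]
    pos <- spacing * i  # 0-based placement of the block
    # rejection-sample the planted structure until, in its real window
    # context, the aligner recovers exactly the configured mismatch/bulge
    # counts and interval — i.e. the planted alignment is the unambiguous
    # optimum under the default scoring
    # spacer positions carrying planted edits or SNPs must keep their
    # reference base, so they are protected from mismatch/bulge planting
    protect <- sort(unique(c(
      which(st$edit_freq[[1]] > 0),
      config$snp_sites$position[config$snp_sites$site_id == st$site_id] + 1L
    )))
    placed_ok <- FALSE
    for (attempt in 1:50) {
      built <- build_protospacer(spacer_chars, st$mismatches, st$dna_bulges,
                                 st$rna_bulges, config$pam,
                                 protect = protect)
      block <- c(built$core, built$pam)
      if (st$strand == "+") {
        placed <- block
        proto_start <- pos
        proto_end <- pos + length(built$core)
        cut <- proto_end - 3L
      } else {
        placed <- strsplit(revcomp(paste(block, collapse = "")), "")[[1]]
        proto_start <- pos + length(built$pam)
        proto_end <- pos + length(block)
        cut <- proto_start + 3L
      }
      trial <- background
      trial[(pos + 1):(pos + length(placed))] <- placed
      wstart <- max(0L, cut - config$flank)
      wend <- min(config$contig_length, cut + config$flank)
      win <- list(seq = paste(trial[(wstart + 1):wend], collapse = ""),
                  chrom = config$contig, start = wstart, end = wend)
      aln <- align_spacer(query, win)
      if (aln$start == proto_start && aln$end == proto_end &&
          aln$strand == st$strand &&
          aln$mismatches == st$mismatches &&
          aln$dna_bulges == st$dna_bulges &&
          aln$rna_bulges == st$rna_bulges) {
        background <- trial
        placed_ok <- TRUE
        break
      }
    }
    if (!placed_ok) {
      stop("could not plant site ", st$site_id,
           " with an unambiguous structure", call. = FALSE)
    }
    rows[[i]] <- tibble(
      site_id = st$site_id, chrom = config$contig,
      start = as.integer(proto_start), end = as.integer(proto_end),
      strand = st$strand, cut = as.integer(cut),
      mismatches = st$mismatches, dna_bulges = st$dna_bulges,
      rna_bulges = st$rna_bulges, abundance = st$abundance,
      is_on_target = st$is_on_target,
      edit_freq = list(effective_edit_freq(st$edit_freq[[1]], built$core,
                                           config$expected_edit)),
      proto_seq = list(paste(built$core, collapse = ""))
    )
  }
  ref <- Biostrings::DNAStringSet(paste(background, collapse = ""))
  names(ref) <- config$contig
  list(reference = ref, truth = bind_rows(rows))
}

# Build one protospacer: mismatches at interior positions kept clear of
# bulge edits; DNA bulge = inserted genomic base, RNA bulge = deleted
# genomic base. Returns core (char vector, genomic, spacer orientation) and
# a concrete PAM realization.
build_protospacer <- function(spacer_chars, n_mm, n_dna, n_rna, pam,
                              protect = integer(0)) {
  m <- length(spacer_chars)
  interior <- setdiff(2:(m - 1), protect)
  # bulges are planted centrally: an edge-proximal bulge can be absorbed as
  # one or two mismatches at equal alignment score, making the planted
  # structure unrecoverable
  central <- max(2, m %/% 2 - 3):min(m - 2, m %/% 2 + 3)
  rna_pos <- if (n_rna > 0) sort(sample(central, n_rna)) else integer(0)
  mm_pool <- setdiff(interior, c(rna_pos - 1, rna_pos, rna_pos + 1))
  mm_pos <- if (n_mm > 0) sort(sample(mm_pool, n_mm)) else integer(0)
  core <- spacer_chars
  for (p in mm_pos) {
    core[p] <- sample(setdiff(DNA_BASES, spacer_chars[p]), 1)
  }
  if (n_rna > 0) core <- core[-rna_pos]
  if (n_dna > 0) {
    ins_after <- sort(sample(central, n_dna))
    for (k in rev(ins_after)) {
      core <- append(core, sample(DNA_BASES, 1), after = k)
    }
  }
  pam_chars <- strsplit(toupper(pam), "")[[1]]
  pam_real <- vapply(pam_chars, function(code) {
    allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[code]], "")[[1]]
    if (length(allowed) == 1) allowed else sample(allowed, 1)
  }, character(1))
  list(core = core, pam = unname(pam_real))
}

# Zero out planted edit frequencies wherever the realized genomic base (in
# spacer orientation) is not the edit's source base.
effective_edit_freq <- function(freq, core, expected_edit) {
  edit <- parse_edit(expected_edit)
  if (length(freq) != length(core)) freq <- freq[seq_along(core)]
  ifelse(core == edit[1], freq, 0)
}

#' Simulate per-tool nomination tables
#'
#' Each tool detects each eligible true site with its detection probability
#' (empirical sources see only dsODN-marked sites, in-silico editing
#' predictors only sites with non-zero planted editing), jitters the
#' reported cut position by a rounded Gaussian, adds Poisson false positives
#' at random loci, and emits scores with configured noise (or none for
#' rank-less tools). True-site scores decrease with mismatch/bulge load.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_reference_and_sites()].
#' @param dir optional directory; per-source nomination TSVs (1-based) are
#'   written there.
#' @return tibble of nomination records in the internal convention.
#' @export
simulate_nomination_tables <- function(config, truth, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  recs <- list()
  for (i in seq_len(nrow(config$tools))) {
    tl <- config$tools[i, ]
    eligible <- switch(
      tl$evidence,
      empirical_cleavage = truth[truth$abundance > 0, ],
      empirical_editing = ,
      insilico_editing = truth[vapply(truth$edit_freq, max, 0) > 0, ],
      truth
    )
    detected <- eligible[stats::runif(nrow(eligible)) <= tl$detection_prob, ]
    n_fp <- stats::rpois(1, tl$fp_rate)
    sample_id <- if (grepl("^empirical", tl$evidence)) "donor1" else
      "insilico"
    if (nrow(detected) > 0) {
      pos <- detected$cut +
        as.integer(round(rnorm(nrow(detected), 0, tl$jitter_sd)))
      score <- if (tl$reports_scores) {
        pmax(0.05, 1 - 0.2 * (detected$mismatches + detected$dna_bulges +
                                detected$rna_bulges)) +
          rnorm(nrow(detected), 0, tl$score_noise)
      } else {
        rep(NA_real_, nrow(detected))
      }
      recs[[length(recs) + 1]] <- tibble(
        source = tl$source_id, sample = sample_id, chrom = detected$chrom,
        start = pos, end = pos + 1L, strand = "*", score = score,
        evidence = tl$evidence,
        abundance = if (tl$evidence == "empirical_cleavage") {
          detected$abundance
        } else {
          NA_integer_
        }
      )
    }
    if (n_fp > 0) {
      fpos <- as.integer(sample.int(config$contig_length - 1L, n_fp))
      recs[[length(recs) + 1]] <- tibble(
        source = tl$source_id, sample = sample_id, chrom = config$contig,
        start = fpos, end = fpos + 1L, strand = "*",
        score = if (tl$reports_scores) {
          abs(rnorm(n_fp, 0, 0.1))
        } else {
          NA_real_
        },
        evidence = tl$evidence,
        abundance = if (tl$evidence == "empirical_cleavage") {
          1L
        } else {
          NA_integer_
        }
      )
    }
  }
  records <- bind_rows(recs)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (src in unique(records$source)) {
      write_nomination_table(
        records[records$source == src, ],
        file.path(dir, paste0(src, ".nominations.tsv"))
      )
    }
  }
  records
}

#' Simulate per-sample edit pileups
#'
#' Case replicates draw destination-base counts binomially at each planted
#' per-position edit frequency; no-editor controls carry zero edit signal.
#' Configured germline SNP positions carry the destination base in cases
#' *and* controls at the configured allele frequency, so they are removable
#' only by control-based masking. Coverage is Poisson around `mean_depth`.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_reference_and_sites()].
#' @param reference the simulated `DNAStringSet`.
#' @param dir optional directory for per-sample pileup TSVs.
#' @return named list of pileup tibbles (`rep_1..n`, `control_1..m`).
#' @export
simulate_edit_pileups <- function(config, truth, reference, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  edit <- parse_edit(config$expected_edit)
  samples <- c(paste0("rep_", seq_len(config$n_replicates)),
               paste0("control_", seq_len(config$n_controls)))
  site_ref <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    fwd <- strsplit(toupper(as.character(
      Biostrings::subseq(reference[[tr$chrom]], tr$start + 1L, tr$end)
    )), "")[[1]]
    if (tr$strand == "+") fwd else rev(fwd)
  })
  out <- list()
  for (smp in samples) {
    is_control <- grepl("^control_", smp)
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      L <- tr$end - tr$start
      gpos <- if (tr$strand == "+") tr$start + seq_len(L) - 1L else
        tr$end - seq_len(L)
      refbase <- site_ref[[i]]
      freq <- if (is_control) numeric(L) else tr$edit_freq[[1]]
      snp <- config$snp_sites[config$snp_sites$site_id == tr$site_id, ]
      if (nrow(snp) > 0) {
        for (j in seq_len(nrow(snp))) {
          p <- snp$position[j] + 1L
          if (p <= L) freq[p] <- min(1, freq[p] + snp$freq[j])
        }
      }
      cov <- stats::rpois(L, config$mean_depth)
      alt <- rbinom(L, cov, freq)
      counts <- matrix(0L, nrow = L, ncol = 4,
                       dimnames = list(NULL, DNA_BASES))
      # counts in spacer orientation, then flip to genomic for the pileup
      ref_spacer <- if (tr$strand == "+") refbase else
        complement_base(refbase)
      dest_spacer <- edit[2]
      for (p in seq_len(L)) {
        counts[p, ref_spacer[p]] <- cov[p] - alt[p]
        counts[p, dest_spacer] <- counts[p, dest_spacer] + alt[p]
      }
      if (tr$strand == "-") {
        counts <- counts[, c("T", "G", "C", "A"), drop = FALSE]
        colnames(counts) <- DNA_BASES
      }
      rows[[i]] <- tibble(
        chrom = tr$chrom, pos = gpos + 1L, ref = refbase,
        A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
        T = counts[, "T"]
      )
    }
    pile <- bind_rows(rows) |> arrange(.data$chrom, .data$pos)
    out[[smp]] <- pile
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (smp in names(out)) {
      write_pileup(out[[smp]], file.path(dir, paste0(smp, ".pileup.tsv")))
    }
  }
  out
}

#' Emit a small SAM file of reads covering one site
#'
#' Generates `depth` full-length reads spanning the protospacer, each base
#' drawn independently at the planted per-position edit frequency, and
#' writes them as plain-text SAM (convertible with [Rsamtools::asBam()]).
#' The exact per-position counts realized in the emitted reads are returned
#' so BAM-path quantification can be checked against them.
#'
#' @param site a [genomic_interval()].
#' @param reference `DNAStringSet` covering the site.
#' @param edit_freq per-position destination-base frequency (spacer
#'   orientation, length `end - start`).
#' @param expected_edit programmed conversion, e.g. `"A>G"`.
#' @param depth number of reads.
#' @param path output SAM path.
#' @return list with `path` and `counts` (per-position tibble in genomic
#'   orientation: `chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`).
#' @export
simulate_site_sam <- function(site, reference, edit_freq, expected_edit,
                              depth, path) {
  edit <- parse_edit(expected_edit)
  L <- site$end - site$start
  stopifnot(length(edit_freq) == L, depth > 0)
  refseq <- strsplit(toupper(as.character(
    Biostrings::subseq(reference[[site$chrom]], site$start + 1L, site$end)
  )), "")[[1]]
  # edit_freq is in spacer orientation; flip to genomic order and bases
  if (site$strand == "-") {
    freq_gen <- rev(edit_freq)
    dest_gen <- complement_base(edit[2])
    src_gen <- complement_base(edit[1])
  } else {
    freq_gen <- edit_freq
    dest_gen <- edit[2]
    src_gen <- edit[1]
  }
  freq_gen[refseq != src_gen] <- 0
  base_mat <- matrix(rep(refseq, depth), nrow = L)
  for (p in seq_len(L)) {
    if (freq_gen[p] > 0) {
      hit <- stats::runif(depth) < freq_gen[p]
      base_mat[p, hit] <- dest_gen
    }
  }
  counts <- t(apply(base_mat, 1, function(b) {
    tabulate(match(b, DNA_BASES), 4)
  }))
  colnames(counts) <- DNA_BASES
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", site$chrom, "\tLN:",
           Biostrings::width(reference[site$chrom]))
  )
  qual <- paste(rep("I", L), collapse = "")
  reads <- vapply(seq_len(depth), function(j) {
    paste(paste0("read_", j), 0, site$chrom, site$start + 1L, 60,
          paste0(L, "M"), "*", 0, 0,
          paste(base_mat[, j], collapse = ""), qual, sep = "\t")
  }, character(1))
  writeLines(c(header, reads), path)
  list(
    path = path,
    counts = tibble(chrom = site$chrom,
                    pos = site$start + seq_len(L), ref = refseq,
                    A = counts[, "A"], C = counts[, "C"],
                    G = counts[, "G"], T = counts[, "T"])
  )
}
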