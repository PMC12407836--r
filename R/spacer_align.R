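#' Describe an sgRNA spacer query
#'
#' @param spacer spacer sequence 5'->3' (typically 20 nt, minimum 10),
#'   A/C/G/T only.
#' @param pam IUPAC PAM pattern (default `"NGG"` for SpCas9).
#' @param pam_side side of the protospacer carrying the PAM.
#' @return an object of class `spacer_query`.
#' @export
spacer_query <- function(spacer, pam = "NGG",
                         pam_side = c("3prime", "5prime")) {
  spacer <- assert_dna(spacer, "spacer")
  if (nchar(spacer) < 10) {
    stop("spacer must be at least 10 nt", call. = FALSE)
  }
  pam <- toupper(pam)
  if (grepl(paste0("[^", paste(names(Biostrings::IUPAC_CODE_MAP),
                               collapse = ""), "]"), pam)) {
    stop("pam must be an IUPAC nucleotide pattern", call. = FALSE)
  }
  structure(
    list(spacer = spacer, pam = pam, pam_side = match.arg(pam_side)),
    class = "spacer_query"
  )
}

#' Alignment scoring parameters
#'
#' Defaults prefer PAM-adjacent placements (bonus `+3`) while still admitting
#' a PAM-less best hit when it is substantially better at the base level.
#' Bulges are capped because larger heteroduplex distortions are not credible
#' protospacers.
#'
#' @param match,mismatch,gap per-base scores; `gap` applies per bulged base.
#' @param pam_bonus score bonus for a PAM-adjacent placement.
#' @param max_bulges maximum total gap characters (DNA + RNA bulges).
#' @param require_pam if `TRUE`, only PAM-adjacent placements are accepted.
#' @return a named list of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap = -2, pam_bonus = 3,
                         max_bulges = 2, require_pam = FALSE) {
  stopifnot(max_bulges >= 0, is.logical(require_pam))
  structure(
    list(match = match, mismatch = mismatch, gap = gap,
         pam_bonus = pam_bonus, max_bulges = as.integer(max_bulges),
         require_pam = require_pam),
    class = "align_params"
  )
}

#' Extract the genomic window around a cluster representative
#'
#' Candidate protospacers are re-aligned within a window of up to
#' `2 * flank` bp centred on the representative cut position, clipped to
#' contig bounds.
#'
#' @param reference a `Biostrings::DNAStringSet` or path to a FASTA file.
#' @param chrom contig name (or a cluster row; see [cluster_cut_sites()]).
#' @param representative 0-based cut coordinate.
#' @param flank positive flank size in bp (default 50).
#' @return a list with `seq` (uppercase character), `chrom`, `start`, `end`.
#' @export
extract_window <- function(reference, chrom, representative, flank = 50) {
  if (!is.numeric(flank) || flank <= 0) {
    stop("flank must be positive", call. = FALSE)
  }
  ref <- load_reference(reference)
  if (!chrom %in% names(ref)) {
    stop("contig not found in reference: ", chrom, call. = FALSE)
  }
  len <- Biostrings::width(ref[chrom])
  start <- max(0L, as.integer(representative - flank))
  end <- min(len, as.integer(representative + flank))
  if (start >= end) {
    stop("window is empty: representative ", representative,
         " lies outside contig ", chrom, call. = FALSE)
  }
  seq <- toupper(as.character(
    Biostrings::subseq(ref[[chrom]], start + 1L, end)
  ))
  list(seq = seq, chrom = chrom, start = start, end = end)
}

load_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (!methods::is(reference, "DNAStringSet")) {
    stop("reference must be a DNAStringSet or FASTA path", call. = FALSE)
  }
  reference
}

#' Unit-cost Levenshtein distance
#'
#' Full dynamic-programming edit distance between two nucleotide strings.
#' Used on the ungapped spacer versus the ungapped aligned protospacer
#' (PAM excluded), as a tool-agnostic divergence measure per candidate site.
#'
#' @param a,b character scalars (empty strings allowed).
#' @return integer edit distance.
#' @export
levenshtein_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(
        prev[j + 1] + 1L,
        cur[j] + 1L,
        prev[j] + (av[i] != bv[j])
      )
    }
    prev <- cur
  }
  as.integer(prev[m + 1])
}

# Bulge states: all (d = DNA bulges, r = RNA bulges) with d + r <= max.
bulge_states <- function(max_bulges) {
  out <- list()
  for (d in 0:max_bulges) {
    for (r in 0:(max_bulges - d)) {
      out[[length(out) + 1]] <- c(d = d, r = r)
    }
  }
  # order with d ascending so same-row DNA-bulge transitions read from
  # already-completed states
  out[order(vapply(out, `[`, 0L, "d"), vapply(out, `[`, 0L, "r"))]
}

# Semi-global DP: spacer S end-to-end against window W (both character
# vectors), bulges internal only, gap-count-bounded. Returns the 3-d score
# array D[i+1, j+1, state] where i spacer chars are consumed and W[j] is the
# last consumed window base.
semiglobal_dp <- function(S, W, params) {
  m <- length(S); n <- length(W)
  states <- bulge_states(params$max_bulges)
  ns <- length(states)
  D <- array(-Inf, dim = c(m + 1, n + 1, ns))
  state_index <- function(d, r) {
    for (k in seq_len(ns)) {
      if (states[[k]]["d"] == d && states[[k]]["r"] == r) return(k)
    }
    NA_integer_
  }
  D[1, , 1] <- 0  # i = 0, any j, no gaps: free leading window skip
  for (i in seq_len(m)) {
    sub <- ifelse(S[i] == W, params$match, params$mismatch)  # over j = 1..n
    for (k in seq_len(ns)) {
      d <- states[[k]]["d"]; r <- states[[k]]["r"]
      best <- D[i, 1:n, k] + sub  # diagonal, lands on j = 1..n
      if (r >= 1 && i >= 2 && i <= m - 1) {
        kk <- state_index(d, r - 1)
        best <- pmax(best, D[i, 2:(n + 1), kk] + params$gap)  # RNA bulge
      }
      D[i + 1, 2:(n + 1), k] <- best
      if (d >= 1 && i >= 1 && i <= m - 1) {
        kk <- state_index(d - 1, r)
        # DNA bulge consumes W[j] at the same i; chains of bulges step
        # through states of increasing d, so the kk row is already complete
        D[i + 1, 2:(n + 1), k] <- pmax(D[i + 1, 2:(n + 1), k],
                                       D[i + 1, 1:n, kk] + params$gap)
      }
    }
  }
  list(D = D, states = states)
}

# Reconstruct one optimal path ending at (i = m, window pos j, state k).
# Transition preference (diagonal, then DNA bulge, then RNA bulge) is a
# deterministic tie-break within equal-scoring paths of the same bulge state.
traceback_path <- function(dp, S, W, params, j_end, k_end) {
  D <- dp$D; states <- dp$states
  m <- length(S)
  eps <- 1e-9
  find_state <- function(d, r) {
    which(vapply(states, function(s) s["d"] == d && s["r"] == r, logical(1)))
  }
  i <- m; j <- j_end; k <- k_end
  cols_s <- character(0); cols_w <- character(0)
  while (i > 0) {
    v <- D[i + 1, j + 1, k]
    d <- states[[k]]["d"]; r <- states[[k]]["r"]
    sub <- if (S[i] == W[j]) params$match else params$mismatch
    if (j >= 1 && abs(D[i, j, k] + sub - v) < eps) {
      cols_s <- c(S[i], cols_s); cols_w <- c(W[j], cols_w)
      i <- i - 1; j <- j - 1
    } else if (d >= 1 && i >= 1 && i <= m - 1 && j >= 1 &&
               abs(D[i + 1, j, find_state(d - 1, r)] + params$gap - v) < eps) {
      cols_s <- c("-", cols_s); cols_w <- c(W[j], cols_w)
      k <- find_state(d - 1, r); j <- j - 1
    } else if (r >= 1 && i >= 2 && i <= m - 1 &&
               abs(D[i, j + 1, find_state(d, r - 1)] + params$gap - v) < eps) {
      cols_s <- c(S[i], cols_s); cols_w <- c("-", cols_w)
      k <- find_state(d, r - 1); i <- i - 1
    } else {
      stop("traceback failed (internal error)")
    }
  }
  list(aligned_spacer = paste(cols_s, collapse = ""),
       aligned_window = paste(cols_w, collapse = ""),
       j_start = j + 1,  # first consumed window base (1-based in window)
       mismatches = sum(cols_s != "-" & cols_w != "-" & cols_s != cols_w))
}

# Enumerate optimal candidate placements of spacer S in window sequence Wstr
# for a 3'-PAM query. Returns a list of candidate records with window-local
# coordinates (1-based j_start/j_end of consumed window bases).
candidates_3prime <- function(S, Wstr, pam, params) {
  W <- strsplit(Wstr, "")[[1]]
  m <- length(S); n <- length(W); p <- nchar(pam)
  dp <- semiglobal_dp(S, W, params)
  cands <- list()
  for (k in seq_along(dp$states)) {
    for (j in seq_len(n)) {
      base <- dp$D[m + 1, j + 1, k]
      if (!is.finite(base)) next
      pam_obs <- if (j + p <= n) {
        paste(W[(j + 1):(j + p)], collapse = "")
      } else {
        paste(W[seq_len(n - j) + j], collapse = "")
      }
      pam_ok <- nchar(pam_obs) == p && iupac_match(pam_obs, pam)
      cands[[length(cands) + 1]] <- list(
        j_end = j, state = k, base_score = base,
        total = base + if (pam_ok) params$pam_bonus else 0,
        pam_observed = pam_obs, pam_match = pam_ok,
        dna_bulges = unname(dp$states[[k]]["d"]),
        rna_bulges = unname(dp$states[[k]]["r"])
      )
    }
  }
  if (length(cands) == 0) return(list())
  totals <- vapply(cands, `[[`, 0, "total")
  best <- max(totals)
  cands <- cands[totals > best - 1e-9]
  lapply(cands, function(cd) {
    tb <- traceback_path(dp, S, W, params, cd$j_end, cd$state)
    c(cd, tb)
  })
}

#' Align an sgRNA spacer within a genomic window
#'
#' Semi-global dynamic-programming alignment: the spacer is aligned
#' end-to-end, the window locally, on both strands, allowing up to
#' `max_bulges` unpaired bases (DNA bulge = extra genomic base, i.e. a gap in
#' the spacer row; RNA bulge = extra spacer base, i.e. a gap in the genome
#' row). Placements whose PAM-adjacent genomic bases match the PAM pattern
#' receive `pam_bonus`. Among equal-scoring placements, ties are broken by
#' fewer total bulges, fewer mismatches, PAM match first, then leftmost
#' genomic start (plus strand first).
#'
#' @param query a [spacer_query()].
#' @param window a window as returned by [extract_window()] (fields `seq`,
#'   `chrom`, `start`, `end`).
#' @param params an [align_params()].
#' @return an object of class `spacer_alignment`: genomic protospacer
#'   interval and strand, gapped `aligned_spacer`/`aligned_protospacer` rows
#'   (spacer orientation, 5'->3'), `protospacer` (ungapped), `pam_observed`,
#'   `pam_match`, `mismatches`, `dna_bulges`, `rna_bulges`, `levenshtein`
#'   (spacer vs ungapped protospacer, PAM excluded) and `score`.
#' @export
align_spacer <- function(query, window, params = align_params()) {
  stopifnot(inherits(query, "spacer_query"))
  Wstr <- toupper(window$seq)
  m <- nchar(query$spacer)
  n <- nchar(Wstr)
  if (n < m) {
    stop("window (", n, " bp) shorter than spacer (", m, " nt)",
         call. = FALSE)
  }
  reversed <- query$pam_side == "5prime"
  S_run <- if (reversed) rev_string(query$spacer) else query$spacer
  pam_run <- if (reversed) rev_string(query$pam) else query$pam
  S <- strsplit(S_run, "")[[1]]

  all_cands <- list()
  for (strand in c("+", "-")) {
    seq_run0 <- if (strand == "+") Wstr else revcomp(Wstr)
    seq_run <- if (reversed) rev_string(seq_run0) else seq_run0
    cands <- candidates_3prime(S, seq_run, pam_run, params)
    for (cd in cands) {
      # window-local coordinates in the orientation actually aligned;
      # undo the 5'-PAM reversal first
      j0 <- cd$j_start; j1 <- cd$j_end
      asp <- cd$aligned_spacer; awin <- cd$aligned_window
      pam_obs <- cd$pam_observed
      if (reversed) {
        tmp <- n + 1 - j1; j1 <- n + 1 - j0; j0 <- tmp
        asp <- rev_string(asp); awin <- rev_string(awin)
        pam_obs <- rev_string(pam_obs)
      }
      if (strand == "+") {
        gstart <- window$start + j0 - 1
        gend <- window$start + j1
      } else {
        gstart <- window$start + n - j1
        gend <- window$start + n - j0 + 1
      }
      all_cands[[length(all_cands) + 1]] <- list(
        chrom = window$chrom, start = gstart, end = gend, strand = strand,
        aligned_spacer = asp, aligned_protospacer = awin,
        pam_observed = pam_obs, pam_match = cd$pam_match,
        mismatches = cd$mismatches,
        dna_bulges = cd$dna_bulges, rna_bulges = cd$rna_bulges,
        score = cd$total
      )
    }
  }
  if (params$require_pam) {
    keep <- vapply(all_cands, `[[`, logical(1), "pam_match")
    if (!any(keep)) {
      stop("no PAM-adjacent placement found and require_pam = TRUE",
           call. = FALSE)
    }
    all_cands <- all_cands[keep]
  }
  scores <- vapply(all_cands, `[[`, 0, "score")
  all_cands <- all_cands[scores > max(scores) - 1e-9]
  ord <- order(
    vapply(all_cands, function(x) x$dna_bulges + x$rna_bulges, 0),
    vapply(all_cands, `[[`, 0, "mismatches"),
    !vapply(all_cands, `[[`, logical(1), "pam_match"),
    vapply(all_cands, `[[`, 0, "start"),
    vapply(all_cands, `[[`, character(1), "strand")
  )
  best <- all_cands[[ord[1]]]
  proto <- gsub("-", "", best$aligned_protospacer, fixed = TRUE)
  best$protospacer <- proto
  best$levenshtein <- levenshtein_distance(query$spacer, proto)
  best$spacer <- query$spacer
  structure(best, class = "spacer_alignment")
}

rev_string <- function(x) {
  paste(rev(strsplit(x, "")[[1]]), collapse = "")
}

#' @export
print.spacer_alignment <- function(x, ...) {
  cat(sprintf("<spacer_alignment %s:%d-%d(%s) score=%.1f>\n",
              x$chrom, x$start, x$end, x$strand, x$score))
  cat(" spacer      ", x$aligned_spacer, "\n")
  cat(" protospacer ", x$aligned_protospacer, " PAM:", x$pam_observed,
      if (x$pam_match) "(match)" else "(no match)", "\n")
  cat(sprintf(" mismatches=%d dna_bulges=%d rna_bulges=%d levenshtein=%d\n",
              x$mismatches, x$dna_bulges, x$rna_bulges, x$levenshtein))
  invisible(x)
}

#' Blunt cut coordinate implied by a spacer alignment
#'
#' For Cas9-family enzymes the blunt cut falls 3 bp 5' of the PAM, i.e.
#' between protospacer positions 16 and 17 in 0-start numbering for a 20-nt
#' spacer. The cut is mapped through the gapped alignment so bulges shift it
#' with the genomic column of the relevant spacer position, and reported as a
#' 0-based between-bases genomic coordinate.
#'
#' @param alignment a `spacer_alignment`.
#' @return integer genomic cut coordinate.
#' @export
protospacer_cut_position <- function(alignment) {
  stopifnot(inherits(alignment, "spacer_alignment"))
  sp <- strsplit(alignment$aligned_spacer, "")[[1]]
  gn <- strsplit(alignment$aligned_protospacer, "")[[1]]
  m <- sum(sp != "-")
  if (m < 18) {
    stop("cut position undefined: fewer than 18 aligned spacer positions",
         call. = FALSE)
  }
  target <- m - 3L  # 0-based spacer index of the first base 3' of the cut
  si <- 0L; gi <- 0L; g_at_target <- NA_integer_
  for (cc in seq_along(sp)) {
    if (gn[cc] != "-") gi <- gi + 1L
    if (sp[cc] != "-") {
      si <- si + 1L
      if (si == target + 1L) {
        # spacer position reached; if it sits in a genome gap (RNA bulge),
        # the boundary falls before the next genomic base
        g_at_target <- if (gn[cc] != "-") gi else gi + 1L
        break
      }
    }
  }
  if (is.na(g_at_target)) {
    stop("cut position undefined for this alignment", call. = FALSE)
  }
  if (alignment$strand == "+") {
    as.integer(alignment$start + g_at_target - 1L)
  } else {
    as.integer(alignment$end - g_at_target + 1L)
  }
}

#' Align the spacer around every cut cluster
#'
#' Convenience wrapper running [extract_window()] and [align_spacer()] per
#' cluster and collecting one row per cluster.
#'
#' @param clusters output of [cluster_cut_sites()].
#' @param reference `DNAStringSet` or FASTA path.
#' @param query a [spacer_query()].
#' @param flank window flank in bp (default 50, i.e. up to a 100 bp window).
#' @param params an [align_params()].
#' @return tibble with one row per cluster: coordinates, strand, protospacer,
#'   PAM, mismatch/bulge counts, Levenshtein distance, score, implied cut
#'   position, and the alignment object in a list-column.
#' @export
align_clusters <- function(clusters, reference, query, flank = 50,
                           params = align_params()) {
  ref <- load_reference(reference)
  rows <- lapply(seq_len(nrow(clusters)), function(i) {
    win <- extract_window(ref, clusters$chrom[i], clusters$representative[i],
                          flank = flank)
    aln <- align_spacer(query, win, params)
    cut <- tryCatch(protospacer_cut_position(aln), error = function(e) NA)
    tibble(
      cluster_id = clusters$cluster_id[i],
      chrom = aln$chrom, start = aln$start, end = aln$end,
      strand = aln$strand, protospacer = aln$protospacer,
      pam = aln$pam_observed, pam_match = aln$pam_match,
      mismatches = aln$mismatches, dna_bulges = aln$dna_bulges,
      rna_bulges = aln$rna_bulges, levenshtein = aln$levenshtein,
      score = aln$score, cut_position = as.integer(cut),
      alignment = list(aln)
    )
  })
  bind_rows(rows)
}
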