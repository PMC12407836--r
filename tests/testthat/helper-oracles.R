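# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms/code paths than the package.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Brute-force best semi-global alignment score: enumerates every genomic
# start x strand x gap configuration with at most `max_bulges` total bulges
# (DNA bulges = extra genomic bases at spacer junctions 1..m-1, repetition
# allowed; RNA bulges = unpaired interior spacer positions 2..m-1) and adds
# the PAM bonus where the adjacent window bases match the pattern.
oracle_best_score <- function(spacer, window_seq, pam = "NGG",
                              match = 1, mismatch = -1, gap = -2,
                              pam_bonus = 3, max_bulges = 2) {
  m <- nchar(spacer)
  S <- strsplit(spacer, "")[[1]]
  p <- nchar(pam)
  pam_chars <- strsplit(pam, "")[[1]]
  iupac <- Biostrings::IUPAC_CODE_MAP

  configs <- list()
  junctions <- 1:(m - 1)
  rna_positions <- 2:(m - 1)
  configs[[1]] <- list(dna = integer(0), rna = integer(0))
  if (max_bulges >= 1) {
    for (k in junctions) configs[[length(configs) + 1]] <-
        list(dna = k, rna = integer(0))
    for (k in rna_positions) configs[[length(configs) + 1]] <-
        list(dna = integer(0), rna = k)
  }
  if (max_bulges >= 2) {
    for (k1 in junctions) for (k2 in junctions[junctions >= k1]) {
      configs[[length(configs) + 1]] <- list(dna = c(k1, k2),
                                             rna = integer(0))
    }
    for (k1 in rna_positions) {
      for (k2 in rna_positions[rna_positions > k1]) {
        configs[[length(configs) + 1]] <- list(dna = integer(0),
                                               rna = c(k1, k2))
      }
      for (k2 in junctions) {
        configs[[length(configs) + 1]] <- list(dna = k2, rna = k1)
      }
    }
  }

  best <- -Inf
  for (strand_seq in c(window_seq, revcomp_chr(window_seq))) {
    W <- strsplit(strand_seq, "")[[1]]
    n <- length(W)
    pam_ok <- vapply(seq_len(n), function(j) {
      if (j + p > n) return(FALSE)
      all(vapply(seq_len(p), function(t) {
        grepl(W[j + t], iupac[[pam_chars[t]]], fixed = TRUE)
      }, logical(1)))
    }, logical(1))
    for (cfg in configs) {
      d <- length(cfg$dna); r <- length(cfg$rna)
      glen <- m + d - r
      if (glen > n) next
      # genome offset of each paired spacer position within the placement
      offsets <- integer(m)
      g <- 0L
      for (i in seq_len(m)) {
        if (i %in% cfg$rna) {
          offsets[i] <- NA_integer_
        } else {
          g <- g + 1L
          offsets[i] <- g
        }
        g <- g + sum(cfg$dna == i)
      }
      starts <- seq_len(n - glen + 1)
      mm <- integer(length(starts))
      paired <- which(!is.na(offsets))
      for (i in paired) {
        mm <- mm + (W[starts + offsets[i] - 1L] != S[i])
      }
      base <- (length(paired) - mm) * match + mm * mismatch +
        (d + r) * gap
      jend <- starts + glen - 1L
      total <- base + ifelse(pam_ok[jend], pam_bonus, 0)
      best <- max(best, max(total))
    }
  }
  best
}

# O(n^2) pair-counting Kendall tau-b.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  num <- sum(sx[up] * sy[up])
  den <- sqrt(sum(sx[up]^2)) * sqrt(sum(sy[up]^2))
  num / den
}

# Tiny toy profile builder for edit-call tests: counts in spacer
# orientation at the given site.
toy_profile <- function(ref, counts, site = genomic_interval("chr1", 100,
                                                             100 +
                                                               length(ref),
                                                             "+")) {
  stopifnot(nrow(counts) == length(ref))
  L <- length(ref)
  gpos <- if (site$strand == "+") site$start + seq_len(L) - 1L else
    site$end - seq_len(L)
  prof <- tibble::tibble(
    position = seq_len(L) - 1L, gpos = gpos, ref = ref,
    A = as.integer(counts[, "A"]), C = as.integer(counts[, "C"]),
    G = as.integer(counts[, "G"]), T = as.integer(counts[, "T"])
  )
  prof$coverage <- prof$A + prof$C + prof$G + prof$T
  structure(prof, site = site, class = c("base_edit_profile", class(prof)))
}

count_matrix <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("A", "C", "G", "T")
  m
}
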