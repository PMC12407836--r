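test_that("base frequencies count pileups in spacer orientation", {
  pile <- tibble::tibble(
    chrom = "chr1", pos = 101:104, ref = c("A", "C", "G", "T"),
    A = c(90L, 0L, 0L, 0L), C = c(0L, 100L, 0L, 0L),
    G = c(10L, 0L, 100L, 0L), T = c(0L, 0L, 0L, 100L)
  )
  site <- genomic_interval("chr1", 100, 104, "+")
  prof <- base_frequencies(pile, site)
  expect_equal(prof$coverage, rep(100L, 4))
  expect_equal(prof$G[1] / prof$coverage[1], 0.10)
  expect_equal(prof$ref, c("A", "C", "G", "T"))
  # counts always sum to coverage
  expect_equal(prof$A + prof$C + prof$G + prof$T, prof$coverage)

  # minus strand: genomic T>C at 20% reads as A>G in spacer orientation
  pile2 <- tibble::tibble(
    chrom = "chr1", pos = 101:102, ref = c("G", "T"),
    A = c(0L, 0L), C = c(0L, 20L), G = c(100L, 0L), T = c(0L, 80L)
  )
  site2 <- genomic_interval("chr1", 100, 102, "-")
  prof2 <- base_frequencies(pile2, site2)
  expect_equal(prof2$ref, c("A", "C"))      # 5'->3' along the spacer
  expect_equal(prof2$position, c(0L, 1L))
  expect_equal(prof2$G[1], 20L)             # the T>C variant, complemented
  expect_equal(prof2$A[1], 80L)

  # zero-coverage positions are flagged, not errors
  site3 <- genomic_interval("chr1", 100, 110, "+")
  prof3 <- base_frequencies(pile, site3)
  expect_equal(prof3$coverage[5:10], rep(0L, 6))
  expect_error(base_frequencies(pile, genomic_interval("chrX", 1, 5, "+")),
               "contig")
})

test_that("edit calls apply the inclusive threshold and coverage floor", {
  ref <- c("A", "A", "A", "C")
  mk_counts <- function(freqs, cov = 1000L) {
    m <- matrix(0L, length(ref), 4, dimnames = list(NULL, c("A", "C", "G",
                                                            "T")))
    for (i in seq_along(ref)) {
      g <- as.integer(round(cov * freqs[i]))
      m[i, "G"] <- g
      m[i, ref[i]] <- m[i, ref[i]] + cov - g
    }
    m
  }
  prof <- toy_profile(ref, mk_counts(c(0.10, 0, 0, 0.5)))
  cl <- call_edits(prof, "A>G")
  expect_true(cl$site_edited)               # 0.10 >= 0.05
  expect_equal(sum(cl$table$eligible), 3)   # the C position is ineligible

  expect_true(call_edits(toy_profile(ref, mk_counts(c(0.05, 0, 0, 0))),
                         "A>G")$site_edited)    # exactly 5% counts
  expect_false(call_edits(toy_profile(ref, mk_counts(c(0.049, 0.01, 0, 0))),
                          "A>G")$site_edited)

  # coverage floor: a high-frequency position with thin coverage is ignored
  thin <- mk_counts(c(0.5, 0, 0, 0), cov = 10L)
  cl2 <- call_edits(toy_profile(ref, thin), "A>G", min_coverage = 20)
  expect_false(cl2$site_edited)

  # no eligible positions is flagged, not an error
  cl3 <- call_edits(toy_profile(c("C", "C"),
                                count_matrix(c(0, 100, 0, 0),
                                             c(0, 100, 0, 0))), "A>G")
  expect_false(cl3$site_edited)
  expect_true(cl3$no_eligible)
  expect_error(call_edits(prof, "A>A"), "distinct")
})

test_that("raising the threshold or masking never adds edited sites", {
  set.seed(12)
  for (i in 1:20) {
    ref <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    cov <- 200L
    counts <- t(vapply(seq_along(ref), function(p) {
      g <- rbinom(1, cov, runif(1, 0, 0.2))
      out <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      out["G"] <- as.integer(g)
      out[ref[p]] <- out[ref[p]] + cov - as.integer(g)
      out
    }, integer(4)))
    prof <- toy_profile(ref, counts)
    th <- sort(runif(2, 0.01, 0.5))
    lo <- call_edits(prof, "A>G", threshold = th[1])
    hi <- call_edits(prof, "A>G", threshold = th[2])
    expect_true(lo$site_edited >= hi$site_edited)
    masked <- call_edits(prof, "A>G", threshold = th[1],
                         masked = sample(0:7, 3))
    expect_true(lo$site_edited >= masked$site_edited)
  }
})

test_that("SNP masking composes with edit calling", {
  ref <- c("A", "A")
  case <- toy_profile(ref, count_matrix(c(400, 0, 600, 0),   # 0.60
                                        c(900, 0, 100, 0)))  # 0.10
  ctrl_masking <- toy_profile(ref, count_matrix(c(520, 0, 480, 0),  # 0.48
                                                c(1000, 0, 0, 0)))  # 0.0
  masked <- mask_snps(list(ctrl_masking), "A>G")
  expect_equal(masked, 0L)                  # heterozygous SNP position
  cl <- call_edits(case, "A>G", masked = masked)
  expect_true(cl$site_edited)               # still edited via position 1
  expect_true(cl$table$masked[1])
  expect_false(cl$table$eligible[1])

  # a clean control masks nothing
  expect_equal(mask_snps(list(toy_profile(ref,
                                          count_matrix(c(1000, 0, 0, 0),
                                                       c(1000, 0, 0, 0)))),
                         "A>G"), integer(0))
  expect_warning(mask_snps(list(), "A>G"), "unmasked")
})

test_that("truth-set rule matches exhaustive application on a grid", {
  set.seed(31)
  grid <- expand.grid(site = paste0("L", 1:10),
                      replicate = paste0("r", 1:5),
                      stringsAsFactors = FALSE)
  grid$edited <- runif(nrow(grid)) < rep(seq(0.05, 0.95, length.out = 10),
                                         5)
  ts <- build_truth_set(grid, min_replicates = 3)
  # brute-force recomputation
  expected <- sort(names(which(tapply(grid$edited, grid$site, sum) >= 3)))
  expect_equal(ts$loci, expected)

  expect_true("L1" %in% build_truth_set(
    tibble::tibble(site = "L1", replicate = paste0("r", 1:5),
                   edited = c(TRUE, TRUE, TRUE, FALSE, FALSE)))$loci)
  expect_false("L1" %in% build_truth_set(
    tibble::tibble(site = "L1", replicate = paste0("r", 1:5),
                   edited = c(TRUE, TRUE, FALSE, FALSE, FALSE)))$loci)
  expect_error(build_truth_set(grid[grid$replicate %in%
                                      c("r1", "r2"), ]),
               "at least 3")
})

test_that("BAM-path quantification matches the emitted read counts", {
  skip_if_not_installed("Rsamtools")
  set.seed(55)
  refseq <- Biostrings::DNAStringSet(c(chrS = random_dna(400)))
  site <- genomic_interval("chrS", 100, 120, "+")
  freq <- numeric(20); freq[c(5, 7, 11)] <- c(0.3, 0.5, 0.1)
  tmp_sam <- withr::local_tempfile(fileext = ".sam")
  sam <- simulate_site_sam(site, refseq, freq, "A>G", depth = 150,
                           path = tmp_sam)
  bam <- Rsamtools::asBam(tmp_sam, withr::local_tempfile(),
                          overwrite = TRUE)
  prof <- base_frequencies(bam, site, reference = refseq)
  # exact agreement with the realized per-position counts
  expect_equal(prof$A, sam$counts$A)
  expect_equal(prof$C, sam$counts$C)
  expect_equal(prof$G, sam$counts$G)
  expect_equal(prof$T, sam$counts$T)
  expect_equal(prof$ref, sam$counts$ref)

  # the same reads summarized as a pileup give the identical profile
  prof2 <- base_frequencies(sam$counts, site)
  expect_equal(as.data.frame(prof), as.data.frame(prof2))
})

test_that("strand-symmetric representations yield identical calls", {
  set.seed(66)
  refseq <- Biostrings::DNAStringSet(c(chrS = random_dna(300)))
  fwd <- genomic_interval("chrS", 100, 120, "+")
  # pileup with an A>G signal wherever the + strand reference has an A
  bases <- strsplit(toupper(as.character(
    Biostrings::subseq(refseq[["chrS"]], 101, 120))), "")[[1]]
  cov <- 500L
  counts <- t(vapply(bases, function(b) {
    out <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    if (b == "A") {
      out["G"] <- 60L; out["A"] <- cov - 60L
    } else {
      out[b] <- cov
    }
    out
  }, integer(4)))
  pile <- tibble::tibble(chrom = "chrS", pos = 101:120, ref = bases,
                         A = counts[, "A"], C = counts[, "C"],
                         G = counts[, "G"], T = counts[, "T"])
  call_fwd <- call_edits(base_frequencies(pile, fwd), "A>G")
  # the same physical locus interpreted on the minus strand carries the
  # complementary conversion
  rev_site <- genomic_interval("chrS", 100, 120, "-")
  call_rev <- call_edits(base_frequencies(pile, rev_site), "T>C")
  expect_equal(call_fwd$site_edited, call_rev$site_edited)
  f1 <- call_fwd$table$edit_freq[call_fwd$table$eligible]
  f2 <- call_rev$table$edit_freq[call_rev$table$eligible]
  expect_equal(sort(f1), sort(f2))
})
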