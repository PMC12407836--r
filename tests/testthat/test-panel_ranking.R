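mk_cluster_set <- function(scores_by_source) {
  # build records across 3 clusters at chr1:100/300/500 with given per-source
  # scores (list: source -> numeric(3), NA = not reported)
  recs <- list()
  pos <- c(100L, 300L, 500L)
  for (src in names(scores_by_source)) {
    sc <- scores_by_source[[src]]
    recs[[src]] <- tibble::tibble(
      source = src, sample = "s1", chrom = "chr1",
      start = pos, end = pos + 1L, strand = "*", score = sc,
      evidence = "insilico_cleavage", abundance = NA_integer_
    )
  }
  cluster_cut_sites(dplyr::bind_rows(recs), window = 10)
}

test_that("per-source Z-standardization follows the sample-sd rule", {
  cl <- mk_cluster_set(list(t1 = c(1, 2, 3), t2 = c(5, 5, 5),
                            t3 = c(NA, NA, NA)))
  sc <- standardize_scores(cl)
  z1 <- vapply(sc$per_source_z, function(x) x[["t1"]], 0)
  expect_equal(z1, c(-1, 0, 1))               # sample sd of {1,2,3} is 1
  z2 <- vapply(sc$per_source_z, function(x) x[["t2"]], 0)
  expect_equal(z2, c(0, 0, 0))                # sd = 0 rule
  z3 <- vapply(sc$per_source_z, function(x) x[["t3"]], 0)
  expect_equal(z3, c(0, 0, 0))                # score-less source
  expect_equal(sc$mean_z, c(-1, 0, 1) / 3)
  expect_equal(sc$rank_by_z, c(3L, 2L, 1L))
  expect_equal(sc$minmax, c(0, 0.5, 1))

  # affine transformation of one source's raw scores leaves Z unchanged
  cl2 <- mk_cluster_set(list(t1 = 10 * c(1, 2, 3) + 7, t2 = c(5, 5, 5),
                             t3 = c(NA, NA, NA)))
  expect_equal(standardize_scores(cl2)$mean_z, sc$mean_z)
})

test_that("min-max scaling maps to [0,1] with a neutral degenerate case", {
  expect_equal(minmax_scale(c(-1, 0, 1)), c(0, 0.5, 1))
  expect_equal(minmax_scale(c(2, 4, 10)), c(0, 0.25, 1))
  expect_equal(minmax_scale(c(3, 3, 3)), c(0.5, 0.5, 0.5))
  expect_error(minmax_scale(numeric(0)), "empty")
  set.seed(5)
  for (i in 1:20) {
    v <- rnorm(sample(2:30, 1))
    out <- minmax_scale(v)
    expect_true(all(out >= 0 & out <= 1))
    if (max(v) > min(v)) expect_setequal(range(out), c(0, 1))
  }
})

test_that("feature annotation uses half-open strand-ignorant overlap", {
  aln <- tibble::tibble(cluster_id = 1:3, chrom = "chr1",
                        start = c(100L, 100L, 400L),
                        end = c(120L, 120L, 420L), strand = "+")
  feats <- tibble::tibble(
    label = c("exon", "exon", "intron", "oncogene"),
    chrom = "chr1",
    start = c(110L, 120L, 95L, 115L), end = c(200L, 200L, 200L, 130L)
  )
  ann <- annotate_clusters(aln[1, ], feats[1, ])
  expect_equal(ann$annotations[[1]], "exon")
  # [100,120) vs [120,200): half-open boundary does not overlap
  ann2 <- annotate_clusters(aln[2, ], feats[2, ])
  expect_equal(ann2$annotations[[2 - 1]], character(0))
  # multiple labels accumulate independently
  ann3 <- annotate_clusters(aln[1, ], feats)
  expect_setequal(ann3$annotations[[1]], c("exon", "intron", "oncogene"))
  ann4 <- annotate_clusters(aln[3, ], feats)
  expect_equal(ann4$annotations[[1]], character(0))
})

test_that("weight tables enumerate criteria and round-trip edits", {
  recs <- tibble::tibble(
    source = c("dsodn", "t1"), sample = c("donor1", "insilico"),
    chrom = "chr1", start = c(10L, 12L), end = c(11L, 13L), strand = "*",
    score = NA_real_,
    evidence = c("empirical_cleavage", "insilico_cleavage"),
    abundance = c(5L, NA)
  )
  wt <- build_weight_table(recs, c("exon", "intron", "oncogene"))
  # 2 sources + 2 samples + 3 features + 1 levenshtein rule
  expect_equal(nrow(wt), 8)
  expect_equal(wt$weight[wt$criterion == "source:dsodn"], 3)
  expect_equal(wt$weight[wt$criterion == "source:t1"], 1)
  expect_equal(wt$weight[wt$criterion == "feature:exon"], 2)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_weight_table(wt, tmp)
  wt2 <- read_weight_table(tmp, reference_table = wt)
  expect_equal(wt2, wt)

  # user edit is honored on reload
  wt$weight[wt$criterion == "feature:exon"] <- 5
  write_weight_table(wt, tmp)
  expect_equal(read_weight_table(tmp, wt)$weight[
    wt$criterion == "feature:exon"], 5)

  # unknown criterion in an edited file is a config error
  wt_bad <- rbind(wt, tibble::tibble(criterion = "feature:bogus",
                                     weight = 1))
  write_weight_table(wt_bad, tmp)
  expect_error(read_weight_table(tmp, wt), "unknown criterion")
})

test_that("rank_sites matches a brute-force weight-sum recomputation", {
  set.seed(21)
  cfg <- sim_config(seed = 21, noise_free = TRUE)
  sim <- simulate_reference_and_sites(cfg)
  recs <- simulate_nomination_tables(cfg, sim$truth)
  feats <- tibble::tibble(label = c("exon", "oncogene"), chrom = cfg$contig,
                          start = c(sim$truth$start[1], sim$truth$start[3]),
                          end = c(sim$truth$end[1], sim$truth$end[3]))
  res <- run_integrate(recs, sim$reference, cfg$spacer, cfg$pam,
                       features = feats, panel_size = 8)
  wmap <- setNames(res$weight_table$weight, res$weight_table$criterion)
  # independent recomputation of every weight sum from the raw pieces
  for (i in seq_len(nrow(res$ranked))) {
    cid <- res$ranked$cluster_id[i]
    members <- res$clusters$members[[match(cid, res$clusters$cluster_id)]]
    expected <- sum(wmap[paste0("source:", unique(members$source))]) +
      sum(wmap[paste0("sample:", unique(members$sample))]) +
      sum(wmap[paste0("feature:", res$ranked$annotations[[i]],
                      recycle0 = TRUE)]) +
      ifelse(res$ranked$levenshtein[i] <= 4, wmap[["levenshtein<=4"]], 0)
    expect_equal(res$ranked$weight_sum[i], unname(expected))
  }
  # descending order with dense ranks
  expect_equal(res$ranked$final_rank, seq_len(nrow(res$ranked)))
  expect_true(all(diff(res$ranked$weight_sum) <= 0))
  # shuffling input order never changes the ranking
  res2 <- run_integrate(recs[sample(nrow(recs)), ], sim$reference,
                        cfg$spacer, cfg$pam, features = feats,
                        panel_size = 8)
  expect_equal(as.data.frame(res2$ranked[, c("cluster_id", "weight_sum")]),
               as.data.frame(res$ranked[, c("cluster_id", "weight_sum")]))
})

test_that("tie-breaking prefers higher mean Z then lower Levenshtein", {
  ranked <- tibble::tibble(
    final_rank = 0L, cluster_id = 1:2, chrom = "chr1",
    start = c(10L, 400L), end = c(30L, 420L), strand = "+",
    levenshtein = c(1L, 1L), mean_z = c(0.3, 1.2), minmax = c(0, 1),
    annotations = list(character(0), character(0)),
    weight_sum = c(4, 4),
    evidence = list("insilico_cleavage", "insilico_cleavage"),
    n_insilico_sources = c(1L, 1L)
  )
  aln <- ranked[, c("cluster_id", "chrom", "start", "end", "strand",
                    "levenshtein")]
  ann <- tibble::tibble(cluster_id = 1:2,
                        annotations = list(character(0), character(0)))
  sc <- tibble::tibble(cluster_id = 1:2, mean_z = c(0.3, 1.2),
                       minmax = c(0, 1))
  cl <- tibble::tibble(
    cluster_id = 1:2,
    source_support = list(c(t1 = 1L), c(t1 = 1L)),
    sample_support = list(c(s1 = 1L), c(s1 = 1L)),
    members = list(
      tibble::tibble(source = "t1", sample = "s1",
                     evidence = "insilico_cleavage"),
      tibble::tibble(source = "t1", sample = "s1",
                     evidence = "insilico_cleavage"))
  )
  wt <- tibble::tibble(criterion = c("source:t1", "sample:s1",
                                     "levenshtein<=4"),
                       weight = c(1, 1, 1))
  rk <- rank_sites(aln, ann, sc, cl, wt)
  expect_equal(rk$cluster_id, c(2L, 1L))  # equal sums: higher mean_z first
})

test_that("panel selection honors tiers, exclusions and size", {
  mk_ranked <- function(n_emp, n_tool, n_weak) {
    n <- n_emp + n_tool + n_weak
    tibble::tibble(
      final_rank = seq_len(n), cluster_id = seq_len(n), chrom = "chr1",
      start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 20L,
      strand = "+", levenshtein = 2L, mean_z = 0, minmax = 0.5,
      annotations = rep(list(character(0)), n),
      weight_sum = rev(seq_len(n)),
      evidence = c(rep(list("empirical_cleavage"), n_emp),
                   rep(list("insilico_cleavage"), n_tool + n_weak)),
      n_insilico_sources = c(rep(2L, n_emp), rep(7L, n_tool),
                             rep(2L, n_weak))
    )
  }
  # 3 empirical + 5 in-silico of which 2 pass min_tools: 5 selected
  r <- mk_ranked(3, 2, 3)
  expect_warning(select_panel(r, panel_size = 10, min_tools = 6),
                 "available")
  p <- suppressWarnings(select_panel(r, panel_size = 10, min_tools = 6))
  expect_equal(sum(p$panel_tier %in% c("empirical", "multi_tool")), 5)
  expect_equal(sum(p$panel_tier == "empirical"), 3)

  # excluding a selected site promotes the next-ranked eligible site
  r2 <- mk_ranked(3, 4, 0)
  p2 <- select_panel(r2, panel_size = 5, min_tools = 6)
  sel2 <- p2$cluster_id[p2$panel_tier != "unselected"]
  p3 <- select_panel(r2, panel_size = 5, min_tools = 6,
                     exclusions = sel2[4])
  expect_equal(sum(p3$panel_tier %in% c("empirical", "multi_tool")), 5)
  expect_true(all(setdiff(sel2, sel2[4]) %in%
                    p3$cluster_id[p3$panel_tier != "unselected"]))
  expect_equal(p3$panel_tier[p3$cluster_id == sel2[4]], "excluded")

  # 200 sites, min_tools = 6, panel of 144: all empirical retained
  set.seed(9)
  n_emp <- 87
  r4 <- mk_ranked(n_emp, 90, 23)
  p4 <- select_panel(r4, panel_size = 144, min_tools = 6)
  expect_equal(sum(p4$panel_tier %in% c("empirical", "multi_tool")), 144)
  expect_equal(sum(p4$panel_tier == "empirical"), n_emp)
  expect_equal(sum(p4$panel_tier == "multi_tool"), 144 - n_emp)
})
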