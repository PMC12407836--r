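#' Run the nomination-integration workflow
#'
#' End-to-end panel design: read nomination tables, cluster cut sites,
#' re-align the spacer around each cluster, standardize scores, annotate
#' with features, build (or load) the criterion weight table, rank, and
#' select the tiered panel. All intermediate tables are written to `outdir`
#' when given, and every effective parameter is recorded in the returned
#' `params` element.
#'
#' @param nominations nomination record tibble, or character vector of
#'   nomination TSV paths.
#' @param reference `DNAStringSet` or FASTA path.
#' @param spacer,pam guide sequence and PAM pattern.
#' @param features feature tibble (`label`, `chrom`, `start`, `end`) or
#'   `NULL`.
#' @param window clustering radius in bp (default 15).
#' @param flank alignment window flank in bp (default 50).
#' @param align_params an [align_params()].
#' @param weights weight table, path to an edited weight TSV, or `NULL` for
#'   defaults.
#' @param panel_size panel size to select (default: all clusters).
#' @param min_tools tier-2 minimum in-silico source support (default 6).
#' @param exclusions cluster ids excluded from the panel.
#' @param dialect coordinate dialect of nomination TSV inputs.
#' @param outdir optional output directory.
#' @return list with `records`, `clusters`, `alignments`, `scores`,
#'   `annotations`, `weight_table`, `ranked`, `panel`, `params`.
#' @export
run_integrate <- function(nominations, reference, spacer, pam = "NGG",
                          features = NULL, window = 15, flank = 50,
                          align_params = crispanel::align_params(),
                          weights = NULL, panel_size = NULL, min_tools = 6,
                          exclusions = integer(0),
                          dialect = "1-based", outdir = NULL) {
  records <- if (is.character(nominations)) {
    bind_rows(lapply(nominations, read_nomination_table, dialect = dialect))
  } else {
    nominations
  }
  if (nrow(records) == 0) stop("no nomination records", call. = FALSE)
  query <- spacer_query(spacer, pam)
  clusters <- cluster_cut_sites(records, window = window)
  alignments <- align_clusters(clusters, reference, query, flank = flank,
                               params = align_params)
  scores <- standardize_scores(clusters)
  annotations <- annotate_clusters(alignments, features)
  default_wt <- build_weight_table(
    records,
    feature_labels = if (is.null(features)) character(0) else
      unique(features$label)
  )
  weight_table <- if (is.null(weights)) {
    default_wt
  } else if (is.character(weights)) {
    read_weight_table(weights, reference_table = default_wt)
  } else {
    weights
  }
  ranked <- rank_sites(alignments, annotations, scores, clusters,
                       weight_table)
  if (is.null(panel_size)) panel_size <- nrow(ranked)
  panel <- select_panel(ranked, panel_size = panel_size,
                        min_tools = min_tools, exclusions = exclusions)
  params <- list(window = window, flank = flank,
                 align = unclass(align_params), panel_size = panel_size,
                 min_tools = min_tools, exclusions = exclusions,
                 dialect = dialect, spacer = spacer, pam = pam)
  out <- list(records = records, clusters = clusters,
              alignments = alignments, scores = scores,
              annotations = annotations, weight_table = weight_table,
              ranked = ranked, panel = panel, params = params)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_cluster_table(clusters, file.path(outdir, "clusters.tsv"))
    readr::write_tsv(select(alignments, -"alignment"),
                     file.path(outdir, "alignments.tsv"), progress = FALSE)
    write_weight_table(weight_table, file.path(outdir, "weights.tsv"))
    write_ranked_table(ranked, file.path(outdir, "ranked.tsv"))
    write_ranked_table(panel, file.path(outdir, "panel.tsv"))
  }
  out
}

#' Run the edit-quantification workflow
#'
#' Computes per-position base-edit profiles for every site in every case
#' and control sample, masks SNP positions seen in controls, calls the
#' expected edit per site and replicate, and builds the
#' replicate-supported truth set.
#'
#' @param case_pileups named list of case pileup tibbles (one per
#'   replicate).
#' @param control_pileups named list of no-editor control pileup tibbles.
#' @param sites tibble of protospacer sites (`site_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param expected_edit programmed conversion, e.g. `"A>G"`.
#' @param threshold edit-call threshold (default 0.05).
#' @param min_coverage per-position coverage floor (default 20).
#' @param snp_threshold control-sample masking threshold (default 0.05).
#' @param min_replicates truth-set replicate support (default 3).
#' @param outdir optional output directory.
#' @return list with `profiles` (nested), `masked` (per site), `calls`
#'   (tidy site x replicate tibble), `truth`.
#' @export
run_editcall <- function(case_pileups, control_pileups, sites,
                         expected_edit, threshold = 0.05,
                         min_coverage = 20, snp_threshold = 0.05,
                         min_replicates = 3, outdir = NULL) {
  masked <- list()
  calls <- list()
  profiles <- list()
  rep_calls <- list()
  for (i in seq_len(nrow(sites))) {
    id <- sites$site_id[i]
    site <- genomic_interval(sites$chrom[i], sites$start[i], sites$end[i],
                             sites$strand[i])
    ctrl_prof <- lapply(control_pileups, base_frequencies, site = site)
    masked[[id]] <- if (length(ctrl_prof) > 0) {
      mask_snps(ctrl_prof, expected_edit, snp_threshold = snp_threshold,
                min_coverage = min_coverage)
    } else {
      warning("no control for site ", id, "; processed unmasked")
      integer(0)
    }
    profiles[[id]] <- list(controls = ctrl_prof, cases = list())
    for (smp in names(case_pileups)) {
      prof <- base_frequencies(case_pileups[[smp]], site)
      profiles[[id]]$cases[[smp]] <- prof
      cl <- call_edits(prof, expected_edit, threshold = threshold,
                       min_coverage = min_coverage, masked = masked[[id]])
      rep_calls[[length(rep_calls) + 1]] <- tibble(
        site = id, replicate = smp, edited = cl$site_edited
      )
      calls[[paste(id, smp, sep = "|")]] <- cl
    }
  }
  call_tab <- bind_rows(rep_calls)
  truth <- build_truth_set(call_tab, min_freq = threshold,
                           min_replicates = min_replicates)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    write_edit_table(calls, file.path(outdir, "edit_calls.tsv"))
    readr::write_tsv(call_tab, file.path(outdir, "site_calls.tsv"),
                     progress = FALSE)
    writeLines(truth$loci, file.path(outdir, "truth_loci.txt"))
  }
  list(profiles = profiles, masked = masked, calls = call_tab,
       edit_calls = calls, truth = truth)
}

#' Run the method-comparison workflow
#'
#' Builds the sample-by-site score matrix, computes Bray-Curtis
#' dissimilarities and their principal-coordinate ordination, all-vs-all
#' top-k rank concordance, and (when a truth set is given) per-sample
#' precision and recall.
#'
#' @param scores tidy tibble `sample`, `site`, `score`.
#' @param truth optional [build_truth_set()] object or character vector.
#' @param universe loci evaluated for precision/recall (defaults to all
#'   sites in `scores`).
#' @param k top-list size for concordance (default 10).
#' @param outdir optional output directory.
#' @return list with `matrix`, `dissimilarity`, `ordination`,
#'   `concordance`, `confusion` (named list or `NULL`).
#' @export
run_compare <- function(scores, truth = NULL, universe = NULL, k = 10,
                        outdir = NULL) {
  m <- score_matrix(scores)
  D <- bray_curtis_matrix(m)
  ord <- pcoa_ordination(D, k = min(2, nrow(m) - 1))
  samples <- rownames(m)
  conc <- matrix(NA_real_, length(samples), length(samples),
                 dimnames = list(samples, samples))
  rankings <- lapply(samples, function(s) {
    colnames(m)[order(-m[s, ])][m[s, order(-m[s, ])] > 0]
  })
  names(rankings) <- samples
  for (a in samples) {
    for (b in samples) {
      conc[a, b] <- suppressWarnings(
        top_k_concordance(rankings[[a]], rankings[[b]], k = k)
      )
    }
  }
  confusion <- NULL
  if (!is.null(truth)) {
    if (is.null(universe)) universe <- colnames(m)
    confusion <- lapply(samples, function(s) {
      precision_recall(names(which(m[s, ] > 0)), truth, universe)
    })
    names(confusion) <- samples
  }
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    readr::write_tsv(as_tibble(D, rownames = "sample"),
                     file.path(outdir, "bray_curtis.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(ord$coordinates, rownames = "sample"),
                     file.path(outdir, "pcoa.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(conc, rownames = "sample"),
                     file.path(outdir, "concordance.tsv"), progress = FALSE)
    if (!is.null(confusion)) {
      pr <- bind_rows(lapply(names(confusion), function(s) {
        x <- confusion[[s]]
        tibble(sample = s, tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
               precision = x$precision, recall = x$recall)
      }))
      readr::write_tsv(pr, file.path(outdir, "precision_recall.tsv"),
                       progress = FALSE)
    }
  }
  list(matrix = m, dissimilarity = D, ordination = ord, concordance = conc,
       confusion = confusion)
}

#' Run the simulation workflow
#'
#' Generates the full synthetic fixture set (reference FASTA, truth table,
#' per-tool nomination TSVs, per-sample pileups) under one seed.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @return list with `reference`, `truth`, `records`, `pileups`.
#' @export
run_simulate <- function(config, outdir = NULL) {
  sim <- simulate_reference_and_sites(config)
  records <- simulate_nomination_tables(config, sim$truth,
                                        dir = outdir)
  pileups <- simulate_edit_pileups(config, sim$truth, sim$reference,
                                   dir = outdir)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    Biostrings::writeXStringSet(sim$reference,
                                file.path(outdir, "reference.fa"))
    truth_flat <- sim$truth |>
      mutate(edit_freq = vapply(.data$edit_freq, paste,
                                character(1), collapse = ","),
             proto_seq = unlist(.data$proto_seq))
    readr::write_tsv(truth_flat, file.path(outdir, "truth.tsv"),
                     progress = FALSE)
  }
  list(reference = sim$reference, truth = sim$truth, records = records,
       pileups = pileups)
}
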