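#' Build a sample-by-site score matrix
#'
#' Rows are samples (or methods), columns the union of sites across all
#' samples, values min-max normalized scores. A site not detected in a
#' sample is a true zero in this assay, not missing data, so absent cells
#' are 0 — this gives all rows the common support that Bray-Curtis
#' dissimilarity requires.
#'
#' @param scores tidy tibble with columns `sample`, `site`, `score`.
#' @param rescale min-max rescale each sample's scores (default `TRUE`).
#' @return numeric matrix, samples in rows, sites in columns.
#' @export
score_matrix <- function(scores, rescale = TRUE) {
  stopifnot(all(c("sample", "site", "score") %in% names(scores)))
  if (rescale) {
    scores <- scores |>
      group_by(.data$sample) |>
      mutate(score = minmax_scale(.data$score)) |>
      ungroup()
  }
  samples <- sort(unique(scores$sample))
  sites <- sort(unique(scores$site))
  m <- matrix(0, nrow = length(samples), ncol = length(sites),
              dimnames = list(samples, sites))
  m[cbind(match(scores$sample, samples), match(scores$site, sites))] <-
    scores$score
  m
}

#' Bray-Curtis dissimilarity between two score vectors
#'
#' `BC = sum(|u - v|) / sum(u + v)`, computed through
#' [vegan::vegdist()]. Undefined (NA, with a warning) when both vectors are
#' all-zero.
#'
#' @param u,v equal-length non-negative numeric vectors.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  if (any(u < 0) || any(v < 0)) {
    stop("Bray-Curtis requires non-negative entries", call. = FALSE)
  }
  if (all(u == 0) && all(v == 0)) {
    warning("both vectors all-zero; Bray-Curtis undefined")
    return(NA_real_)
  }
  as.numeric(vegan::vegdist(rbind(u, v), method = "bray"))
}

#' @rdname bray_curtis
#' @param m sample-by-site matrix (see [score_matrix()]).
#' @return for `bray_curtis_matrix`, the symmetric dissimilarity matrix.
#' @export
bray_curtis_matrix <- function(m) {
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Classical metric scaling via [ape::pcoa()]: the doubly-centred matrix
#' `B = -1/2 J D^2 J` is eigendecomposed and coordinates are the
#' eigenvectors scaled by the square roots of the positive eigenvalues,
#' sorted descending. Negative eigenvalues (non-Euclidean D) are reported
#' and their axes dropped.
#'
#' @param D symmetric non-negative dissimilarity matrix with zero diagonal.
#' @param k number of axes to return (default 2, capped at the number of
#'   positive eigenvalues).
#' @return list with `coordinates` (n x k matrix), `eigenvalues` (all,
#'   descending) and `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(D, k = 2) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8)) {
    stop("D must be a symmetric matrix", call. = FALSE)
  }
  if (any(diag(D) != 0)) stop("D must have a zero diagonal", call. = FALSE)
  if (any(D < 0)) stop("D must be non-negative", call. = FALSE)
  n <- nrow(D)
  if (all(D == 0)) {
    coords <- matrix(0, n, k,
                     dimnames = list(rownames(D), paste0("Axis.", 1:k)))
    return(list(coordinates = coords, eigenvalues = rep(0, n),
                negative_eigenvalues = numeric(0)))
  }
  fit <- ape::pcoa(stats::as.dist(D))
  values <- fit$values$Eigenvalues
  pos <- sum(values > 1e-12)
  k_use <- min(k, pos)
  coords <- matrix(0, n, k,
                   dimnames = list(rownames(D), paste0("Axis.", 1:k)))
  if (k_use > 0) {
    coords[, seq_len(k_use)] <- fit$vectors[, seq_len(k_use), drop = FALSE]
  }
  list(coordinates = coords, eigenvalues = values,
       negative_eigenvalues = values[values < -1e-12])
}

#' Top-k rank concordance (Kendall tau)
#'
#' Takes the union of the two rankings' top-`k` sites, ranks the union
#' members by each full ranking (sites absent from a ranking are tied
#' beyond its end), and computes Kendall's tau-b on the paired ranks via
#' [stats::cor()].
#'
#' @param ranking_a,ranking_b character vectors of site ids ordered
#'   best-first (full rankings).
#' @param k top-list size (default 10).
#' @return Kendall tau in `[-1, 1]`.
#' @export
top_k_concordance <- function(ranking_a, ranking_b, k = 10) {
  k_use <- min(k, length(ranking_a), length(ranking_b))
  if (k_use < k) {
    warning("fewer than ", k, " ranked sites; using top ", k_use)
  }
  top <- union(head(ranking_a, k_use), head(ranking_b, k_use))
  ra <- match(top, ranking_a)
  rb <- match(top, ranking_b)
  ra[is.na(ra)] <- length(ranking_a) + 1L
  rb[is.na(rb)] <- length(ranking_b) + 1L
  stats::cor(ra, rb, method = "kendall")
}

#' Precision and recall of a call set against a truth set
#'
#' @param calls character vector of sites called positive.
#' @param truth a [build_truth_set()] object or character vector of truly
#'   edited sites.
#' @param universe all evaluated loci; `calls` and `truth` must be subsets.
#' @return an object of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`,
#'   `precision` (NA when no positive calls), `recall` (NA when the truth
#'   set is empty).
#' @export
precision_recall <- function(calls, truth, universe) {
  if (inherits(truth, "truth_set")) truth <- truth$loci
  calls <- unique(calls); truth <- unique(truth)
  if (length(setdiff(calls, universe)) > 0) {
    stop("calls outside the evaluated universe", call. = FALSE)
  }
  if (length(setdiff(truth, universe)) > 0) {
    stop("truth loci outside the evaluated universe", call. = FALSE)
  }
  tp <- length(intersect(calls, truth))
  fp <- length(setdiff(calls, truth))
  fn <- length(setdiff(truth, calls))
  tn <- length(universe) - tp - fp - fn
  structure(
    list(
      tp = tp, fp = fp, fn = fn, tn = tn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion: tp=%d fp=%d fn=%d tn=%d precision=%s recall=%s>\n",
    x$tp, x$fp, x$fn, x$tn,
    ifelse(is.na(x$precision), "NA", sprintf("%.3f", x$precision)),
    ifelse(is.na(x$recall), "NA", sprintf("%.3f", x$recall))))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration over all tables with the observed
#' margins; the two-sided p-value sums the probabilities of tables whose
#' point probability does not exceed the observed table's (within 1e-12).
#' A zero margin gives p = 1 by convention.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != floor(tab))) {
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  }
  r <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(r == 0) || any(cs == 0)) {
    warning("zero margin; p = 1 by convention")
    return(1)
  }
  # x11 ~ Hypergeometric(m = col1 total, n = col2 total, k = row1 total)
  support <- max(0, r[1] - cs[2]):min(r[1], cs[1])
  probs <- stats::dhyper(support, cs[1], cs[2], r[1])
  p_obs <- stats::dhyper(tab[1, 1], cs[1], cs[2], r[1])
  p <- sum(probs[probs <= p_obs + 1e-12])
  min(1, max(p, .Machine$double.xmin))
}
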