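---
title: "Methods: off-target panel design and base-edit quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: off-target panel design and base-edit quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crispanel)
```

## The problem

Base editors (here the adenine editor ABE8e, programmed conversion A→G)
modify DNA without requiring double-strand breaks, which makes their
off-target activity hard to observe directly. The practical surveillance
strategy is two-staged: *nominate* candidate sites genome-wide — from
empirical cut-marking assays (a dsODN oligonucleotide captured at
double-strand breaks, located by sequencing) and from in-silico predictors
— then *validate* a bounded panel of those candidates by targeted amplicon
sequencing in the therapeutically relevant cell type. `crispanel`
implements the computational machinery of both stages.

Everything internal uses 0-based half-open coordinates (BED convention);
1-based inputs (GFF3, 1-based nomination tables, pileup positions) are
shifted on read and back on write. A nomination "position" is interpreted
as the predicted blunt-cut boundary between bases; tools that report
protospacer starts should be converted upstream via the dialect switch.

## Clustering nominations

Different assays and predictors report the same physical site with a few
bases of jitter. Records are sorted by `(chrom, position)` and swept once:
a record joins the open cluster iff it lies within `window` bp of the
cluster's *seed* (first record). Anchoring to the seed — rather than to the
last member or a running centroid — bounds cluster diameter at `2·window`
and prevents percolation through dense regions; the three anchoring
variants coincide on well-separated sites. The default `window = 15` bp
spans the cut-position jitter observed between nucleases and tools while
keeping nearby distinct protospacers separate. The representative position
maximizes support (record count plus summed dsODN abundance), ties going to
the smaller coordinate, so abundantly marked empirical positions win over
stray predictions.

## Spacer re-alignment

Each cluster is re-examined by aligning the spacer within ±`flank`
(default 50, i.e. ≤100 bp) of the representative. The alignment is
semi-global — the spacer end-to-end, the window locally — evaluated on both
strands by dynamic programming over a bulge-count-bounded state space:
states `(i, j, d, r)` with `i` spacer bases and `j` window bases consumed,
`d` DNA bulges (gap in the spacer row = extra genomic base) and `r` RNA
bulges (gap in the genome row = extra spacer base), `d + r ≤ 2` by default.
Larger distortions are not credible protospacers and explode the tie space.
Bulges are restricted to interior columns: a terminal gap is always
dominated by shifting the placement. Scoring defaults are `match +1,
mismatch −1, gap −2` per bulged base, with a `+3` bonus when the bases
adjacent to the placement match the PAM pattern (IUPAC codes; NGG default).
The bonus *prioritizes* PAM-adjacent placements without forbidding a
PAM-less hit that is far superior at the base level; `require_pam = TRUE`
turns it into a hard filter. Ties break deterministically: fewer total
bulges, fewer mismatches, PAM match first, leftmost start, plus strand.
With these scores, one bulge (−2) is preferred over two mismatches (−2 each
relative to match) only when it recovers at least two matches, which keeps
mismatch-only explanations dominant where they exist.

The Levenshtein distance is computed by full unit-cost dynamic programming
between the ungapped spacer and the ungapped aligned protospacer. The PAM
is excluded: it is not part of the spacer, and including it would conflate
targeting divergence with PAM identity. The implied blunt cut falls 3 bp 5′
of the PAM — between protospacer positions 16 and 17 in 0-start numbering
for a 20-nt spacer — and is mapped through the gapped alignment so bulges
shift it with the genomic column of the relevant spacer position.

An alignment is tested against brute-force enumeration of every placement ×
strand × gap configuration on small windows; the enumeration and the DP
share no code.

## Scoring, annotation, ranking

Raw scores are comparable only within a source, so each source's scores are
Z-standardized across clusters (sample SD, n−1). Sources reporting no
scores — or constant scores — contribute z = 0, which encodes "calls all
its sites equally" rather than biasing the mean; the per-cluster `mean_z`
averages member z-scores and is min–max rescaled to [0, 1] for
cross-source display. A constant vector min–max rescales to 0.5 everywhere
(neutral), not 0 or 1, so a degenerate source neither boosts nor buries
sites.

Clusters are annotated by half-open, strand-ignorant overlap of the
protospacer interval with user feature sets (exons, introns, oncogenes,
arbitrary labels). Feature intervals are used exactly as supplied — no
merging — so a user's redundant annotation intentionally counts once per
label, not per interval.

The final priority is a sum of criterion weights from an editable TSV: by
default each empirical source +3, each in-silico source +1, each sample +1,
exon +2, oncogene +2, other features +1, Levenshtein ≤ 4 +1. These defaults
encode the stated design priorities — empirical evidence first, then
multi-tool support, then genotoxicity-relevant context — and are expected
to be tuned per application; the ranking itself is a deterministic total
order (weight sum, then mean z, then Levenshtein, then coordinates) with
dense ranks so a panel cut line is always unambiguous. Panel selection
takes all empirically marked sites, then in-silico sites supported by at
least `min_tools` (default 6) sources in rank order up to `panel_size`,
replacing exclusion-listed sites (e.g. multiplex-primer incompatibilities)
with the next-ranked eligible candidate.

## Edit quantification

Per-position base counts at a protospacer come either from a plain pileup
TSV (`chrom pos ref A C G T`, `pos` 1-based as in samtools) or from a
coordinate-sorted BAM through `Rsamtools::pileup` with a base-quality floor
(default Q20), deletions skipped and insertions ignored. Reverse-strand
sites are complemented so every profile reads 5′→3′ along the spacer.
Eligible positions have the edit's source base as reference, coverage at
least `min_coverage` (default 20, a conventional amplicon-seq floor; the
quality and coverage floors are exposed as arguments since no canonical
values exist), and are not SNP-masked. A site is *edited* iff any eligible
position's destination-base frequency is at least the threshold — 5%,
inclusive, so a frequency of exactly 0.05 counts. Masking removes positions
where any no-editor control shows the destination base at ≥ 5% (the same
scale as the edit threshold) with adequate coverage: a heterozygous
germline A>G variant looks like a 50% edit in cases and controls alike, and
only the control comparison separates the two. The truth set admits a locus
iff it is called edited, post-masking, in at least 3 replicate samples.

Zero-coverage positions are flagged and can never support an edited call;
a site with no eligible positions is reported `site_edited = FALSE` with an
explicit flag rather than an error, since amplicon panels routinely contain
dropout loci.

## Method comparison

Sample-by-site matrices hold min–max-normalized scores with absent sites as
true zeros (non-detection is informative in these assays, and Bray–Curtis
requires common support). Bray–Curtis dissimilarity and its
principal-coordinate ordination go through `vegan::vegdist` and
`ape::pcoa`; two all-zero profiles have undefined dissimilarity and are
flagged. Top-10 concordance takes the union of both rankings' top-10 sites,
ranks union members by each full ranking (absent sites tie beyond the end),
and computes Kendall tau-b — the union-with-full-ranks construction is this
package's choice for handling non-shared top-10 members, using all
available order information. Precision and recall are plain confusion
counts over an explicit locus universe, with undefined ratios flagged
rather than coerced to 0. The two-sided Fisher test enumerates the full
hypergeometric support and sums point probabilities not exceeding the
observed table's (tolerance 1e−12); on the 8-of-9 versus 0-of-8 cell-type
contingency this gives p = 0.000411, and the enumeration is checked against
`stats::fisher.test` in the tests.

## The synthetic study

The generator defines the package's study conditions; one seed determines
every output. The default configuration emulates a single-guide ABE8e
experiment at desk scale: a 20-kb uniform-i.i.d. contig; eight planted
sites — one on-target (80% editing at the targeted A6, 15% at A4, 10% at
A10, mirroring the editing-window pattern of adenine editors), two hot
off-targets (56% and 21% at A6), a weak multi-tool site (8%), and four
unedited sites including bulged and empirically rare ones; dsODN abundances
dominated by the on-target site (500 vs 180/60/10/2); thirteen nomination
sources — one empirical marker, ten cut-site predictors with detection
probabilities 0.5–1, positional jitter SD 0–3 bp, Poisson false-positive
loads 2–40 and three of them rank-less, plus two editing predictors; five
editor-treated replicates, two no-editor controls at mean depth 400; and
one heterozygous A>G germline SNP at the targeted position of an unedited
site, present in cases and controls.

Choices that keep the planted truth well-defined, all fixed at design time:

* **Central bulges with rejection sampling.** An edge-proximal bulge can be
  rewritten as one or two mismatches at equal alignment score, and adjacent
  mismatch pairs can be rewritten as an indel pair at better score, so
  "recovered exactly as planted" would be ill-posed. Bulges are planted in
  the central third of the spacer and each site is re-drawn until the
  aligner's optimum in the site's real window equals the configured
  structure.
* **Protected positions.** Spacer positions carrying planted edits or SNPs
  are excluded from mismatch planting, so the reference base at those
  positions is always the edit source and truth-set membership does not
  depend on the seed.
* **Clear threshold separation.** The weakest edited site uses 8%: at depth
  400 the probability of a replicate falling below the 5% call threshold is
  ~1%, so the four-locus truth set is stable across seeds. A site planted
  *exactly at* the 5% boundary is called edited in only about half of
  replicates per eligible position — an unavoidable property of an unbiased
  frequency estimate at an inclusive threshold, not a defect of the caller
  — which is why the package's statistical checks assert rule fidelity and
  estimation accuracy at the boundary rather than a deterministic call.
* **Sites separated by more than two flanks** so alignment windows never
  overlap and no secondary hits confound the closed loop.

What the generator does *not* model — sequencing error, PCR duplicates, UMI
structure, mapping ambiguity, non-uniform genomic composition — bounds what
green tests mean: they demonstrate the correctness of the statistical
machinery on its stated input contract, not robustness to upstream
artifacts, which belongs to the aligner and library-prep QC.

Problem sizes used in the checked examples (eight sites, 13 sources, depth
400–1000, 500-replicate recovery studies, ≤40-bp oracle windows) were
chosen to exercise every code path at desk scale.

## Known limitations

* The windowed re-alignment assumes the nominating tools put a cut within
  `flank` of the true protospacer; it is not a genome-wide search.
* Bulged protospacers cannot carry planted per-position edit frequencies in
  the generator (the bookkeeping assumes a colinear protospacer); the
  quantifier itself handles any site given its interval.
* `select_panel` warns and truncates lowest-ranked empirical sites if they
  alone exceed `panel_size`; a real design would renegotiate the panel.
* Indel calling and Sanger-trace analysis are out of scope.
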