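# crispanel

Genome-wide surveillance of off-target base editing needs two computational
steps that no single upstream tool provides: (1) merging heterogeneous
off-target *nominations* — empirical cut-site marking assays
(GUIDE-seq-style dsODN incorporation) and in-silico predictors that disagree
wildly in call counts, score scales and coordinate conventions — into one
ranked, annotated candidate list from which a targeted amplicon panel can be
built, and (2) quantifying, per protospacer position, how often the
programmed base conversion (e.g. A→G for the adenine base editor ABE8e)
actually occurred in aligned amplicon reads, with germline SNPs masked
against no-editor controls.

`crispanel` implements both, for people running preclinical off-target
safety assessment of base-editor products in primary cells.

## What it computes

**Panel design.** Nominated cut positions from all sources are clustered by
a seed-anchored greedy sweep (records within `window` bp of the cluster's
first record join it; diameter ≤ 2·window). The sgRNA spacer is re-aligned
semi-globally within ≤100 bp of each cluster representative, on both
strands, allowing up to 2 unpaired bases (DNA bulge = extra genomic base,
RNA bulge = extra spacer base) with scoring `match +1, mismatch −1, gap −2`
and a `+3` bonus for placements whose flanking bases match the PAM pattern
(IUPAC). Per-source raw scores are Z-standardized across clusters
(`z = (x − x̄)/s`, sample SD; score-less or constant sources contribute
z = 0), averaged per cluster, min–max rescaled to [0, 1], and the spacer–
protospacer Levenshtein distance (PAM excluded) is computed by full dynamic
programming. Each cluster's panel priority is a sum of user-editable
criterion weights (per-source detection, per-sample detection, exon/intron/
oncogene/user-feature overlap, Levenshtein ≤ threshold); the panel takes
every empirically marked site first, then sites supported by ≥ `min_tools`
in-silico sources in rank order, with an exclusion list for primer-
incompatible amplicons.

**Edit quantification.** From coordinate-sorted BAM or a plain pileup TSV,
per-position A/C/G/T counts are reported in spacer orientation
(reverse-strand sites complemented), positions whose reference base equals
the edit source and whose coverage ≥ `min_coverage` are eligible, and a site
is called edited iff any eligible position's destination-base frequency is
≥ 5% (inclusive). Positions where any no-editor control shows the
destination base at ≥ 5% are SNP-masked. A locus enters the truth set iff it
is called edited in ≥ 3 replicates.

**Method comparison.** Bray–Curtis dissimilarities on min–max-normalized
score profiles (absent site = true zero), principal-coordinate analysis,
top-10 Kendall tau-b rank concordance, per-sample precision/recall against
the truth set, and an exact two-sided Fisher test (full hypergeometric
enumeration) for cell-type contrasts.

A seeded generator (`sim_config()`, `run_simulate()`) plants protospacers
with known mismatch/bulge structure, heterogeneous nomination tools, and
binomial per-position edit signals, so the whole pipeline is testable
end-to-end without any external data.

## Worked example

```r
library(crispanel)

cfg <- sim_config(seed = 1, noise_free = TRUE)   # planted ground truth
sim <- simulate_reference_and_sites(cfg)
recs <- simulate_nomination_tables(cfg, sim$truth)

res <- run_integrate(recs, sim$reference, cfg$spacer, cfg$pam,
                     panel_size = 8, min_tools = 6)
res$panel[res$panel$panel_tier != "unselected",
          c("final_rank", "chrom", "start", "strand", "levenshtein",
            "weight_sum", "panel_tier")]
```

```
  final_rank chrom   start strand levenshtein weight_sum panel_tier
1          1 chr_sim  2222 +                0         18 empirical
2          2 chr_sim  4444 +                1         18 empirical
3          3 chr_sim  6669 -                2         18 empirical
4          4 chr_sim 13332 +                3         16 empirical
5          5 chr_sim 15557 -                4         16 empirical
6          6 chr_sim  8888 +                3         14 multi_tool
7          7 chr_sim 11113 -                4         12 multi_tool
8          8 chr_sim 17776 +                4         12 multi_tool
```

All five dsODN-marked sites (any `empirical` evidence) rank above the
in-silico-only sites and enter the panel first; `weight_sum` is the summed
criterion weights (e.g. rank 1: empirical source +3, ten cut-site tools and
two editing predictors +12, two samples +2, Levenshtein 0 ≤ 4 +1 = 18), and
`levenshtein` is the planted spacer–protospacer divergence, recovered
exactly.

Quantifying editing at the on-target site of a noisy simulation:

```r
cfg <- sim_config(seed = 1001)
sim <- simulate_reference_and_sites(cfg)
piles <- simulate_edit_pileups(cfg, sim$truth, sim$reference)
ec <- run_editcall(piles[grep("^rep_", names(piles))],
                   piles[grep("^control_", names(piles))],
                   sim$truth, "A>G")
ec$truth
#> <truth_set: 4 locus/loci (>=5% edit in >=3 of 5 replicates)>
ec$truth$loci
#> [1] "off_hot1"  "off_hot2"  "off_multi1" "on_target"
```

The heterozygous A>G SNP planted at the `off_rare` locus is detected in the
no-editor controls and masked, so it never enters the truth set.

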