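---
title: "ccscan: methods, parameter choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ccscan: methods, parameter choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccscan)
```

# The problem

Small, closed wildlife populations with a heritable disease burden pose a
statistical problem that neither GWAS nor classical selection scans solve
cleanly: a dozen affected individuals, modest sequencing depth, a
cross-species reference genome, and strong genome-wide drift. `ccscan`
implements the pragmatic strategy used in such studies — empirical
percentile genome scanning with three complementary statistics, backed by
careful filtration — for a three-cohort design: cases, same-island
controls, and a diverged second-island population as an outgroup control.
Because real cohorts of this kind cannot ship with a package, a
synthetic-cohort generator with known truth is a first-class module, and
every claim the package makes about itself is a claim about what it
recovers from that stated world.

# Filtration model

Cross-species alignment (fox reads on a dog reference, in the motivating
design) produces two characteristic artifacts: apparent SNVs in
collapsed paralogs or copy-number-variable regions, visible as per-call
depth far from the individual's genome-wide mean, and noisy calls at low
genotype quality. The filter applies, in order:

1. per call: missing if DP < 60% or > 250% of that sample's mean depth.
   The mean is computed **once over all input sites** and carried with
   the filtered matrix, which makes the filter exactly idempotent;
   boundary calls (exactly 60%/250%) are retained because the rule is
   stated as a strict inequality.
2. per call: missing if GQ < 20 (strictly).
3. per site: dropped if the call rate over surviving calls falls below
   0.95, or the MAF over surviving called alleles falls below 0.01. MAF
   is computed after call-level masking — the order the rules are listed
   in is the order they run. A site with no surviving calls fails the
   MAF rule only when a positive MAF threshold is in force, so the
   all-thresholds-off configuration is the exact identity.

Ts/Tv is reported as a diagnostic: random ref/alt pairs give 0.5 by
construction (one transition among three substitution classes per
position, at a 1:2 class ratio), genuine mammalian call sets exceed 2.

# Kinship

The KING-robust estimator is used because the cohorts are drawn from two
diverged islands, and allele-frequency-based estimators are biased under
that structure. For a pair (i, j), over sites called in both:

φ̂ = 1/2 − (N_het(i) + N_het(j) − 2·N_het,het + 4·N_opp.hom) / (4·min(N_het(i), N_het(j)))

A duplicated sample gives exactly 0.5; the package validates
parent-offspring (≈ 0.25), half-sib (≈ 0.125, above the 0.0884
second-degree cutoff) and first-cousin (≈ 0.0625, below it) recovery by
pedigree simulation rather than by trusting the formula. The maximum
unrelated subset is found exactly by branch-and-bound over the related
graph (cohorts here are ≤ 32 samples; the search is feasible to 64),
with ties broken toward the lexicographically smallest ID set so results
are independent of input order. Pairs with undefined kinship (a member
with zero heterozygous calls) impose no constraint, and are warned about.

# Windowed statistics

Windows are 1-based inclusive, starting at 1, 1+step, …, with the scan
scales 100 kb/10 kb (coarse) and 50 kb/1 kb (fine). Per-site nucleotide
diversity uses the unbiased pairwise form 2c(n−c)/(n(n−1)); windowed π
divides the site sum by the window length in bp (truncated length for a
chromosome-end window). F_ST is Weir & Cockerham's θ from the 1984
variance components with r = 2 populations — a (among populations), b
(among individuals), c (within individuals), from sample sizes, allele
frequencies, and **observed** heterozygote frequencies — with the
windowed estimate the ratio of sums Σa/Σ(a+b+c). Tajima's D uses the
standard constants at a fixed n = 2 × cohort size; with the upstream
call-rate filter at 0.95 the called allele count is nearly constant per
site, and sites with missing calls contribute through their allele
frequency scaled to the fixed n (a documented approximation;
`fully_called_only = TRUE` restricts to complete sites instead).

Δ statistics are oriented control − case so the signals expected for a
disease-susceptibility region — lower diversity and an excess of rare
variants in cases — fall in the upper tail; they are signed, not
absolute (the choice the scan makes where the convention was genuinely
open). Z-scores standardize by the genome-wide mean and sample SD.

**Full-length windows only in the tails.** A truncated chromosome-end
window rests on a fraction of the evidence: at typical densities the
final 1 kb-step windows hold a handful of sites, and their π, θ and D
estimates have far higher sampling variance than the rest of the genome.
In null simulations those windows reached |z| of 13–22 in all three
statistics at once and manufactured chromosome-end "candidate regions".
The scan therefore reports raw statistics for truncated windows but
excludes them from z-standardization (their z-scores are `NA`), a
parameter-free equalization of the evidence base per window. This is the
one place the implementation deviates from treating end windows like any
other, and it is deliberate.

# Outlier intersection

Per statistic, windows at or above the empirical 99th percentile are
outliers; overlapping or abutting (gap 0) outlier windows merge into
peaks; a candidate region is the **intersection interval** of three
mutually overlapping peaks, one per statistic — the most-supported core,
rather than the union — ranked by summed peak z-maxima. Within ±150 kb
of each region, every SNV gets a single-site Weir θ ("allelic F_ST") and
the absolute case-control allele-frequency difference; selection keeps
differences strictly greater than 0.45. Nearest-gene annotation reports
basepair distance (0 inside a gene) with ties broken to the
lexicographically smaller gene name; TFBS membership is interval
containment. BED input is 0-based half-open and converted centrally; all
TSV output is 1-based inclusive. No multiple-testing correction is
applied anywhere: the procedure is empirical-percentile outlier
selection, reproduced as such.

# Runs of homozygosity

The detector follows the sliding-window method of detectRUNS: a 50-SNV
window slides one SNV at a time; a window is homozygous-classified with
at most 1 heterozygous and 2 missing calls; a SNV is in-run when at
least 5% of the windows covering it are homozygous-classified (edge SNVs
are covered by fewer windows and the denominator accounts for that).
In-run stretches split at inter-SNV gaps over 100 kb and must contain
≥ 2 SNVs, span ≥ 100 kb, and carry ≥ 1 SNV per 50 kb. Run coordinates
are SNV-delimited (first to last member). These defaults are a
deliberately permissive small-population configuration, meant to be run
on an LD-pruned call set (the strong r² > 0.90 prune exists for exactly
this); they are reproduced as stated, not "corrected". F_ROH divides
total run length by the SNV-map length (per-chromosome first-to-last
span). Sharing tracks report, per SNV and cohort, the fraction of
members whose run covers it; candidate ROH regions are stretches with
case sharing > 0.75 and each control cohort < 0.75 (the separate 70%
reporting threshold is a parameter, not a default).

Window-based callers blur tract edges: a tract-interior SNV needs ~3 of
its ~50 covering windows fully homozygous, so recovered boundaries sit a
few SNV spacings inside the planted tract. Tests assert ≥ 85–90%
overlap rather than basepair-exact edges for that reason.

# PCA

Dosages at pruned, putatively neutral sites are centered by 2p̂ and
scaled by sqrt(2p̂(1−p̂)) (the PLINK variance-standardized convention),
missing values mean-imputed, and the sample covariance
eigendecomposed. The sign convention — largest-magnitude loading
positive per component — makes output deterministic and sample-order
invariant up to sign.

# The synthetic world

`simulate_study()` draws ancestral frequencies from Uniform(0.05, 0.95)
and island frequencies from the Balding–Nichols beta model with a single
drift parameter F; cases and same-island controls share island-A
frequencies, the second island follows its own. Genotypes are
Binomial(2, p); depth is Poisson (default mean 10); GQ = min(99,
round(10·DP/3)), a crude but monotone-in-depth model sufficient to
exercise the GQ < 20 rule; missingness is injected last (default 2%).
Cohort-size defaults are 12 cases, 11 same-island controls, 9
second-island controls. Positions are uniform without replacement per
chromosome; no mutation-rate or recombination realism is claimed.

**Planted causal loci carry a footprint.** A selected haplotype drags
linked variation; a frequency shift at one isolated SNV among ~100 per
window is invisible to windowed statistics, and a generator whose
planted signals cannot be detected by the method it is meant to test
would be useless. Each planted locus therefore shifts the focal SNV by
exactly `causal_delta` (direction away from the nearer frequency
boundary; infeasible ancestral draws are retried a bounded number of
times, then error) and shifts neighbors within ±`causal_width_bp`/2 in
the same direction, clamped to [0, 1]. The default width, 50 kb, is on
the order of the LD-decay scale (~40 kb) measured in the motivating
island populations, and equals the fine scan window. Truth tables record
the focal position only. Planted ROH tracts overwrite carriers with
homozygous genotypes drawn from the island frequency — autozygous, not
artificially fixed — before missingness injection.

What the generator does **not** emulate: linkage disequilibrium between
background sites (each site is drawn independently), realistic site
frequency spectra (no mutation/coalescent model), depth overdispersion
or batch structure, reference bias, or the bottleneck demography of real
island populations. A green end-to-end test therefore establishes that
the pipeline recovers window-scale frequency-shift signals and planted
autozygosity at the stated cohort sizes and noise levels — not that it
would have equal power against a coalescent-realistic genome. Null
simulations do capture the key difficulty, shared sampling noise across
the three statistics, which is what makes their triple intersection
informative.

# Numerical and degenerate-input choices

- Per-site θ is `NA` where a + b + c = 0 (e.g. monomorphic overall);
  such sites contribute zeros to window sums. θ can legitimately be
  negative at undifferentiated sites.
- Tajima's D is `NA` for windows with S = 0 or a non-positive variance
  term.
- `z_transform()` errors on fewer than 2 finite values or zero SD rather
  than returning all-NA.
- LD pruning drops the later site of an offending pair (position order),
  iterating within each window until clean — deterministic and
  order-stable; missing dosages are handled pairwise-complete, never
  imputed.
- The LD-decay crossing distance is the midpoint of the first bin whose
  mean r² is below threshold with every later informative bin also
  below; empty bins are not allowed to declare a crossing.
- `max_unrelated()` explores vertices in lexicographic order,
  include-first, so the first maximum found is the lexicographically
  smallest — a documented tie rule, not an accident of storage order.
- Kinship for a pair whose minimum heterozygote count is zero is
  undefined (`NA`), warned, and non-constraining.

# Known limitations

- The generator's independence between sites means LD-based operations
  (pruning, decay) are exercised on purpose-built correlated fixtures in
  the tests, not on the simulator output.
- Tajima's D with missing data uses the fixed-n frequency-scaling
  approximation described above.
- The exact maximum-unrelated search is exponential in the worst case;
  it is intended for cohort-scale inputs (≤ 64 samples).
- The "multiple r²" strong-prune of the original tooling is realized as
  pairwise `--indep-pairwise` semantics with r² = 0.90, the variant the
  pipeline actually cites; multi-locus regression pruning is not
  implemented.
- Pooled-control scans (case vs both control cohorts) are supported by
  passing several labels to `control`; pooling is the union of cohort
  members, the one unambiguous reading.
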