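---
title: "Methods and models behind transevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind transevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

transevo implements the statistical core of a comparative-evolution
workflow for de novo assembled transcriptomes: assembly-integrity
assessment through ortholog coverage, proportion-based differential
expression for count libraries, repeat (mobilome) summarization and
cross-species transposable-element (TE) activity, outlier-based detection
of gene-family expansions, and lineage-rate / selection analyses on 1:1
ortholog alignments. This vignette states each method's model, the
package's parameter defaults and why they were chosen, what the synthetic
data generators emulate, and the numerical conventions used. Nothing here
is an empirical claim about any particular organism; all quantitative
statements are properties of the algorithms, verified by the package's
test suite on synthetic data.

## Data model and synthetic generators

Every analysis consumes plain, text-based formats: FASTA sequence sets,
12-column tabular similarity-hit files, RepeatMasker-style `.out`
annotation files, count matrices with transcript lengths, per-species
protein-domain count tables, and aligned FASTA blocks. The
`synthetic_data` module generates all of them with known ground truth so
each downstream method can be validated end to end without external data.
All generator randomness is a pure function of a `sim_config()` object,
including its seed.

- **Transcript lengths** are log-normal (`meanlog = log(1200)`,
  `sdlog = 0.6`) floored at 250 nt. The floor mirrors the common assembler
  convention of discarding very short contigs; the log-normal shape gives
  the heavy right tail typical of assembled transcript length
  distributions.
- **TE-derived transcripts**: a configured fraction of transcripts per
  class (default LINE 3%, SINE 1%, LTR 2%, DNA 1.5%) receives one
  contiguous segment copied from a small packaged synthetic consensus
  library; the planted interval is emitted both as a masking-style hit
  table and as truth.
- **Count matrices**: true proportions are drawn once from a log-normal
  and normalized; planted fold changes multiply group-2 proportions (then
  renormalize). Per sample, proportions receive a Beta perturbation with
  dispersion `rho` and counts are drawn from one multinomial at the exact
  configured library size, so column sums are exact by construction. The
  default `overdispersion = 1e-4` gives a between-library biological
  coefficient of variation near 0.3 for a median-expression transcript
  (relative SD ≈ sqrt(rho/p) for small p), typical of bulk RNA-seq
  replicates; much larger values imply implausibly volatile replicate
  libraries for all but the most abundant transcripts.
- **Protein alignments** evolve i.i.d. sites down a branch-length tree
  under an equal-exchangeability 20-state process (a Jukes–Cantor
  analogue on amino acids): along a branch of length `d` a site differs
  from its parent with probability `(19/20)(1 − exp(−20/19 d))`.
  Per-lineage rate multipliers scale terminal branches, planting the
  asymmetries the relative-rate test is meant to find.
- **Domain tables**: reference-species counts per domain are negative
  binomial with a shared, domain-specific mean; planted expansions
  multiply the focal species' mean.
- **Ortholog hit tables**: reciprocal hit pairs where a configured
  fraction of "assembled" sequences covers only a sub-interval of the
  reference ortholog, making the planted truncation fraction recoverable
  from the coverage distribution.

## Assembly integrity: ortholog hit ratio

For a transcript hitting its reciprocal-best ortholog over subject
coordinates `[s_start, s_end]` in a reference gene of length `L`, the
ortholog hit ratio is `OHR = (s_end − s_start + 1)/L`, capped at 1. Best
hits minimize e-value, break ties by maximal bit score and then by
lexicographically smallest subject id, so results are deterministic.
`integrity_summary()` restricts to pairs with percent identity strictly
above 90 (coverage of divergent pairs conflates truncation with
divergence) and reports the share with OHR ≥ 0.8, the conventional
full-length threshold.

## Expression

**TPM.** Counts are divided by effective length and rescaled per sample to
sum to 10^6, making values proportional to relative molar concentration
and comparable across depths.

**Weighted-proportions test.** For a transcript with counts `y_i` in
libraries of size `n_i`, each group is summarized by the depth-weighted
proportion `p̂ = Σ w_i p_i` with `w_i = n_i/Σn`. Its variance combines a
known binomial component `p̂(1−p̂)/Σn` with a method-of-moments estimate
of the between-library (beta-binomial) variance. Because the
beta-binomial model assumes a single overdispersion, the between-library
estimate is pooled across the two groups with `k1 + k2 − 2` degrees of
freedom. The statistic is the difference of weighted proportions over the
pooled standard error. With one library per group the test reduces
exactly to the unpooled two-proportion z-test. With replicates, a t
reference is used whose Satterthwaite-style degrees of freedom let only
the *estimated* overdispersion component consume degrees of freedom — the
binomial part is known, so when sampling noise dominates the reference
approaches the normal, and when overdispersion dominates it approaches a
pooled t with `k1 + k2 − 2` df. This construction holds its nominal
type-I error (verified at 0.05 under a beta-binomial null with ρ = 0.05,
3 vs 3 libraries) *in the regime where the mixing Beta is unimodal*, i.e.
null proportion above ρ/(1−ρ). For much rarer transcripts the mixing
density piles up at zero and any normal-theory reference is conservative;
the package documents rather than masks this limitation.

**Differential expression.** A transcript is called differentially
expressed iff |fold change| ≥ 2 *and* Bonferroni-corrected p < 0.01. The
fold change is the ratio of group weighted proportions with a
pseudo-proportion floor of 1/(total library size) guarding zeros (flagged
in the output). Only transcripts with a total count of ≥ 10 across all
samples are tested, and only that universe enters the Bonferroni factor.

**Enrichment.** Annotation terms are scored by the upper-tail
hypergeometric probability `P(X ≥ q)`; a term is over-represented only
when p < 10^-5 and the observed count strictly exceeds 5 — deliberately
strict cutoffs for exploratory screens over many terms.

**Sample clustering.** Samples are clustered by average linkage on
`d = 1 − Pearson cor` of square-root-transformed expression. Support
values are ordinary bootstrap proportions from gene resampling: each
replicate resamples genes with replacement, reclusters, and the
percentage of replicate trees containing each sample bipartition is
attached as the node label.

## Mobilome

`parse_repeatmasker_out()` reads the whitespace-delimited masking dialect
(three header lines, ≥ 14 columns), normalizes complement-strand
coordinates, and splits class/family on the first `/`; raw class labels
map onto a fixed vocabulary through a packaged, editable table.
`summarize_repeat_hits()` counts elements raw (unmerged) but merges
overlapping same-class intervals per transcript for base-pair totals; for
the distinct masked-base total, cross-class overlaps are attributed to
the higher-scoring hit. `repeat_summary_table()` assembles the
conventional summary layout: a retroelement total (SINE + LINE + LTR), a
total-interspersed row (retroelements + DNA transposons + unclassified),
and percentages of the scanned length rounded *half away from zero* to
two decimals (the convention of masking summary tables, unlike R's
round-half-even; a tiny epsilon guards binary-representation artifacts
such as `1.005 × 100 = 100.4999…`).

Candidate repeat libraries from de novo discovery are filtered by
`filter_repeat_library()`: candidates matching a reference proteome or
carrying any protein domain are removed *unless* one of their domains is
TE-related (reverse transcriptase, integrase, transposase, …), which
re-includes them; candidates not strictly longer than 100 nt are dropped
regardless.

Cross-species TE activity cannot be compared on whole-transcriptome TPM
because transcriptome size and annotation differ between species.
`calibrated_te_activity()` instead computes the per-million scaling
factor on a reduced transcriptome of shared unambiguous orthologs:
`S = Σ count/length` over the calibration set, and each element's
activity is `10^6 (count/length)/S`. Activities are invariant to library
rescaling by construction.

## Gene-family expansions

Protein sets are first reduced by `cluster_reduce()` (greedy longest-first
clustering at a global-alignment identity threshold, default 0.75) so that
re-assembled fragments do not inflate counts. For each domain with at
least 20 focal-species members, `scan_expansions()` applies a one-sided
Grubbs test of the focal count against each reference-species group: with
`N` values (focal plus references), `G = (focal − mean)/sd`, and the
critical value is the classical `((N−1)/√N) √(t_α² / (N−2+t_α²))`. The
reported p is the exact per-observation tail
`P(T_{N−2} ≥ t)` with `t = sign(G) √(N(N−2)G² / ((N−1)² − NG²))`, which is
consistent with that critical value (`G > critical ⇔ p < α`). A
per-observation rather than maximum-order-statistic p is appropriate here
because the tested species is fixed a priori — the question is "is this
species' count an outlier?", not "is any count an outlier?" — and it makes
the null false-positive count per table ≈ α × tests, which the acceptance
suite verifies. A domain is called expanded only when the focal count is
the maximum and p < α in *every* reference group (the intersection).

## Lineage rates and selection

**1:1 orthologs.** `select_121_orthologs()` keeps only reciprocal best
hits that are unambiguous in both directions: any tie (equal e-value and
bit score for different subjects) disqualifies the gene, because
co-orthologs make rate attribution ambiguous.

**Column filtering and concatenation.** `filter_columns()` removes
alignment columns whose fraction of gaps/ambiguous residues exceeds a
threshold (default 0 — resolved columns only) and re-indexes the gene
partition; `concatenate_blocks()` joins blocks by taxon name into a
supermatrix with a partition map.

**Relative-rate test.** For ingroups A, B and outgroup O, sites where all
three states are resolved are classified: `m1` counts sites with A unique
(A ≠ B, B = O) and `m2` sites with B unique. Under equal rates
`m1 ≈ m2`, and `χ² = (m1 − m2)²/(m1 + m2)` is referred to a 1-df
chi-square (p = 1 when `m1 + m2 = 0`). Gaps and ambiguity codes
(`X B Z J U O - . *`) exclude a site entirely.

**Ka/Ks.** `kaks_counting()` implements a counting (Nei–Gojobori-style)
estimator: per codon, synonymous site fractions are computed over all
three positions (mutations to stop codons count as non-synonymous);
observed differences are classified by averaging over substitution
orders, excluding paths through stop codons (falling back to all orders
only if every path is blocked); proportions receive the Jukes–Cantor
correction `−3/4 ln(1 − 4/3 p)`, returned as `NA` at saturation
(`p ≥ 3/4`); ω = Ka/Ks is `NA` when Ks = 0. A counting estimator is
transparent and fast at desk scale; it is *not* a maximum-likelihood
estimator and output is labelled accordingly.

**Motif scanning.** `count_motif()` counts possibly overlapping
occurrences of a fixed-width motif given in `x`-wildcard notation
(default `C[ND]PxxDPxC`) using a lookahead regular expression.

## Numerical conventions and limitations

- Percentages in summary tables round half away from zero to 2 decimals;
  everything else keeps full double precision.
- All tie-breaking in best-hit selection is total and deterministic.
- Monte-Carlo test sizes in the suite use 3-standard-error binomial bands
  around nominal values.
- The replicated proportions test is conservative for transcripts whose
  expected proportion is below ρ/(1−ρ) (see above); the single-replicate
  z-form assumes pure within-library binomial sampling and will flag
  overdispersion as signal — which is why the package verifies its power
  under multinomial sampling and its type-I error separately under the
  replicated beta-binomial null.
- The amino-acid evolution model is an equal-exchangeability caricature:
  adequate for validating site-pattern counting, not for inference about
  real substitution processes.
- `evolve_alignment()` applies rate multipliers to terminal branches
  only; internal-branch rate shifts are out of scope.
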