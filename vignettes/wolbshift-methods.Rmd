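---
title: "Methods: strain detection, sharing tests, divergence dating and the CI/MK screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain detection, sharing tests, divergence dating and the CI/MK screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wolbshift)
```

# Scope and model

`wolbshift` implements an inference chain for endosymbiont strain
dynamics in host resequencing data. The chain runs: dereplicate a panel
of symbiont reference genomes into strains; competitively map each host
library against the panel and decide which strain(s) infect each
specimen; test whether host sister-species pairs share strains more than
random pairings do; convert strain consensus divergences into split-time
ranges and compare them with host split times; estimate the rate at
which strains are gained and lost; and screen strain genomes for
cytoplasmic-incompatibility (cifA/cifB) and male-killing (wmk) candidate
loci. Every stage is backed by a synthetic-data generator with full
ground truth, so the whole chain is testable without sequencing data.

# The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
conditions under which the pipeline's properties are verified.

**Strain genomes.** `evolve_strains()` draws a random ancestor and lets
each strain accumulate `Poisson(r_i L)` substitutions at uniform
positions *with replacement*, each hit moving the base to a uniform
other base. Placement with replacement was chosen deliberately: multiple
hits (including reversions) make the realized proportion of differing
sites follow the same saturation behaviour the downstream Jukes–Cantor
correction assumes, so the simulator and the estimator share one model.
Per-lineage branch lengths `r_i` are the star-tree least-squares
decomposition of the requested pairwise distance matrix — exact whenever
the matrix is star-additive (constant matrices and two-strain cases, the
ones used throughout); a non-representable matrix triggers a warning
rather than silent distortion. Distances above 0.70 are rejected because
the Jukes–Cantor correction degenerates near saturation (it diverges at
0.75).

**Reads.** `simulate_reads()` is a single-end abstraction (pairing adds
nothing to the decisions being tested): reads of fixed length start
uniformly on the linear genome, per-strain counts are
`weight × coverage × L / read_length` rounded, and errors are
substitutions only — the heterozygous-site rule concerns substitutions,
and the mapper's ungapped model matches. Qualities are a constant "I";
no quality model is attempted.

**Host systems.** `simulate_host_system()` draws, per sister pair, a
scenario among codivergence (symbiont split = host split), horizontal
transfer (symbiont split independent of the host split, so older or
younger), introgressive transfer (symbiont and mitochondrial splits
equal and 5–50% of the host nuclear split), loss (one species
uninfected) and uninfected. Sequences evolve at a symbiont rate of
6.4e-10 subs/site/generation by default — inside the slow/fast clock
bounds used for dating, so codivergent pairs are recoverable by
construction — and a mitochondrial rate of 1.9%/My, the midpoint of the
two published bounds. Two species are recorded as sharing a strain when
their simulated symbiont divergence is below the 99%-ANI dereplication
radius (total divergence < 0.01), which is exactly the criterion the
detection side applies.

**Turnover histories.** `simulate_turnover_history()` uses an
infinite-strains event model: gains/losses arrive as a Poisson process
along each pair's branch length and every event leaves one distinct
strain-set difference. This makes the symmetric-difference estimator
unbiased, which is the property the recovery suite checks; repeated
events on the same strain (which would make the estimate a lower bound,
as with real data) are deliberately out of the generator's scope.

**Hit tables.** `simulate_hit_tables()` plants operons, orphan cif
genes and wmk copies as genes along a contig, with a filler gene between
planted elements so operon partners are adjacent and nothing else is;
every decoy violates exactly one screening criterion (e-value, query
coverage, reciprocal identity, annotation overlap, or strand), recorded
in the truth table.

What the generator does *not* emulate: indels and structural variation,
quality-score error profiles, GC or coverage bias, contamination,
within-strain polymorphism, and host demography. Passing tests therefore
demonstrate the decision logic under its own assumptions, not robustness
to those artefacts of real libraries.

# Dereplication and ANI

`fragment_ani()` cuts the query into consecutive 1000 bp fragments
(final partial fragment dropped — keeping it inflates identity on short
tails), anchors each fragment in the reference by shared 15-mers and
scores the best ungapped placement; a fragment is "aligned" when its
identity reaches 80%. ANI is the mean identity of aligned fragments and
is asymmetric, so clustering tests both directions and requires
ANI > 99% both ways with min(MAF) ≥ 0.90 — a conservative, symmetric
reading of the thresholds. Clustering is greedy on genomes sorted by
decreasing length (ids ascending on ties), so the representative is
always the longest member and the result is independent of input file
order. The fragment length, seed size and identity floor are
configuration, not constants; 1000 bp gives 20 fragments at the 20 kb
test scale and is accurate to within 0.5 ANI points of the realized
identity up to 5% divergence (verified against full dynamic-programming
alignment in the test suite).

# Competitive mapping and strain assignment

The mapper is a deliberate simplification of a general-purpose aligner,
with the one contract the decision algorithm relies on: each read gets
its single best placement across all references (lowest ungapped edit
distance; ties to the earlier reference, then the leftmost position),
and is unmapped above 10% divergence of its length. Candidate placements
are anchored by 25-mer seeds, seven per read, and a placement must
collect at least three concordant seed hits to be evaluated. The
seed-vote minimum is what makes mapping sensitivity decay with
divergence in a controlled way: at 3% divergence (the scale separating
panel strains) enough seeds stay intact for cross-mapping — which is
what exposes coinfections as heterozygous sites — while at ~8%
divergence (a strain absent from the panel) so few reads map that
breadth falls below the 90% infection threshold and the sample is
flagged ambiguous instead of being assigned a wrong strain. An
any-seed policy cannot produce both behaviours at 150 bp reads.

A site is heterozygous when two or more bases each have ≥ 2 supporting
reads (robust to singleton sequencing errors; at 0.5% error and 25×
the expected het density stays far below threshold). The het threshold
is applied per reference genome in the current set. "Almost no mapped
reads" is quantified as best breadth < 0.10. Iterative assignment adds
panel genomes in screening order while any current reference shows
het density > 10 sites/kb, then tries the first+last shortcut when three
or more genomes accumulated; if the ranking is exhausted with het still
high the sample is reported infected with an `unresolved_coinfection`
flag rather than silently resolved. Consensus calling is majority-base
at depth ≥ 3 with ties going to the reference base — deterministic and
dependency-free, adequate at the 99%+ identities where it is used.

Coordinates are 0-based half-open internally; file exports are 1-based.

# Sharing statistics

The permutation null re-pairs the filtered species uniformly at random
into disjoint pairs (shuffle-then-chunk is uniform over perfect
matchings), with 30,000 replicates by default and the observed value
included as one replicate, so the empirical p never falls below
1/n_reps. The three filters (all pairs / at least one infected / both
infected) are one parameter; headline reporting uses both-infected. For
the mean-ANI statistic, pairs with an undefined value (no cross
occurrences after excluding shared strains) are skipped rather than
scored 0, and per-pair statistics are precomputed for all species pairs
so each replicate is a single indexing step.

Calibration is verified two ways, and the choice is worth recording:
uniformity of the p-value under a permuted-occurrence null (KS test over
200 simulated datasets) is checked with the *mean-ANI* statistic, which
is continuous; the shared-count statistic is integer-valued, and its
empirical p is valid but conservative under ties — a two-sided KS test
against the uniform would flag that discreteness as a failure even
though the test is correctly calibrated in the sense that matters
(P(p ≤ α) ≤ α, which is checked separately for shared counts). The
type-I error rate at α = 0.05 over 500 nulls uses the continuous
statistic for the same reason. Calibration replicates use smaller
`n_reps` (1000–2000) than the 30,000 default; `n_reps` is a free
parameter of the test and the default is unchanged.

Prevalence intervals use the Wilson method — a deliberate choice where
the source of the convention is silent; Wilson behaves sensibly at the
0/n and n/n boundaries that occur in real prevalence tables.

The sharing model is a Bayesian logistic regression fitted by random-walk
Metropolis (60,000 iterations, 10,000 burn-in, thinning 10; proposal
scales adapted during burn-in only, so the kept chain is a valid
fixed-kernel sample). Priors are Normal(0, 5²) on standardized
coefficients — weakly informative, and they regularize the
quasi-separation that small pair tables produce (a warning is emitted
when an unpenalized fit degenerates). Coefficients are reported on both
the standardized and the raw scale; pMCMC is twice the smaller tail
probability around zero.

# Divergence dating and turnover

Distances are `1 − ANI/100` (or direct p-distances with N/gap sites
excluded), Jukes–Cantor corrected, then converted to time ranges using
the slow and fast clock bounds. Two open choices are resolved as
follows:

* **Divergence factor.** Clock rates are per lineage, and divergence
  accrues on two branches, so the default converts distance to time as
  `d / (2 r)`. The factor is configurable (`divergence_factor = 1`)
  and logged, because published range figures elsewhere may correspond
  to the single-branch convention.
* **Corrected vs uncorrected distance for the mitochondrial clocks.**
  The mitochondrial rates are defined on uncorrected distance, yet the
  literal published procedure applies them after Jukes–Cantor
  correction. `mito_split_range()` takes whatever distance the caller
  passes; the pipeline passes the corrected one (the literal
  procedure), and passing the uncorrected value gives the internally
  consistent alternative. At the < 5% distances involved the difference
  is below 4%.

Year conversion combines the generation-range bounds with the 1–3
generations/year bounds into the widest defensible interval. Congruence
classification (containment of the narrower range, or the wider range's
midpoint inside the narrower; otherwise older/younger by midpoints,
exact midpoint equality counting as congruent) is verified against a
12-case hand truth table.

The turnover estimator counts strain-set symmetric differences across
pairs over total branch length (`2 × split_gen` per pair by default,
same configurable factor) and reports events per million host
generations; the waiting time between events is `1/(rate × gpy)` My.
Because repeated gains/losses of the same strain collapse into one
observable difference, the estimate is a lower bound on real data; the
recovery suite therefore uses the infinite-strains generator where the
estimator is unbiased, at a total branch length giving ~800 expected
events per replicate (per-replicate sampling error ~3.5%, well inside
the 15% recovery criterion).

# The CI/MK locus screen

The screen is a filter pipeline over standard homology-hit tables
(12-column tabular plus query coverage; coverage is consumed from the
table, not recomputed) and gene annotations. Thresholds are strict
inequalities as published: e-value < 10⁻²⁰ AND query coverage > 60%.
Reciprocal confirmation requires the top reciprocal hit (lowest
e-value, ties by bit score then subject id) to belong to the
originating family. Annotation concordance requires a same-contig,
same-strand gene overlapping at least half the hit span. "Consecutive"
cifA+cifB is operationalized as adjacent predicted genes — same contig
and strand, no intervening gene of any strand, no base-pair gap limit —
with greedy left-to-right pairing so each gene joins at most one operon.
An open-reading-frame integrity check (no internal stop codon) runs only
when the genome sequence is supplied. Whether query coverage should be
per-hit or per-query-across-hits is unstated in the source material;
per-hit is the declared contract here. The search step itself (TBLASTN/
BLASTX) is external: the module owns the format contract, so all logic
is testable from tables alone.

# Problem sizes, determinism and limitations

Property suites run at 20 kb genomes, 25× coverage, 150 bp reads, and
0.2% error, with a 6-strain panel and 20-sample panels (4 uninfected,
8 single, 8 dual infections); dual infections use strains 2.5–6%
diverged. The panel floor of ~1% divergence between strains is a
boundary by construction: at exactly 1%, the expected heterozygous-site
density of a balanced mixture equals the 10 sites/kb decision threshold,
so mixtures are simulated away from that knife edge. Permutation
calibration uses 16-species/24-strain occurrence matrices. Every
simulation consumes an explicit integer seed, identical seeds give
byte-identical outputs, and `run_pipeline()` writes a log with seeds and
thresholds so each reported number is traceable.

Known limitations: no indel or quality-aware handling anywhere in the
chain; the mapper reports one best placement and no mapping-quality
model; dereplication representative choice is by length, not by a
quality score; the sharing model's sampler is a simple Metropolis
random walk (adequate for 4 coefficients, not general); and the
congruence rules inherit the coarseness of range-overlap reasoning —
wide clock bounds make "congruent" easy to satisfy, which is a property
of the bounds, not of the data.
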