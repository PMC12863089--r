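---
title: "Methods: paralog surveys, Pfaffl quantification and PHBV composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralog surveys, Pfaffl quantification and PHBV composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

halopha bundles the three computational workflows used to characterize
multi-paralog PHA synthase systems in halophilic archaea: a
comparative-genomics survey of PhaC/PhaE homologs, efficiency-corrected
RT-qPCR quantification, and polymer/medium composition arithmetic. This
vignette documents the models behind each module, the tunable
parameters and their defaults, the design decisions taken where the
methodology was genuinely open, and what the synthetic-data generators
do and do not emulate.

## The paralog survey

### Alignment model

`local_align()` computes the optimal Smith–Waterman local alignment
under affine gap penalties, delegating the dynamic programming to
`Biostrings::pairwiseAlignment` and deriving BLASTp-style tabular
statistics from the optimal alignment. Defaults are the BLASTp protein
defaults: BLOSUM62, gap open 11, gap extend 1 (a gap of length *k*
costs 11 + *k*). Percent identity is computed over alignment columns
*including* gaps (identities / alignment length × 100), the convention
of BLAST's tabular `pident`; `mismatch` counts aligned non-identical
residue pairs and `gapopen` counts gap runs in either sequence.

Bitscores use the Karlin–Altschul transform
S' = (λS − ln K)/ln 2 with the gapped BLOSUM62(11,1) constants
λ = 0.267, K = 0.041; e-values are E = m·n·2^(−S') with *n* defaulting
to the total residue count of the searched proteomes. Because
classification operates on percent identity and ranking on bitscore — a
strictly increasing function of the raw score — neither the constants
nor the database-size choice can change any call. Alignments with
non-positive score, or below `min_pident` (default 25 %), are not
reported.

The test suite fuzz-compares the aligner against an independent
exhaustive Gotoh dynamic-programming oracle on hundreds of random pairs
of length ≤ 30, so the delegation is continuously verified rather than
assumed.

### Search, deduplication, classification

`search_homologs()` aligns one reference against every subject and
keeps at most `max_targets` (default 4) hits per species, ordered by
descending bitscore with ties broken by ascending subject accession.
`deduplicate_hits()` collapses hits identical on
(sacc, pident, length, mismatch, gapopen, evalue, bitscore) within one
reference class — a documented 7-field key; it is idempotent and its
output is always a subset of its input.

`classify_organism()` retains, per reference class, the single
highest-scoring unique hit for the organism (bitscore, then pident,
then accession) and assigns the organism to the class whose retained
hit has maximal percent identity. A call is **strong** when the best
identity is ≥ `weak_threshold` (default 65 %) and **weak** strictly
below it; the boundary is sharp and tested by bisection. Ties on
identity go to the higher bitscore, then to the fixed class order
PhaC_Hme, PhaC1, PhaC2, PhaC3. These tie-break rules are not part of
the underlying methodology — any rule would do — but fixing them makes
survey outputs deterministic. PhaE hits are retained for colocalization
but never compete for the paralog class.

`query_coverage()` (alignment length / reference length × 100, capped
at 100) flags truncated homologs: a PhaC2-style protein missing both
termini shows coverage near its retained fraction. `tally_profiles()`
counts, per organism, the classes with strong calls; weak calls stay
visible in the calls table but are excluded from the occurrence
tallies and histograms.

### Colocalization

`nearest_partner()` implements the distance
|start(phaC) − end(phaE)| literally, with no strand correction — the
annotated start field is used as given. This is deliberate: the
quantity is a simple proximity heuristic for phaEC operon structure,
not a promoter-aware model. An opt-in `strand_aware` mode measures to
the strand-corrected gene start instead. A pair is *colocalized* when
the partner lies within `max_distance` (default 1000 bp — a value
chosen as a conservative operon-scale distance, since no canonical
cutoff exists) on the same replicon; the raw distance is always
reported so users can re-threshold. Nearest-partner selection is
verified against brute-force enumeration of all pairwise distances.

## RT-qPCR quantification

### Standard curves and efficiencies

`fit_standard_curve()` fits Ct = b + m·log₁₀(q) by ordinary least
squares over a dilution series (≥ 3 distinct points) and reports the
amplification efficiency E = 10^(−1/m); the ideal E = 2 corresponds to
m ≈ −3.3219 cycles per decade. QC bounds — E outside (1.8, 2.1) or
r² < 0.98 — produce warnings, never failures, because marginal assays
are a judgement call for the analyst.

### The Pfaffl ratio

`pfaffl_ratio()` computes R = E_t^ΔCt_t / NF with
ΔCt = mean Ct(control) − mean Ct(sample). With several reference genes,
NF is the geometric mean over references of E_r^ΔCt_r — the
geNorm-style combination, which is the standard reading of
"geometric mean of both" reference genes; with one reference it is the
classical two-gene Pfaffl formula, and with all efficiencies exactly 2
it reduces to 2^ΔΔCt (tested to machine precision).

Three points were genuinely open and are fixed as follows:

* **Ratio spread.** Per-replicate ratios pair each *sample* biological
  replicate against the *control-condition mean*; their standard
  deviation is the reported `ratio_sd`. Pairing against the mean keeps
  the point estimate and the spread consistent when replicate counts
  differ between conditions.
* **What the t-test tests.** The p-value comes from a two-sided
  unpaired pooled-variance Student's t-test on per-replicate
  *reference-normalized Ct values* (target Ct minus the mean of the
  reference Cts), not on the ratios themselves: the Ct scale is the
  variance-stabilized scale on which qPCR error is approximately
  Gaussian. Welch's test is available behind `welch = TRUE`.
* **Normality gate.** Shapiro–Wilk runs per group; failure (p < 0.05)
  sets `normality_ok` to FALSE and warns but does not block the t-test
  — a verify-then-test workflow. Groups too small (< 3) or constant
  are flagged NA. Degenerate zero-variance comparisons are answered
  exactly (identical groups → p = 1, separated constants → p = 0)
  rather than erroring.

`absolute_quantity()` inverts a standard curve, Q = 10^((Ct − b)/m),
yielding relative template quantities that are comparable across genes
whenever the curves share a quantity unit — the transcript-level proxy
used for cross-paralog comparisons.

## Polymer and medium composition

Each PHBV monomer backbone carries exactly one methine proton, so peak
areas in the methine region are mole-proportional and
%3HV = 100·I_V/(I_B + I_V) is a mole percent; %3HB is its complement
and the two sum to 100 by construction. Default assignment windows are
5.20–5.30 ppm (3HB) and 5.10–5.20 ppm (3HV), half-open `[lo, hi)`,
following standard PHBV ¹H-NMR assignments in CDCl₃; they are a
labeling convenience and fully configurable, since integrated peak
lists (not raw spectra) are the package's input. PHA content is simply
polymer mass over cell dry weight.

`cnp_ratio()` sums assimilable elemental millimoles from a recipe
(concentration × atom count) and normalizes to phosphorus, by default
on the mass basis with IUPAC atomic masses. Two conventions in the
shipped recipes deserve note. First, the Tris buffer and mineral salts
carry zero assimilable C/N counts: a buffer is not a carbon or nitrogen
source, and counting Tris (63.6 mM C, 15.9 mM N) would dominate and
distort the nutritional balance the ratio is meant to express; trace
vitamins *are* counted (thiamine C₁₂N₄, biotin C₁₀N₂) although they
contribute < 0.1 %. Second, `cnp_mass_set("p32")` provides an
alternative mass set referencing phosphorus at 32 g/mol; ratios of
haloarchaeal defined media are commonly printed under this rounding
convention, and the two conventions differ by ~3 % in the C term
(e.g. 64.8 vs 62.7 for the mixed-carbon medium). The default remains
the standard-mass convention; printed literature values should be
compared loosely, not treated as exact.

## The synthetic-data generators

The generators exist so that every downstream module can be validated
by planted-truth recovery: for noise-free settings the pipelines
recover planted parameters exactly, and under realistic noise within
stated tolerances. Each generator call takes a single integer seed;
all draws flow from it, outputs are byte-identical across runs, and
the caller's RNG state is restored afterwards.

**Proteomes** (`generate_survey_dataset()`): each species receives one
homolog per planted (class, identity, truncation) triple.
`mutate_to_identity()` substitutes residues — stratified along the
sequence so no long native run biases the local alignment, with
replacements drawn ∝ exp(score/2) under the substitution matrix to
preserve alignability — and iterates until the *aligner-measured*
identity is within ±3 points of target; targets below 25 % are refused.
Truncation removes residues from both termini, emulating terminally
shortened paralogs. Decoys are random-composition sequences of
unrelated length, rejection-sampled at generation time so none aligns
to any reference at ≥ 40 % identity; short spurious local hits in the
25–40 % band remain, which is realistic background, and never perturb
strong calls. Loci tables place each phaE gene at the planted signed
distance from its partner and all other genes ≥ 40 kb away, so the
planted partner is the nearest by construction.

What this does *not* emulate: insertions/deletions within homologs,
phylogenetically correlated divergence (no tree-based simulation),
genome-scale gene content, or real database redundancy. Passing the
recovery tests therefore demonstrates the correctness of the pipeline's
logic under controlled separation (planted identity exceeding
cross-class background by ≥ 10 points), not robustness to every
evolutionary scenario in a live database.

**Ct data** (`generate_qpcr_dataset()`): Ct = baseline −
log_E(template) + N(0, sd), with the relative template equal to 1 in
the calibrator condition and the planted fold change elsewhere;
reference genes are planted unchanged. Gaussian noise on the cycle
scale is the conventional qPCR error model; defaults (three biological
× two technical replicates, 0 noise unless requested, five-point
10-fold dilution series, E = 2) mirror a standard plate design.
Inter-run calibration drift, pipetting-volume correlation and
amplification inhibition are not modeled.

**NMR peaks** (`generate_nmr_peaklist()`): two methine peaks with
integrals proportional to the planted mole fractions, multiplicative
Gaussian integral noise, optional extra peaks (e.g. residual solvent at
7.26 ppm) that the assignment windows must ignore. Baseline and phase
artefacts of real spectra are out of scope since the input contract is
an integrated peak list.

## Numerical choices and problem sizes

Coordinates are 1-based inclusive throughout (GenBank convention). Hit
tables serialize pident to 3 decimals, bitscore to 1, e-values in
scientific notation, making written artifacts byte-stable. Ambiguity
letters B/Z/U/O/J/* are mapped to X with a warning on FASTA input
rather than rejected, since real RefSeq proteomes contain them.

The shipped validation sizes were chosen to exercise every code path
while keeping a full run on a laptop-scale machine comfortable: a
three-species survey fixture (two-paralog species with a colocalized
phaE–phaC pair at 50 bp, a 0.62-truncated single-paralog species, a
weak-only species; 8 decoys each), 250 aligner-oracle fuzz cases at
≤ 30 aa, 100–200 seeds for noisy Pfaffl recovery, and 100 coloc
brute-force instances. Survey-scale screening of hundreds of real
genomes is a matter of wall-clock time and database access, not of
different code paths, and is intentionally not part of the test suite.

## Known limitations

* The internal aligner is rigorous Smith–Waterman, not a heuristic
  seeded search; on large proteome collections it is slower than
  BLAST+, and e-values are parameterized by a simple database-size
  constant rather than composition-adjusted statistics.
* Colocalization is a distance heuristic; it does not model promoters,
  terminators or transcription units, and the strand-naive default can
  pair genes in divergent orientation.
* The Pfaffl spread is one documented convention among several; error
  bars produced by other software (e.g. propagated Ct SDs) are not
  numerically comparable.
* Multiple-testing correction across genes is deliberately not applied;
  comparisons are reported per gene.
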