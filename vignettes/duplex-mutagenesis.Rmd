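---
title: "Duplex sequencing mutagenesis analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplex sequencing mutagenesis analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupseq)
```

# The measurement model

Duplex sequencing reads both strands of each source DNA fragment
independently. A *read family* is the set of raw reads sharing a corrected
UMI barcode pair and fragment shear points; each strand of the family is
collapsed to a single-strand consensus, and a *duplex consensus* base is
emitted only where the two strand consensuses agree. Because PCR and
sequencing errors arise per read, and single-strand chemical damage arises
on one physical strand, both are structurally incapable of producing a
concordant two-strand signal; only mutations fixed in the double-stranded
source molecule survive. This is the entire error model of the package, and
its central testable contract: *no duplex consensus without both strands,
and no duplex variant from single-strand noise*.

The quantity estimated downstream is the per-nucleotide mutant frequency

$$\mathrm{MF} = \frac{m}{B},$$

where $m$ counts unique mutant nucleotides and $B$ the duplex base pairs
interrogated. Counting $m$ requires a decision about identical variants
observed in several molecules of one sample: they are either independent
mutational events or one clonally expanded event. `classify_clonality()`
fits log₁₀(VAF) of all non-germline calls with a Normal(μ, σ) model (moment
fit, equivalent to maximum likelihood for the normal) and labels a call
*clonal* iff its log-VAF exceeds μ + 3σ **and** its alternate molecule
count is ≥ 2 — one molecule can never evidence an expansion. With
`clone_collapse = TRUE` (default) a clonal call contributes 1 to $m$;
independent calls contribute their molecule count. Both counts are
reported. The 95% CI on MF is the exact Poisson (Garwood) interval on the
event count, scaled by $B$ — the natural choice for counts of rare events;
the reference figures show 95% CIs without naming a method.

# The synthetic-data generator

The generator exists so that every downstream stage is testable without any
external sequencing data. It emulates, at configurable scale:

* **true mutant frequencies** in the 10⁻⁸–10⁻⁵ range per (tissue,
  treatment), with defaults of 1.5 × 10⁻⁷ for vehicle control and
  1.2 × 10⁻⁶ for the treated arm — the background and ~8-fold induction
  regime reported for chemically exposed rodent cohorts;
* **treatment-specific trinucleotide signatures**: mutations are drawn per
  site-and-alternate channel with probability proportional to the 96-class
  signature mass of the channel's pyrimidine-space context, rescaled so the
  genome-wide mean rate equals the configured MF. Total counts are Poisson
  with mean `mf × length × molecules`, the limit of independent per-site
  Bernoulli draws at these frequencies;
* **transcription-coupled strand bias**: on transcribed targets, channels
  whose pyrimidine reference base lies on the transcribed strand are
  down-weighted by `strand_bias_factor` (total rate preserved), emulating
  preferential repair of the template strand. The factor is recoverable by
  `strand_bias()` as the fold difference between reciprocal substitutions;
* **clonal expansions**: a clone at cell fraction *f* is injected into
  `floor(f × molecules)` molecules, lowest molecule indices first, so truth
  is exactly reproducible;
* **cohort structure**: tissues × treatments × replicate animals.

Read families then add the noise the consensus caller must remove: family
sizes per strand are zero-truncated Poisson (mean 3 by default; the source
protocol does not publish family sizes) with a per-strand dropout
probability (default 0.2) producing single-strand-only families; sequencing
errors are independent per read per base; UMI tags are drawn from a
generated whitelist (256 tags of length 10, minimum pairwise Hamming
distance 4) and corrupted with 1–2 mismatches at a configurable rate.

**Directional damage.** Single-strand damage is modelled as a chemically
directional lesion — by default `G>T`, the signature of an oxidised guanine
— applied per eligible base on each *physical* strand. Directionality
matters: a top-strand lesion reads G→T while a bottom-strand lesion at the
same site would read C→A in plus orientation, so damage on the two strands
can never masquerade as a concordant duplex mutation. A direction-free
damage model would produce false duplex calls at a rate of roughly
(damage rate)²/3 per site, which at 1% damage over 10⁵ families would no
longer be negligible — and would also be chemically unrealistic, since real
abasic/oxidative lesions are base-specific. The lesion is configurable
(`damage_lesion = "C>T"` gives a deamination-flavoured model).

What the generator does **not** model: hybrid-capture probe efficiency and
GC bias, PCR duplication structure beyond family sizes, indels (cigar
discordance is exercised with synthetic cigar strings in tests),
interspecies contamination, and mapping ambiguity (synthetic reads carry
true coordinates). Passing tests therefore demonstrate the correctness of
the consensus/calling/statistics chain under the stated error model, not
robustness to alignment artifacts in real BAMs.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_reads_per_strand` | 1 | reads required on *each* strand for a duplex consensus |
| `min_family_agreement` | 0.7 | plurality fraction below which a strand consensus base is N |
| `trim_quality`, `mask_quality` | Q20 | running-sum 3′ trim threshold; N-masking threshold |
| `end_trim` | 5 bp | bases removed from each duplex consensus end (fragment termini carry end-repair artifacts) |
| `germline_vaf` | 0.3 | calls at/above this VAF are treated as inherited |
| `cutoff_sd` | 3 | clonality outlier threshold in SD of log₁₀(VAF) |
| `min_alt_count` | 1 | any nonreference duplex molecule is reportable |
| `linkage` | WPGMA | spectrum clustering linkage (Ward available) |

The consensus confidence values (`min_reads_per_strand`,
`min_family_agreement`, end trim) are declared defaults, not reproductions:
the source protocol defers to unspecified "prespecified confidence
criteria". The germline VAF rule and the 3-SD clonality cutoff are likewise
declared decisions where the protocol states none; both are configurable
and logged in the run manifest.

# Numerical and convention choices

* **Coordinates** are 0-based half-open everywhere internally; BED is
  written natively, VCF output converts to 1-based. One convention, no
  off-by-one drift.
* **Quality trimming** places the cut at the suffix minimising the running
  sum of (quality − threshold) accumulated from the 3′ end, ties broken
  toward the shorter trim; the empty suffix (score 0) means reads with all
  qualities at/above threshold are untouched.
* **Consensus ties** (two bases sharing the plurality) give N, as does any
  plurality below the agreement fraction; input N bases support nothing.
* **Cigar filtering** keeps the family's plurality cigar and rejects
  families with a tied plurality outright.
* **Overlap clipping** splits the overlap at its midpoint (left mate keeps
  the odd base); a mate properly contained in its partner is clipped away
  entirely so the union stays covered exactly once.
* **Spectra** are computed in pyrimidine space. Context abundance for the
  96-class normalisation is counted on *both* strands (each position
  contributes its 3-mer and that 3-mer's reverse complement):
  pyrimidine-space symmetry requires double-stranded accounting, and the
  source method does not state its convention. Calls at the first/last base
  of a target have no flanking context; they are dropped from 96-class
  spectra and counted, never silent.
* **Strand bias** orients substitutions onto the forward direction of the
  transcribed strand, corrects by oriented reference-base abundance, and
  uses the exact conditional rate-ratio test for the fold CI; a zero
  reciprocal count reports `NA` fold with the one-sided CI rather than
  infinity.
* **Clustering** uses `stats::hclust` with `"mcquitty"` (WPGMA) on cosine
  distance. The figure captions of the source study name the weighted
  (WPGMA) method while its methods text says "Wald"; both linkages are
  provided (`linkage = "ward"` uses Ward.D2) and neither is asserted to be
  the study's true setting. Optimal leaf ordering is replaced by a
  deterministic smaller-subtree-first traversal; leaf order affects display
  only, never merges.
* **Determinism**: every stochastic function takes a seed; the pipeline
  derives all stage seeds from the single config seed, and deterministic
  outputs (metrics TSVs, manifest) are byte-identical across reruns.

# Design choices where the design was open

* The clonality model's "outlier" criterion is operationalised as
  mean + 3 SD on log₁₀(VAF) with the ≥ 2-molecule guard. Its false-positive
  behaviour depends on the dispersion of the background VAF distribution:
  under a strictly constant-depth background, an independent coincident
  doublet *is* a high outlier with multiple observations and would be
  flagged — the model cannot distinguish it from a small clone. The
  package's tests therefore evaluate the false-positive rate on clone-free
  call sets with roughly a decade of per-site depth variation, the regime
  of pooled multi-locus, multi-sample call sets, where the rule flags
  essentially nothing; clones ≥ 10× background VAF are detected in > 95%
  of replicates.
* `mutant_frequency()` counts independent multiplets per molecule and
  collapsed clones once, because a VAF that varies 100-fold across samples
  should move the MF only ~2-fold when the expansion is recognised as one
  event — the motivating observation for clone collapsing.
* Germline truth in simulations is injected through scenario clones at
  cell fractions 0.5/1.0 rather than a separate germline machinery.

# Problem sizes in the shipped tests

The test suite and acceptance script run the method at desk scale, chosen
so the full suite completes in a few minutes while keeping every stochastic
check statistically meaningful: duplex-contract runs use 10⁵ single-read
families on a 40 bp target; recovery of MF uses 10⁷ simulated duplex
nucleotides per replicate (25 replicates per frequency); clonality
sensitivity/specificity use 50 replicates of 80–200-call samples;
strand-bias recovery uses ~10⁴ mutations on a 3 kb transcribed target;
cluster recovery uses 8 samples of 300–400 mutations each. Mutant
frequencies in worked examples are inflated (10⁻⁵–10⁻⁴) so that short toy
panels yield nonzero counts; the estimator itself is scale-free.

# Known limitations

* At a true MF of 10⁻⁷, 10⁷ duplex base pairs contain on average a single
  mutant nucleotide; any estimator's relative error is then dominated by
  Poisson counting noise (the estimate is exact only when the count is
  exactly 1, probability e⁻¹). Precise background-MF estimation requires
  the ~10⁸ bp per sample of a real study; the package reports exact CIs so
  this uncertainty is always visible.
* Consensus calling assumes reads of a family share fragment coordinates
  (guaranteed by grouping on shear points); indel-bearing reads are handled
  by exclusion (cigar plurality), not by indel-aware consensus.
* The pipeline does not align reads; it consumes the simulator's true
  coordinates or, for external data, expects pre-grouped input.
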