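---
title: "Timing mutant-allele copy-number gains from whole-genome variant data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing mutant-allele copy-number gains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohtimer)
```

## The problem

In carriers of a pathogenic germline *TP53* variant (Li-Fraumeni
syndrome), tumors almost always lose the remaining wildtype allele, and
they typically do so by *gaining* extra copies of the mutant allele —
most often whole-chromosome copy-neutral LOH (allele-specific state
2+0). Because every somatic mutation present on the ancestral chromosome
*before* the duplication is copied along with it, while mutations
arriving *after* sit on a single copy, the allele counts of somatic SNVs
on the gained segment encode **when** the gain happened, on the clock of
the tumor's own mutation accumulation. `lohtimer` implements that
inference chain end to end: somatic-call filtering, LOH state
classification, purity-aware multiplicity estimation, clock-signature
attribution, molecular-time estimation with bootstrap uncertainty, and a
telomere-content estimator — plus a generator of synthetic tumors with
known ground truth, because the real cohorts this kind of analysis runs
on are controlled-access.

## The model

### Read counts and multiplicity

A clonal mutation carried on $m$ of the $C_T$ tumor copies at a locus,
in a sample of purity $\rho$, has expected variant allele fraction

$$ \mathbb{E}[\mathrm{VAF}] \;=\;
   \frac{m\rho + m_N(1-\rho)}{\rho\, C_T + 2(1-\rho)}, $$

where $m_N$ is the number of mutant copies per contaminating normal
cell (0 for somatic mutations, 1 for the heterozygous germline
variant). Observed alt counts are modelled as
$k \sim \mathrm{Binomial}(n, \mathbb{E}[\mathrm{VAF}])$ at the observed
depth $n$. `expected_vaf()` caps the expectation at $1-\varepsilon$
(default $\varepsilon = 0.01$) so that a fully mutant locus keeps
nonzero likelihood when a stray reference-supporting error read
appears. Inverting the relation gives the continuous mutation copy
number (`mutation_copy_number()`); `assign_multiplicity()` compares
binomial likelihoods across integer multiplicities $1..m_{\max}$ (the
segment's major copy number) plus one subclonal branch ($m=1$ at the
plug-in CCF, constrained to $[0.05, 0.95]$) under a flat prior.

**Clonality.** A mutation is treated as clonal when its CCF estimate
reaches 0.8 *or* when a Jeffreys binomial interval on the VAF,
propagated to CCF, covers 1. The interval level is 99%: timing uses
clonal mutations only, so the clonality gate is deliberately
conservative — at depth 60 a 95% interval would spuriously discard
about 12% of true-clonal single-copy mutations and bias the estimated
time upward, whereas the 99% gate loses well under 1%.

### Molecular time

Assume a constant per-copy mutation rate and one synchronous gain at
molecular time $\pi \in [0,1]$ (the fraction of the segment's clonal
mutation history elapsed before the gain). Counting clonal mutations at
multiplicity $\ge 2$ ($n_2$, pre-gain) and multiplicity 1 ($n_1$,
post-gain), the expected counts give closed forms
(`molecular_time()`):

| state | pre-gain opportunity | post-gain opportunity | estimator |
|-------|----------------------|----------------------|-----------|
| 2+0   | $1 \cdot \pi$        | $2(1-\pi)$           | $\pi = 2n_2/(2n_2+n_1)$ |
| 2+1   | $2 \cdot \pi$ (one copy duplicates) | $3(1-\pi)$ | $\pi = 3n_2/(2n_2+n_1)$ |
| 2+2   | $2 \cdot \pi$        | $4(1-\pi)$           | $\pi = 2n_2/(2n_2+n_1)$ |

The 2+2 form assumes both gains are synchronous; sequential double
gains (two distinct times) are not modelled, and states with major
copy number $\ge 3$ (copy-gain LOH) are excluded from closed-form
timing and flagged, since the timing analysis targets copy-neutral LOH
of the whole chromosome. The 2+1 form can exceed 1 when $n_2 > n_1$;
estimates are capped at 1 with an `overflow` flag.

### Why the default estimator is a mixture ML, not hard counting

Plugging hard argmax multiplicity calls into the closed forms is biased
whenever the two binomial VAF components overlap: at depth 60 and
purity 0.7 the upper tail of the $m=1$ distribution leaks into the
$m=2$ call region, and when the true pre-gain count is small (early
gains — precisely the regime of interest here) those false positives
dominate $n_2$. We measured the bias of the hard-count path at up to
+0.05 for $\pi = 0.05$ on 2+1 and 2+2 states. `time_gain()` therefore
fits the multiplicity-2 fraction $q$ of clonal mutations by 1-D
maximum likelihood on the two-component binomial mixture — no hard
per-mutation assignment — and maps $\hat q$ through the same closed
forms via the effective counts $(\hat q N, (1-\hat q)N)$. This is
essentially the deconvolution that dedicated gain-timing tools perform.
Across the full grid of supported states and
$\pi \in \{0.05, \ldots, 0.95\}$ the mean bias is below 0.01 (the
acceptance suite re-measures this). Hard counts are still computed and
reported (`count_pre_post()`), and `method = "counts"` selects the
literal count-based path.

**Uncertainty.** `bootstrap_ci()`/`time_gain()` resample mutations with
replacement and report empirical percentile intervals. The default is
$B = 200$ replicates; $B = 10$ — the default of the reference
gain-timing tool — is selectable but too coarse for stable 95%
intervals.

### Clock-like mutations and chronological extrapolation

SBS1 (CpG deamination) and SBS5 accumulate roughly linearly with age.
Exposures are refit against a provided 96-channel catalog by
multinomial-mixture EM (`fit_exposures()`; the update is
$e_s \leftarrow \frac{1}{N}\sum_c n_c P(s\,|\,c)$, log-likelihood
provably non-decreasing). Per-mutation posteriors follow by Bayes'
rule (`mutation_posterior()`). A mutation counts as clock-like when it
is a C>T at a CpG site, or when its posterior probability of arising
from SBS1+SBS5 strictly exceeds 0.5 (`is_clock_mutation()`; a tie at
exactly 0.5 is *not* clock-like). Counting is binary by default;
posterior-weighted counting would be a straightforward variant but the
binary rule is the documented convention. Timing restricted to
clock-like mutations, multiplied by the age at diagnosis, gives a
rough age at gain (`chronological_bound()`) — reported strictly as a
linear-clock extrapolation, never as a measurement.

De-novo signature discovery (NMF) is out of scope: the catalog is an
input. Tests and the simulator use a clearly labelled *synthetic*
three-signature catalog (`synthetic_catalog()`: an SBS1-like CpG-heavy
column, a flat SBS5-like column, an APOBEC-like column); real COSMIC
v3.2 TSVs load with `read_catalog()`.

## LOH classification

`classify_locus()` maps the (major, minor) state of the clonal segment
containing the locus midpoint through a total state table — HOM_DEL
(0,0), LOH_LOSS (1,0), CN_LOH (2,0), CG_LOH (&ge;3,0), GAIN_NO_LOH
(&ge;2,&ge;1), NO_LOH (1,1). LOH_LOSS and HOM_DEL are representable
even though gains dominate in practice; totality means the classifier
never falls through. The extent is WHOLE_CHROMOSOME when the run of
abutting same-state segments spans at least 95% of the chromosome
(configurable; "whole chromosome" has no standard quantification, and
0.95 tolerates unassigned telomeric/centromeric ends). Which parental
allele was gained is decided by binomial likelihood of the tumor read
counts at the germline variant under "mutant on major" vs "mutant on
minor" (`assign_mutant_allele()`); exact likelihood ties and
major = minor states are surfaced as ties rather than guessed. A
Fisher exact test on germline-vs-tumor allele counts
(`vaf_shift_test()`) quantifies the supporting VAF shift.

## Filter cascade

`depth_normal_filter()` (&ge;10X in tumor and normal, &le;1 — or,
configurably, 0 — variant reads in the normal),
`panel_of_normals_filter()` (exact site/allele matches), and
`mapping_filter()`, which removes a call only when at least 2 of 4
mappability cutoffs fire: unique-mapping fraction < 70%, multi-mapping
cluster, excessively high depth, DUST score > 60. The multi-mapping
and excessive-depth flags have no published numeric definition, so
they are accepted precomputed; `annotate_excessive_depth()` offers an
explicit proxy (normal depth > 3x the chromosome median) for users who
lack them. Each filter is a pure per-record predicate, so the cascade
is order-invariant (property-tested). Burden is passing calls / 2800
Mb (`mutation_burden()`).

## Telomere content

`count_telomeric_reads()` counts reads with at least 12 non-overlapping
TTAGGG repeats (or CCCTAA on the other strand; the larger strand count
is compared to the threshold — 12 is the published operating point for
150 bp reads). `estimate_telomere_length()` normalizes by GC-adjusted
coverage from reads in the 48–52% GC bin and divides across 46
chromosome ends. Reads counted as telomeric are excluded from the GC
bin: TTAGGG is itself 50% GC, and counting signal as background
coverage would deflate the estimate. The verbal description of this
normalization is ambiguous about operation order; the published
tool's formula (telomeric mass / coverage / ends) is what is
implemented. `tn_ratio()` is the plain tumor/normal length ratio.

## The synthetic tumor generator

`simulate_tumor()` draws, for each mutation: a segment (probability
proportional to length x time-integrated copy number), a lineage
branch within gained segments (pre-gain branches produce multiplicity
2 with opportunity proportional to $\pi$ per duplicating ancestral
copy; post-gain branches multiplicity 1), a trinucleotide channel from
the exposure-weighted catalog, a depth from Poisson(D), and an alt
count from Binomial(depth, expected VAF x CCF). Subclonal mutations
(default 15% of calls) ride a single later clone at CCF 0.4 and
multiplicity 1 — multi-clone trees are out of scope. Defaults (purity
0.7, depth 60, 2000 SNVs, whole-chr17 2+0 gained at $\pi = 0.3$,
exposures 0.2/0.5/0.3 over the synthetic catalog) describe a typical
high-purity pediatric tumor genome; all are overridable via
`sim_params()`. Output is deterministic given a seed, down to the
bytes of the emitted VCF/TSV/JSON.

What the generator does *not* emulate — and hence what passing tests
do not establish about real data: mapping artifacts and
sequencing-error alt reads (filter inputs are simulated clean),
copy-number miscalls and subclonal segment states, signature
misspecification (real tumors contain processes outside any fixed
catalog), kataegis-style clustering, and multi-region heterogeneity.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; VCF and segment TSV
  are 1-based on disk, converted at the boundary.
* Contexts must arrive pyrimidine-normalizable (an `INFO/TNC` tag or
  simulator truth); no reference genome is bundled, purine-strand
  records are reverse-complemented at load.
* Multiallelic records are split; indels are excluded (counted and
  logged) — the substitution analyses are SNV-only.
* EM stops at $|\Delta \log L| < 10^{-8}$ (max 10,000 iterations);
  identical duplicate catalog columns trigger a non-identifiability
  warning rather than silent arbitrary splits.
* The bootstrap and every simulation consume one seeded RNG stream;
  reruns with the same configuration are byte-identical.
* Problem sizes used by the test and acceptance suites — 50 tumors per
  grid cell at N = 2000, 200 tumors for interval calibration, 5000
  draws for exposure recovery — were chosen as the smallest sizes at
  which Monte-Carlo error is comfortably below the tolerances being
  asserted.

## Limitations

The estimator assumes one synchronous clonal gain, a constant per-copy
rate, and correct purity and segment calls; violations (subclonal
gains, rate changes at the gain, purity error) bias $\pi$ in ways the
bootstrap does not capture. The clonality stand-in replaces proper
subclonal deconvolution and is flagged as such in reports. The
chronological bound inherits the linear-clock assumption and the age
at diagnosis; it is an extrapolation. Telomere estimation is
alignment-free and does not attempt per-arm assignment or ALT
classification.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_tumor(sim_params(), seed = 11, dir = "sim1")
fit <- run_tumor(list(vcf = "sim1/snvs.vcf.gz",
                      segments = "sim1/segments.tsv", purity = 0.7,
                      tumor_sample = "TUMOR", normal_sample = "NORMAL",
                      germline = sim$profile$germline_tp53,
                      age_at_dx = 10, seed = 3, B = 200))
summary(fit)
coef(fit)      # pi
confint(fit)   # bootstrap interval
plot(fit)      # multiplicity along chr17 with segment bars
```
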