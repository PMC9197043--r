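---
title: "Modelling self-eliminating Cas9 drivers and their payload drives in cage trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self-eliminating Cas9 drivers and their payload drives in cage trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivecage)
```

## The system being modelled

`drivecage` simulates laboratory cage trials of a *split* CRISPR homing
gene-drive system in *Anopheles gambiae*. One locus (`zpg`, required for
gonad development in both sexes) hosts an autonomous **driver** allele `D`
that encodes Cas9 and its own gRNA; three unlinked loci (`cp`, `aper1`,
`ap2`) host non-autonomous **payload** alleles `E` that encode only a
gRNA and an antiparasitic effector, and can home only when a `D` allele
elsewhere in the genome supplies Cas9 in trans. Because the driver
disrupts its host gene, females carrying `D` over a cleavage-susceptible
allele are dominantly sterile, so the driver is under strong
counter-selection — it is *self-eliminating* — while it mobilises the
payloads. Cleavage-resistant target-site alleles either preserve host-gene
function (`R1`, e.g. the naturally segregating resistant haplotype at
`zpg`) or disrupt it (`R2`). An `R1` partner both blocks homing (the
driver then segregates in Mendelian fashion) and restores female
fertility, which is what allows payload drive in females.

## Germline gamete model

Each locus carries an unordered pair of allele classes from
`{S, D, E, R1, R2}`. A locus is *actively targeted* in an individual's
germline iff (i) a `D` allele anywhere supplies Cas9, (ii) the locus's own
gRNA source is present (`D` at the driver locus, `E` at the payload locus
itself), and (iii) the locus carries at least one cuttable `S` allele.
Pre-meiotically, each `S` allele at an active locus is

* converted to the resident construct with probability `p_cut * p_hdr`
  (homing),
* turned into `R1` with probability `p_cut (1 - p_hdr) p_r1`
  (end-joining, function-preserving),
* turned into `R2` with probability `p_cut (1 - p_hdr) (1 - p_r1)`,
* left unchanged otherwise.

One allele of the post-modification pair is then transmitted uniformly;
loci segregate independently. The net construct transmission from a
construct/`S` heterozygote is therefore `(1 + p_cut p_hdr) / 2`, so the
homing efficiency that cross assays report is `e = p_cut p_hdr`.

Only `e` is identifiable from transmission data; the decomposition is
needed so that de novo resistance can be generated. Defaults: `p_cut =
0.98` and `p_r1 = 1/3` at every locus, with `p_hdr` solved from the
measured efficiencies — `e = 0.92` at the driver locus (male
transmission 96%) and `e = 0.98` at payload loci (female transmission
99%). Two consequences worth noting: payload `p_hdr` is exactly 1 under
these defaults, so de novo resistance arises only at the driver locus
unless the user raises payload `p_cut`; and male and female germline
parameters are identical by default (the data measure driver homing in
males and payload homing in females only), with per-sex overrides
available in `locus_spec()`. Embryo-stage cutting by maternally deposited
Cas9 is implemented as an optional per-locus hook (`maternal = list(p_cut,
p_r1)`, end-joining only) and is disabled by default.

## Fertility and the cage life cycle

Fitness acts through the driver-locus genotype. Females are fertile
unless they carry `D/S`, `D/D`, `D/R2` or `R2/R2`; `D/R1` females are
fully fertile. The homing-induced sterility of `D/S` females is encoded
statically in this table rather than emergently through germline
conversion, matching the phenotype data; somatic leakiness is not
modelled separately. Males carry relative mating-success and
offspring-output weights: 1 for every genotype except `D/D`
(mating 0.20/0.36 ≈ 0.56 and fecundity 26/74 ≈ 0.35, the ratios of the
measured homozygote and hemizygote insemination rates and offspring
counts) and `R2/R2` (0, a null homozygote at a gene required for gonad
development). Entries not measured directly (`D/R2` females sterile,
`S/R2` fertile, `R2/R2` sterile in both sexes) follow loss-of-function
genetics with `D` treated as female-nonfunctional/male-functional and
`R2` as a recessive null. All weights are configurable.

Each discrete generation: every female mates exactly once (Anopheles
females are effectively monandrous), drawing a male with replacement with
probability proportional to mating weight; a pair is productive iff the
female is fertile and the male's fecundity weight is positive; exactly
`population_size` offspring (default 600) are then drawn multinomially
over productive pairs weighted by male fecundity, mimicking the cage
protocol of randomly choosing 600 larvae, with no explicit egg-count
intermediate; offspring combine one gamete per parent and get a fair
Bernoulli sex. The *egg-output index* — total productive-pair fecundity
over (number of females x maximum fecundity weight) — is a dimensionless
proxy for the cage's measured egg output; absolute egg numbers are not
modelled. Zero productive pairs raises a typed extinction condition which
`run_cage()` converts into a truncated, flagged trajectory rather than a
silent zero fill. Each generation additionally records carrier and allele
frequencies from the census and from `sample_size` (default 47)
individuals drawn without replacement, mirroring the genotyping protocol;
whether the original model sampled with or without replacement is not
stated, and without replacement matches the physical experiment.

Reproducibility: one master seed; replicate `r` runs on the
counter-derived substream `derive_seed(master, r)`, so any replicate can
be reproduced in isolation and identical (configuration, seed) pairs give
bit-identical trajectories.

## Frequency estimation

Carrier frequency is carriers/n with a percentile bootstrap over
individuals; allele frequency counts copies over `2n` chromosomes and
resamples individuals. Defaults follow the 68% intervals used for cage
trajectories: `B = 1000` replicates and the 16th/84th percentiles (the
percentile convention and `B` are not stated by the source experiment;
both are configurable). Negative-control rows (`is_control == 1`) are
schema-supported and excluded from estimation. A known numerical
property, pinned by a test: on a discrete proportion at `n = 47` the 68%
percentile interval undercovers slightly — exact coverage at `p = 0.4` is
0.627 in the large-`B` limit and about 0.645 at `B = 1000` with
interpolated quantiles. This is the classic small-sample behaviour of
percentile intervals, not an implementation artefact; users needing
calibrated coverage at small `n` should prefer larger nominal levels.

## Cross assays

`simulate_crosses()` draws clutch sizes from a truncated normal (mean
50.9, sd 17.9, minimum 20, matching screened clutches; inverse-CDF
sampling) and marked-progeny counts as Binomial(clutch, analytic gamete
probability). Statistics wrap the standard tests: equal-weight one-sample
t on per-cross proportions against 0.5, Pearson chi-square on 2x2
insemination tables *without* Yates correction by default (this
reproduces the printed statistic exactly; the correction is available by
flag), and Welch's t with Satterthwaite df for unbalanced offspring
counts. Two-sided p-values throughout. `estimate_homing_efficiency()`
inverts the closed form (`e_hat = 2 * pooled - 1`, clipped to `[0, 1]`
with a warning below 0.5) and propagates a Wilson score interval.
Zero-variance inputs are flagged degenerate rather than erroring.

## Amplicon resistance classification

Alleles are consumed post-alignment, CRISPResso-style: an aligned
sequence in the coordinate frame of a reference window (gaps mark
deletions) plus insertion annotations anchored to the left reference base
(`"pos:SEQ"`), all coordinates 0-based and half-open — chosen so interval
overlap tests are unambiguous. No internal read aligner is provided; the
upstream demultiplexing/merging/mapping steps belong to external tools.
An allele is *resistant* iff at least one edit overlaps the 20 nt spacer
or the 3 nt PAM (an insertion counts when its anchor base lies inside the
region). Resistant alleles are predicted `R1` when the net indel length
is a multiple of 3, the annotated start codon (when inside the window) is
untouched, and translation in the annotated frame introduces no premature
stop; otherwise `R2`. Substitution-only alleles therefore default to `R1`
unless they create a stop or destroy the start codon — the borderline
treatment of non-synonymous substitutions is a documented prediction, not
a fitness measurement. Sites annotated on the antisense strand are
reverse-complemented into window coordinates at load time. Rankings of
the most common resistant alleles use mean per-sample read percentage
with absent alleles zero-filled and lexicographic tie-breaks, and
generation contrasts use paired two-sided t-tests plus the fold change of
means, with explicit flags for zero-variance differences and undefined
folds.

## Synthetic data

The generators produce every input the analysis consumes, with the
statistical structure the method assumes: binomial super-Mendelian cross
tables; genotyping CSVs of 47 sampled individuals plus a wild-type
negative control per cage-generation, exported from real simulation runs;
and Dirichlet-multinomial amplicon tables over a fixed synthetic 240 nt
reference window (embedded 20 nt spacer, NGG PAM, forward frame, ATG at
the window start, stop-free frame — deterministically generated, not a
natural sequence) in which the resistant allele mass evolves
logistically under a selection coefficient `s`. They deliberately do
*not* emulate raw reads, sequencing error, genotyping error or
multiplex-PCR band calling; passing tests therefore demonstrate correct
recovery of the generators' statistical structure, not robustness to
those real-data artefacts.

## Known limitations

* **Male fitness costs dominate the driver's elimination rate, and the
  data under-determine them.** The printed insemination rates compare
  hemizygous with homozygous driver males only; no wild-type comparator
  exists, so the default weights set hemizygotes to 1. Under these
  defaults the simulated driver carrier frequency declines only slowly
  after its generation-1 peak (roughly 4-6% per generation; ensemble
  means around 35-40% at generation 6 from a 30% release), whereas the
  physical cage trials fell below 20% by generation 6. Reproducing that
  faster elimination requires a substantial mating or viability cost on
  *all* driver-carrying males (roughly 0.6 relative weight), which the
  printed data neither support nor exclude; conversely, treating the
  printed insemination rates as absolute mating success collapses the
  payload spread that the trials did observe. We keep the
  data-conservative defaults and expose every weight in the
  configuration; sensitivity to this choice should be reported alongside
  any forward prediction.
* Non-overlapping generations, no age structure, no density dependence,
  no spatial structure or migration; payload loci are fitness-neutral.
* Alleles are classes, not sequences, inside the simulator; the amplicon
  module's R1/R2 call is a sequence-level prediction.

## Problem sizes used by the test-suite

The packaged tests run the cage model at its native census (600) with 4-25
replicates for dynamics checks, 60-200 replicates for neutrality
(martingale) checks, 1e5 gamete draws per genotype for
analytic-vs-Monte-Carlo equivalence, about 2e4 simulated progeny for
transmission recovery, 1000-2000 Monte Carlo repetitions for bootstrap
coverage, and amplicon depths of 2e4-1e6 reads — sizes chosen so every
stochastic assertion sits at least three standard errors from its
decision boundary under the stated tolerances.
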