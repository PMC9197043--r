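# drivecage

Stochastic cage-trial modelling of a **self-eliminating CRISPR Cas9
driver** that mobilises **non-autonomous payload gene drives** in the
malaria mosquito *Anopheles gambiae*, together with the statistics used
to analyse such trials: single-cross transmission assays, bootstrap
transgene-frequency estimation from genotyped samples, and
classification of amplicon alleles into cleavage-resistant classes.

It is aimed at gene-drive modellers and molecular entomologists who want
to explore split-drive release designs — a costly, autonomous Cas9
"driver" at one locus plus gRNA-only effector "payloads" at unlinked
loci — before or alongside physical cage experiments.

## The model

Each individual is diploid at a driver locus (`zpg`) and payload loci
(`cp`, `aper1`, `ap2`), with alleles from `{S, D, E, R1, R2}`:
susceptible wild type, driver construct, effector construct, and
resistant alleles that preserve (R1) or disrupt (R2) host-gene function.
In the germline of an individual carrying Cas9 (a `D` allele) and the
locus's gRNA source, each susceptible allele is converted to the
resident construct with probability `p_cut·p_hdr`, to R1 with
`p_cut(1−p_hdr)p_r1`, to R2 with `p_cut(1−p_hdr)(1−p_r1)`; a
construct/S heterozygote therefore transmits the construct at
`(1 + e)/2` with homing efficiency `e = p_cut·p_hdr` (defaults: driver
`e = 0.92`, payload `e = 0.98`). The driver dominantly sterilises
`D/S`, `D/D` and `D/R2` females while `D/R1` females are fully fertile,
so pre-existing R1 resistance simultaneously blocks the driver's homing,
removes it by selection, and unlocks payload drive in females. Cage
generations are discrete: monandrous females, weighted polygynous males,
and a fixed census of 600 drawn multinomially over productive pairs,
with 47 individuals sampled per generation for genotyping.

## Worked example

```r
library(drivecage)
model <- default_drive_model()

# transmission from a driver/susceptible male crossed to wild type
g <- genotype(zpg = c("D", "S"), cp = c("S", "S"),
              aper1 = c("S", "S"), ap2 = c("S", "S"))
gamete_distribution(g, model, "male")$zpg
#>    S    D   R1   R2
#> 0.01 0.96 0.01 0.02

set.seed(1)
crosses <- simulate_crosses("male", g, n_crosses = 30, model)
tr <- transmission_rate(crosses, "zpg")
round(tr$pooled, 3)
#> [1] 0.961
estimate_homing_efficiency(crosses, "zpg")$e_hat
#> [1] 0.9214464

# a resistant-seeded cage release: 600 individuals, 30% driver carriers
sc <- scenario_config("paper-cage")
ens <- run_replicates(sc$config, sc$model, sc$fertility,
                      replicates = 4, master_seed = 1)
subset(ens$means, generation == 6)
#>    generation construct mean_census_freq mean_sampled_freq n_replicates
#> 25          6       zpg        0.3991667         0.3563830            4
#> 26          6        cp        0.2612500         0.2500000            4
#> 27          6     aper1        0.5229167         0.4414894            4
#> 28          6       ap2        0.3908333         0.3510638            4
```

A driver/susceptible father transmits the driver to 96% of progeny
(homing), the inferred homing efficiency recovers the configured 0.92,
and over six cage generations the payloads spread well beyond their 10%
release frequency while the driver declines slowly from its
generation-1 peak (see the vignette's discussion of how strongly this
decline rate depends on male fitness parameters the data do not pin
down). The `analysis/` directory contains numbered drivers
(`01_crosses.R` … `04_resistance_amplicons.R`) that run the full set of
analyses — cross statistics, 25-replicate cage ensembles for the
resistant-seeded and susceptible-only scenarios, bootstrap frequency
estimation, and the amplicon resistance pipeline — writing tidy tables
under `results/`.

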