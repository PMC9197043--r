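# Shared fixtures built in code.

# Full four-locus genotype with unspecified loci wild type.
gt <- function(zpg = c("S", "S"), cp = c("S", "S"), aper1 = c("S", "S"),
               ap2 = c("S", "S")) {
  genotype(zpg = zpg, cp = cp, aper1 = aper1, ap2 = ap2)
}

# Independent brute-force enumeration of the single-locus gamete fate tree:
# pick one of the two resident alleles uniformly, then (if the locus is
# active and the allele is S) branch over cut / repair outcomes. Kept
# deliberately separate from the package's analytic path.
enumerate_gamete_dist <- function(pair, active, p_cut, p_hdr, p_r1, construct) {
  out <- c(S = 0, D = 0, E = 0, R1 = 0, R2 = 0)
  for (a in pair) {
    w <- 0.5
    if (active && a == "S") {
      out[construct] <- out[construct] + w * p_cut * p_hdr
      out["R1"] <- out["R1"] + w * p_cut * (1 - p_hdr) * p_r1
      out["R2"] <- out["R2"] + w * p_cut * (1 - p_hdr) * (1 - p_r1)
      out["S"] <- out["S"] + w * (1 - p_cut)
    } else {
      out[a] <- out[a] + w
    }
  }
  out
}

# All distinct unordered driver-locus allele pairs.
driver_pairs <- function() {
  alleles <- c("S", "D", "R1", "R2")
  pairs <- list()
  for (i in seq_along(alleles)) {
    for (j in i:length(alleles)) {
      pairs[[length(pairs) + 1L]] <- c(alleles[i], alleles[j])
    }
  }
  pairs
}

# Paper-design cage seeding (resistant-seeded unless aper1_partner = "S").
paper_config <- function(aper1_partner = "R1", ...) {
  trans <- function(partner, payload) {
    g <- list(zpg = c("D", partner), cp = c("S", "S"),
              aper1 = c("S", "S"), ap2 = c("S", "S"))
    g[[payload]] <- c("E", "S")
    do.call(genotype, g)
  }
  cage_config(list(
    seed_group(300, "female", gt()),
    seed_group(120, "male", gt()),
    seed_group(60, "male", trans("S", "cp")),
    seed_group(60, "male", trans("S", "ap2")),
    seed_group(60, "male", trans(aper1_partner, "aper1"))
  ), ...)
}
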