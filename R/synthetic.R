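# Synthetic-data generators: every input format the analysis consumes can
# be produced in code, with the statistical structure the method assumes —
# binomial/super-Mendelian cross progeny, multiplex-PCR-style carrier
# genotyping of sampled individuals, and Dirichlet-multinomial amplicon
# allele tables with selection on the resistant allele mass.

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Generate a single-cross progeny dataset
#'
#' Simulates `n_crosses` single-pair crosses of a transgenic parent to wild
#' type under the stated homing efficiencies and writes the cross CSV.
#'
#' @param path Output CSV path (`NULL` to skip writing).
#' @param sex,g Parent sex and [genotype()].
#' @param e_driver,e_payload Net homing efficiencies used to build the
#'   model.
#' @param n_crosses Number of crosses.
#' @param clutch Clutch-size model (default truncated normal 50.9 +/- 17.9,
#'   min 20).
#' @param seed RNG seed fixing the dataset bit-exactly.
#' @return The cross-record data frame, invisibly when written.
#' @export
gen_cross_dataset <- function(path = NULL, sex, g, e_driver = 0.92,
                              e_payload = 0.98, n_crosses = 30L,
                              clutch = clutch_model(), seed = 1L) {
  set.seed(seed)
  model <- default_drive_model(driver_e = e_driver, payload_e = e_payload)
  rec <- simulate_crosses(sex, g, n_crosses, model, clutch = clutch)
  if (!is.null(path)) {
    write_cross_table(rec, path)
    return(invisible(rec))
  }
  rec
}

#' Generate genotyping-sample fixtures from simulated cages
#'
#' Runs `cages` replicate cage trials and exports the per-generation random
#' samples in the genotyping CSV schema: `sample_size` genotyped
#' individuals plus one wild-type negative-control row per cage and
#' generation.
#'
#' @param config A [cage_config()].
#' @param model,fertility Simulation model.
#' @param cages Number of replicate cages.
#' @param seed Master seed (replicate substreams via [derive_seed()]).
#' @param path Output CSV path (`NULL` to skip writing).
#' @return List with `samples` (the genotyping data frame) and
#'   `trajectories`.
#' @export
gen_cage_fixture <- function(config, model = default_drive_model(),
                             fertility = fertility_model(), cages = 4L,
                             seed = 1L, path = NULL) {
  ens <- run_replicates(config, model, fertility, replicates = cages,
                        master_seed = seed)
  loci <- locus_names(model)
  rows <- list()
  for (cg in seq_len(cages)) {
    tr <- ens$trajectories[[cg]]
    for (st in tr) {
      flags <- st$sample
      df <- data.frame(cage = cg, generation = st$generation,
                       individual = seq_len(nrow(flags)), is_control = 0L)
      df <- cbind(df, as.data.frame(flags))
      ctrl <- data.frame(cage = cg, generation = st$generation,
                         individual = 0L, is_control = 1L)
      ctrl[loci] <- 0L
      rows[[length(rows) + 1L]] <- rbind(df, ctrl)
    }
  }
  samples <- do.call(rbind, rows)
  if (!is.null(path)) write_genotype_samples(samples, path)
  list(samples = samples, trajectories = ens$trajectories,
       extinct_at = ens$extinct_at)
}

# Deterministic base sequence from a tiny LCG (independent of R's RNG).
lcg_bases <- function(n, state = 20220602) {
  out <- character(n)
  for (i in seq_len(n)) {
    state <- (1103515245 * (state %% 65536) + 12345) %% 2147483648
    out[i] <- c("A", "C", "G", "T")[state %% 4 + 1]
  }
  out
}

#' A synthetic amplicon target-site window
#'
#' A fixed 240 nt window (deterministically generated, not a natural
#' sequence) with an embedded 20 nt spacer at `[100, 120)`, an NGG PAM at
#' `[120, 123)`, cut position 117 (3 nt inside the spacer from the PAM),
#' forward reading frame starting at 0 with an ATG start codon at the
#' window start and no stop codon in frame.
#'
#' @param locus Name for the synthetic locus.
#' @return A [target_site()].
#' @export
synthetic_target_site <- function(locus = "synthetic") {
  b <- lcg_bases(240)
  b[1:3] <- c("A", "T", "G")
  b[121:123] <- c("C", "G", "G")  # codon 40 spans the PAM; CGG fixes NGG
  # scrub in-frame stop codons (TAA, TAG, TGA)
  for (i in seq(1, 238, by = 3)) {
    if (paste(b[i:(i + 2)], collapse = "") %in% c("TAA", "TAG", "TGA")) {
      b[i + 2] <- "C"
    }
  }
  target_site(locus, paste(b, collapse = ""),
              spacer_start = 100, spacer_end = 120,
              pam_start = 120, pam_end = 123, cut_pos = 117,
              strand = "+", frame_offset = 0, translation_direction = "+",
              start_codon_pos = 0L)
}

substitute_safe <- function(chars, pos, site) {
  # pick a replacement base that neither restores the reference nor
  # introduces an in-frame stop codon
  for (cand in c("C", "G", "T", "A")) {
    if (cand == chars[pos]) next
    trial <- chars
    trial[pos] <- cand
    codon_start <- pos - (pos - 1L) %% 3L
    codon <- paste(trial[codon_start:(codon_start + 2L)], collapse = "")
    if (!codon %in% c("TAA", "TAG", "TGA")) return(trial)
  }
  stop("no safe substitution at position ", pos)
}

#' A synthetic allele pool for amplicon fixtures
#'
#' Five alleles over [synthetic_target_site()]: the reference; a natural
#' R1-style haplotype with 4 SNPs inside the spacer; an in-frame 3 bp
#' deletion at the cut site (R1); a 1 bp frameshift deletion at the cut
#' site (R2); and a substitution well outside the spacer/PAM
#' (susceptible). `freq` gives the generation-1 mean allele frequencies.
#'
#' @param site A [target_site()] from [synthetic_target_site()].
#' @return Data frame: `name`, `aligned_sequence`, `insertions`, `freq`,
#'   `resistant`, `r_class`.
#' @export
synthetic_allele_pool <- function(site = synthetic_target_site()) {
  ref <- strsplit(site$reference, "")[[1L]]
  snp4 <- ref
  for (p in c(103L, 108L, 113L, 119L)) snp4 <- substitute_safe(snp4, p, site)
  del3 <- ref
  del3[115:117] <- "-"
  del1 <- ref
  del1[117] <- "-"
  distal <- substitute_safe(ref, 11L, site)
  pool <- data.frame(
    name = c("reference", "snp4_r1", "inframe_del_r1", "frameshift_r2",
             "distal_sub"),
    aligned_sequence = vapply(list(ref, snp4, del3, del1, distal),
                              paste, character(1), collapse = ""),
    insertions = "",
    freq = c(0.70, 0.07, 0.10, 0.08, 0.05))
  calls <- lapply(seq_len(nrow(pool)), function(i) {
    classify_allele(pool$aligned_sequence[i], site, pool$insertions[i])
  })
  pool$resistant <- vapply(calls, `[[`, logical(1), "resistant")
  pool$r_class <- vapply(calls, `[[`, character(1), "r_class")
  stopifnot(identical(pool$resistant, c(FALSE, TRUE, TRUE, TRUE, FALSE)),
            identical(pool$r_class[2:4], c("R1", "R1", "R2")))
  pool
}

#' Generate Dirichlet-multinomial amplicon allele tables
#'
#' Per cage and generation, allele frequencies are drawn from a Dirichlet
#' distribution centred on the scenario means and read counts from a
#' multinomial at the stated depth. Between the early and late generation
#' the total resistant allele mass m is updated logistically under selection
#' coefficient `s` over `generations_apart` generations,
#' m' = m e^(s t) / (1 - m + m e^(s t)), with individual resistant
#' (susceptible) alleles scaled proportionally. Zero-count alleles are
#' dropped from the table, as in real allele tables.
#'
#' @param site A [target_site()].
#' @param pool Allele pool data frame (`aligned_sequence`, `insertions`,
#'   `freq`; resistance is classified against `site`).
#' @param s Selection coefficient per generation on resistant mass.
#' @param generations_apart Generations between the two sampled time points.
#' @param depth Reads per sample.
#' @param cages Number of replicate cages.
#' @param concentration Dirichlet concentration (larger = less between-cage
#'   variation).
#' @param seed RNG seed.
#' @param path Optional TSV output path.
#' @return Allele-table data frame with columns `sample`, `cage`,
#'   `generation`, `aligned_sequence`, `insertions`, `n_reads`.
#' @export
gen_amplicon_tables <- function(site, pool = synthetic_allele_pool(site),
                                s = 0.25, generations_apart = 5L,
                                depth = 1e5, cages = 4L,
                                concentration = 200, seed = 1L,
                                path = NULL) {
  set.seed(seed)
  stopifnot(abs(sum(pool$freq) - 1) < 1e-8)
  res <- vapply(seq_len(nrow(pool)), function(i) {
    classify_allele(pool$aligned_sequence[i], site, pool$insertions[i])$resistant
  }, logical(1))
  m1 <- sum(pool$freq[res])
  grow <- exp(s * generations_apart)
  m6 <- m1 * grow / (1 - m1 + m1 * grow)
  f6 <- pool$freq
  if (m1 > 0 && m1 < 1) {
    f6[res] <- pool$freq[res] * m6 / m1
    f6[!res] <- pool$freq[!res] * (1 - m6) / (1 - m1)
  }
  rows <- list()
  for (cg in seq_len(cages)) {
    for (gen in c(1L, 6L)) {
      mu <- if (gen == 1L) pool$freq else f6
      p <- rdirichlet1(concentration * mu)
      counts <- as.integer(stats::rmultinom(1L, size = depth, prob = p))
      keep <- counts > 0L
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("cage%d_G%d", cg, gen), cage = cg, generation = gen,
        aligned_sequence = pool$aligned_sequence[keep],
        insertions = pool$insertions[keep],
        n_reads = counts[keep])
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(path)) write_allele_table(tab, path)
  tab
}
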