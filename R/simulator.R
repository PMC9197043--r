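# Discrete-generation stochastic cage simulation.
#
# A population is a fixed-size cohort of diploid individuals. Each
# generation: every female picks one mate (males polygynous, drawn with
# replacement, weighted by mating success); a pair is productive iff the
# female's driver-locus genotype is fertile and the male's fecundity weight
# is positive; the next generation of exactly `population_size` offspring is
# drawn multinomially over productive pairs weighted by male fecundity; each
# offspring combines one gamete from each parent (germline cut/repair model)
# and is assigned a sex by a fair coin.

#' One seeding group of a cage
#'
#' @param count Number of individuals (>= 0).
#' @param sex `"female"` or `"male"`.
#' @param genotype A [genotype()] shared by all individuals of the group.
#' @return An object of class `seed_group`.
#' @export
seed_group <- function(count, sex = c("female", "male"), genotype) {
  sex <- match.arg(sex)
  if (!is.numeric(count) || length(count) != 1L || count < 0 || count != round(count)) {
    stop("`count` must be a nonnegative integer", call. = FALSE)
  }
  if (!inherits(genotype, "genotype")) stop("`genotype` must be a genotype()", call. = FALSE)
  structure(list(count = as.integer(count), sex = sex, genotype = genotype),
            class = "seed_group")
}

#' Cage trial configuration
#'
#' Defaults follow the cage-trial design: populations of 600 individuals,
#' discrete generations, 6 generations, 47 individuals genotyped per cage
#' per generation, 25 simulated replicates.
#'
#' @param seed_groups List of [seed_group()]s; counts must sum to
#'   `population_size`.
#' @param population_size Adults per generation.
#' @param generations Number of generation steps to simulate.
#' @param sample_size Individuals sampled (without replacement) per
#'   generation for genotyping.
#' @param replicates Default number of replicate cages for
#'   [run_replicates()].
#' @param rng_seed Master seed; per-replicate substreams are derived from it.
#' @return An object of class `cage_config`.
#' @export
cage_config <- function(seed_groups, population_size = 600L, generations = 6L,
                        sample_size = 47L, replicates = 25L, rng_seed = 1L) {
  stopifnot(population_size >= 1, generations >= 0, replicates >= 1)
  if (sample_size > population_size) {
    stop("sample_size cannot exceed population_size", call. = FALSE)
  }
  if (!length(seed_groups) ||
      !all(vapply(seed_groups, inherits, logical(1), "seed_group"))) {
    stop("`seed_groups` must be a list of seed_group() objects", call. = FALSE)
  }
  total <- sum(vapply(seed_groups, `[[`, integer(1), "count"))
  if (total != population_size) {
    stop(sprintf("population_size mismatch: seed groups sum to %d, expected %d",
                 total, population_size), call. = FALSE)
  }
  structure(list(seed_groups = seed_groups,
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 sample_size = as.integer(sample_size),
                 replicates = as.integer(replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "cage_config")
}

geno_cols <- function(loci) as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))

#' Seed a cage population
#'
#' @param config A [cage_config()].
#' @param model A [drive_model()].
#' @return A `population`: list with `sex` (character vector) and `geno`
#'   (character matrix, two columns per locus), generation index 0.
#' @export
seed_population <- function(config, model) {
  loci <- locus_names(model)
  n <- config$population_size
  geno <- matrix(NA_character_, n, 2L * length(loci),
                 dimnames = list(NULL, geno_cols(loci)))
  sex <- character(n)
  i <- 1L
  for (grp in config$seed_groups) {
    validate_genotype(grp$genotype, model)
    if (grp$count == 0L) next
    rows <- i:(i + grp$count - 1L)
    sex[rows] <- grp$sex
    for (nm in loci) {
      geno[rows, paste0(nm, ".1")] <- grp$genotype[[nm]][1L]
      geno[rows, paste0(nm, ".2")] <- grp$genotype[[nm]][2L]
    }
    i <- i + grp$count
  }
  structure(list(sex = sex, geno = geno, loci = loci, generation = 0L),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("<population>", length(x$sex), "individuals, generation", x$generation, "\n")
  invisible(x)
}

# 0/1 carrier flags (one column per locus construct) for given rows.
carrier_flags <- function(pop, model, rows = seq_along(pop$sex)) {
  loci <- locus_names(model)
  out <- sapply(loci, function(nm) {
    cons <- construct_class(model$loci[[nm]])
    as.integer(pop$geno[rows, paste0(nm, ".1")] == cons |
                 pop$geno[rows, paste0(nm, ".2")] == cons)
  })
  matrix(out, nrow = length(rows), dimnames = list(NULL, loci))
}

# Census allele frequencies: loci x allele classes matrix.
census_allele_freqs <- function(pop, model) {
  loci <- locus_names(model)
  t(vapply(loci, function(nm) {
    alleles <- c(pop$geno[, paste0(nm, ".1")], pop$geno[, paste0(nm, ".2")])
    tab <- table(factor(alleles, levels = ALLELE_CLASSES))
    as.numeric(tab) / length(alleles)
  }, numeric(length(ALLELE_CLASSES)), USE.NAMES = TRUE)) |>
    (\(m) {colnames(m) <- ALLELE_CLASSES; m})()
}

# Per-generation summary: census carrier/allele frequencies plus carrier
# flags of a random genotyping sample of `sample_size` individuals.
population_stats <- function(pop, model, sample_size, egg_output_index = NA_real_) {
  n <- length(pop$sex)
  cf <- colMeans(carrier_flags(pop, model))
  sample_rows <- sort(sample.int(n, min(sample_size, n)))
  sampled <- carrier_flags(pop, model, sample_rows)
  structure(list(generation = pop$generation,
                 census_carrier = cf,
                 census_allele = census_allele_freqs(pop, model),
                 sampled_carrier = colMeans(sampled),
                 sample = sampled,
                 egg_output_index = egg_output_index),
            class = "generation_stats")
}

extinct_condition <- function(generation) {
  structure(class = c("drivecage_extinct", "error", "condition"),
            list(message = sprintf(
              "population extinct: no productive pairs at generation %d", generation),
              call = NULL, generation = generation))
}

# Vectorised gamete draw for parents at given row indices; returns a
# character matrix (length(idx) x loci) of transmitted alleles.
draw_gametes <- function(pop, idx, model, sex) {
  loci <- locus_names(model)
  n <- length(idx)
  has_cas9 <- rowSums(pop$geno[idx, , drop = FALSE] == "D") > 0
  out <- matrix(NA_character_, n, length(loci), dimnames = list(NULL, loci))
  for (nm in loci) {
    spec <- model$loci[[nm]]
    gp <- spec$germline[[sex]]
    cons <- construct_class(spec)
    a1 <- pop$geno[idx, paste0(nm, ".1")]
    a2 <- pop$geno[idx, paste0(nm, ".2")]
    active <- has_cas9 & (a1 == cons | a2 == cons) & (a1 == "S" | a2 == "S")
    pick1 <- stats::runif(n) < 0.5
    a <- ifelse(pick1, a1, a2)
    hit <- active & a == "S"
    if (any(hit)) a[hit] <- sample_fate(sum(hit), gp, cons)
    out[, nm] <- a
  }
  out
}

#' Advance a cage population by one generation
#'
#' @param pop A `population`.
#' @param model A [drive_model()].
#' @param fertility A [fertility_model()].
#' @param config A [cage_config()] (supplies census and sample sizes).
#' @return List with elements `population` (the next generation) and `stats`
#'   (a `generation_stats` for it, including the egg-output index of the
#'   reproduction event: total productive-pair fecundity over females times
#'   the maximum fecundity weight).
#' @seealso [run_cage()]
#' @export
step_generation <- function(pop, model, fertility, config) {
  drv <- driver_locus(model)
  d1 <- pop$geno[, paste0(drv, ".1")]
  d2 <- pop$geno[, paste0(drv, ".2")]
  keys <- paste(pmin(d1, d2), pmax(d1, d2), sep = "/")

  females <- which(pop$sex == "female")
  males <- which(pop$sex == "male")
  if (!length(females) || !length(males)) stop(extinct_condition(pop$generation))

  mate_w <- unname(fertility$male_mating[keys[males]])
  if (anyNA(mate_w)) stop("driver genotype missing from fertility model", call. = FALSE)
  if (all(mate_w == 0)) stop(extinct_condition(pop$generation))
  # each female mates once; males drawn with replacement by mating weight
  mates <- males[sample.int(length(males), length(females), replace = TRUE,
                            prob = mate_w)]
  fem_fertile <- unname(fertility$female_fertile[keys[females]])
  fec_w <- unname(fertility$male_fecundity[keys[mates]])
  productive <- fem_fertile & fec_w > 0
  if (!any(productive)) stop(extinct_condition(pop$generation))

  pair_w <- fec_w[productive]
  egg_output <- sum(pair_w) / (length(females) * max(fertility$male_fecundity))

  pick <- sample.int(sum(productive), config$population_size, replace = TRUE,
                     prob = pair_w)
  mothers <- females[productive][pick]
  fathers <- mates[productive][pick]

  mat_g <- draw_gametes(pop, mothers, model, "female")
  pat_g <- draw_gametes(pop, fathers, model, "male")
  loci <- locus_names(model)
  geno <- matrix(NA_character_, config$population_size, 2L * length(loci),
                 dimnames = list(NULL, geno_cols(loci)))
  for (nm in loci) {
    geno[, paste0(nm, ".1")] <- mat_g[, nm]
    geno[, paste0(nm, ".2")] <- pat_g[, nm]
  }
  # optional embryo-stage cutting by maternally deposited Cas9 and gRNA
  # (end-joining only; disabled unless a locus configures `maternal`)
  mat_cas9 <- rowSums(pop$geno[mothers, , drop = FALSE] == "D") > 0
  for (nm in loci) {
    md <- model$loci[[nm]]$maternal
    if (is.null(md) || md$p_cut <= 0) next
    cons <- construct_class(model$loci[[nm]])
    mat_grna <- pop$geno[mothers, paste0(nm, ".1")] == cons |
      pop$geno[mothers, paste0(nm, ".2")] == cons
    for (col in paste0(nm, c(".1", ".2"))) {
      hit <- mat_cas9 & mat_grna & geno[, col] == "S" &
        stats::runif(config$population_size) < md$p_cut
      if (any(hit)) {
        geno[hit, col] <- ifelse(stats::runif(sum(hit)) < md$p_r1, "R1", "R2")
      }
    }
  }
  nxt <- structure(list(
    sex = c("male", "female")[stats::rbinom(config$population_size, 1L, 0.5) + 1L],
    geno = geno, loci = loci, generation = pop$generation + 1L),
    class = "population")
  list(population = nxt,
       stats = population_stats(nxt, model, config$sample_size, egg_output))
}

#' Run one cage trial
#'
#' Simulates `config$generations` discrete generations from the seeded
#' population. If the population goes extinct (no productive pairs) the
#' trajectory is truncated and flagged.
#'
#' @inheritParams step_generation
#' @param seed Optional integer; when supplied, seeds the RNG so the
#'   trajectory is exactly reproducible.
#' @return A `trajectory`: list of `generation_stats` of length
#'   generations + 1 (including generation 0) unless truncated, with
#'   attributes `extinct_at` (NA or the generation at which reproduction
#'   failed).
#' @export
run_cage <- function(config, model = default_drive_model(),
                     fertility = fertility_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- seed_population(config, model)
  stats_list <- list(population_stats(pop, model, config$sample_size))
  extinct_at <- NA_integer_
  if (config$generations > 0) {
    for (g in seq_len(config$generations)) {
      res <- tryCatch(step_generation(pop, model, fertility, config),
                      drivecage_extinct = function(e) e)
      if (inherits(res, "drivecage_extinct")) {
        extinct_at <- res$generation
        break
      }
      pop <- res$population
      stats_list[[g + 1L]] <- res$stats
    }
  }
  constructs <- vapply(model$loci, construct_class, character(1))
  structure(stats_list, class = "trajectory", extinct_at = extinct_at,
            loci = locus_names(model), constructs = constructs)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x), "generations recorded")
  if (!is.na(attr(x, "extinct_at"))) cat(" (extinct at", attr(x, "extinct_at"), ")")
  cat("\n")
  print(utils::head(as.data.frame(x), 12))
  invisible(x)
}

#' Tidy a trajectory
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return Long data frame: generation, construct (locus name), census
#'   carrier and allele frequency, sampled carrier frequency, egg-output
#'   index.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  loci <- attr(x, "loci")
  constructs <- attr(x, "constructs")
  do.call(rbind, lapply(x, function(st) {
    data.frame(generation = st$generation,
               construct = loci,
               census_freq = unname(st$census_carrier[loci]),
               census_allele_freq = unname(st$census_allele[cbind(loci, constructs[loci])]),
               sampled_freq = unname(st$sampled_carrier[loci]),
               egg_output_index = st$egg_output_index,
               row.names = NULL)
  }))
}

#' Derive a replicate substream seed from a master seed
#'
#' Deterministic counter-based derivation so replicate `i` is reproducible
#' in isolation; results stay below 2^31.
#'
#' @param master Integer master seed.
#' @param i Replicate counter (>= 1).
#' @return Integer seed.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483647 * 48271 + i * 9973) %% 2147483629)
}

#' Run an ensemble of replicate cages
#'
#' @inheritParams run_cage
#' @param replicates Number of replicate cages (default from `config`).
#' @param master_seed Master seed (default `config$rng_seed`); replicate
#'   `i` runs on [derive_seed()]`(master_seed, i)`.
#' @return List with `trajectories` (one `trajectory` per replicate),
#'   `means` (data frame of per-generation ensemble means of census and
#'   sampled carrier frequencies per construct, over non-truncated
#'   replicates at that generation), and `extinct_at` (integer vector).
#' @export
run_replicates <- function(config, model = default_drive_model(),
                           fertility = fertility_model(),
                           replicates = config$replicates,
                           master_seed = config$rng_seed) {
  trajs <- lapply(seq_len(replicates), function(r) {
    run_cage(config, model, fertility, seed = derive_seed(master_seed, r))
  })
  loci <- locus_names(model)
  gens <- 0:config$generations
  means <- do.call(rbind, lapply(gens, function(g) {
    have <- Filter(function(tr) length(tr) > g, trajs)
    if (!length(have)) return(NULL)
    cens <- rowMeans(sapply(have, function(tr) tr[[g + 1L]]$census_carrier[loci]))
    samp <- rowMeans(sapply(have, function(tr) tr[[g + 1L]]$sampled_carrier[loci]))
    data.frame(generation = g, construct = loci,
               mean_census_freq = unname(cens), mean_sampled_freq = unname(samp),
               n_replicates = length(have), row.names = NULL)
  }))
  list(trajectories = trajs, means = means,
       extinct_at = vapply(trajs, attr, integer(1), "extinct_at"))
}
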