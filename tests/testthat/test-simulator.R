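# Cage simulation: seeding, generation stepping, reproducibility.

test_that("paper-design seeding reproduces the release frequencies", {
  cfg <- paper_config()
  m <- default_drive_model()
  pop <- seed_population(cfg, m)
  expect_length(pop$sex, 600)
  af <- drivecage:::census_allele_freqs(pop, m)
  expect_equal(unname(af["zpg", "D"]), 180 / 1200)
  expect_equal(unname(af["zpg", "R1"]), 60 / 1200)
  for (pl in c("cp", "aper1", "ap2")) {
    expect_equal(unname(af[pl, "E"]), 60 / 1200)
  }
  carriers <- colMeans(drivecage:::carrier_flags(pop, m))
  expect_equal(unname(carriers["zpg"]), 0.30)
  expect_equal(unname(carriers[c("cp", "aper1", "ap2")]), rep(0.10, 3))
})

test_that("all-wild-type populations stay wild type with full egg output", {
  m <- default_drive_model()
  cfg <- cage_config(list(seed_group(30, "female", gt()),
                          seed_group(30, "male", gt())),
                     population_size = 60, generations = 1, sample_size = 10)
  set.seed(1)
  res <- step_generation(seed_population(cfg, m), m, fertility_model(), cfg)
  expect_true(all(res$population$geno == "S"))
  expect_equal(res$stats$egg_output_index, 1)
  expect_equal(unname(res$stats$census_carrier), rep(0, 4))
})

test_that("sterile-female populations raise an extinction error with the generation index", {
  m <- default_drive_model()
  cfg <- cage_config(list(seed_group(20, "female", gt(zpg = c("D", "S"))),
                          seed_group(20, "male", gt())),
                     population_size = 40, generations = 2, sample_size = 5)
  set.seed(1)
  err <- tryCatch(step_generation(seed_population(cfg, m), m,
                                  fertility_model(), cfg),
                  drivecage_extinct = function(e) e)
  expect_s3_class(err, "drivecage_extinct")
  expect_equal(err$generation, 0L)
  # run_cage flags the truncation instead of failing
  tr <- run_cage(cfg, m, seed = 3)
  expect_length(tr, 1L)
  expect_equal(attr(tr, "extinct_at"), 0L)
})

test_that("census size is constant and zero-generation runs return seeding only", {
  sc <- scenario_config("paper-cage")
  set.seed(5)
  pop <- seed_population(sc$config, sc$model)
  for (i in 1:3) {
    res <- step_generation(pop, sc$model, sc$fertility, sc$config)
    pop <- res$population
    expect_length(pop$sex, sc$config$population_size)
  }
  cfg0 <- paper_config(generations = 0)
  tr <- run_cage(cfg0, sc$model, sc$fertility, seed = 1)
  expect_length(tr, 1L)
  expect_equal(tr[[1]]$generation, 0L)
})

test_that("identical configuration and seed give bit-identical trajectories", {
  sc <- scenario_config("paper-cage")
  a <- run_cage(sc$config, sc$model, sc$fertility, seed = 42)
  b <- run_cage(sc$config, sc$model, sc$fertility, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # replicate substreams are reproducible in isolation
  ens <- run_replicates(sc$config, sc$model, sc$fertility, replicates = 3,
                        master_seed = 9)
  solo <- run_cage(sc$config, sc$model, sc$fertility, seed = derive_seed(9, 2))
  expect_identical(as.data.frame(ens$trajectories[[2]]), as.data.frame(solo))
})

test_that("a neutral marker allele frequency is a martingale", {
  sc <- scenario_config("neutral-null", generations = 6)
  ens <- run_replicates(sc$config, sc$model, sc$fertility, replicates = 60,
                        master_seed = 77)
  g6 <- vapply(ens$trajectories, function(tr) {
    unname(tr[[7]]$census_allele["zpg", "D"])
  }, numeric(1))
  se <- stats::sd(g6) / sqrt(length(g6))
  expect_lt(abs(mean(g6) - 0.15), 3 * se)
})

test_that("offspring alleles are traceable to parental alleles or cut fates", {
  # without cutting, no new allele classes can appear
  m0 <- default_drive_model(driver_e = 0, payload_e = 0, p_cut = 0)
  cfg <- paper_config(rng_seed = 3)
  tr <- run_cage(cfg, m0, fertility_model(), seed = 13)
  for (st in tr) {
    expect_equal(unname(st$census_allele["zpg", "R2"]), 0)
    expect_equal(unname(st$census_allele[c("cp", "aper1", "ap2"), "D"]),
                 rep(0, 3))
    expect_equal(unname(st$census_allele["zpg", "E"]), 0)
    expect_equal(unname(st$census_allele["cp", "R1"]), 0)
  }
  # with default cutting, payload p_hdr = 1 means no payload end-joining
  tr2 <- run_cage(cfg, default_drive_model(), fertility_model(), seed = 13)
  for (st in tr2) {
    expect_equal(unname(st$census_allele[c("cp", "aper1", "ap2"), "R2"]),
                 rep(0, 3))
  }
})

test_that("carrier frequency never exceeds twice the allele frequency", {
  sc <- scenario_config("paper-cage")
  tr <- run_cage(sc$config, sc$model, sc$fertility, seed = 21)
  constructs <- c(zpg = "D", cp = "E", aper1 = "E", ap2 = "E")
  for (st in tr) {
    for (nm in names(constructs)) {
      af <- st$census_allele[nm, constructs[nm]]
      expect_gte(st$census_carrier[nm], af)
      expect_lte(st$census_carrier[nm], min(1, 2 * af) + 1e-12)
    }
  }
})

test_that("seed-group miscounts are rejected as configuration errors", {
  expect_error(cage_config(list(seed_group(10, "male", gt())),
                           population_size = 600),
               "population_size mismatch")
  expect_error(cage_config(list(seed_group(10, "male", gt())),
                           population_size = 10, sample_size = 20),
               "sample_size")
})

test_that("maternally deposited Cas9 creates embryo-stage resistant alleles when enabled", {
  m <- drive_model(
    locus_spec("zpg", "driver", germline_from_efficiency(0.92),
               maternal = list(p_cut = 0.9, p_r1 = 0.5)))
  fert <- fertility_model()
  cfg <- cage_config(list(
    seed_group(100, "female", genotype(zpg = c("D", "R1"))),
    seed_group(100, "male", genotype(zpg = c("S", "S")))),
    population_size = 200, generations = 1, sample_size = 10)
  set.seed(8)
  res <- step_generation(seed_population(cfg, m), m, fert, cfg)
  af <- res$stats$census_allele["zpg", ]
  # paternal S alleles of D-mothers' offspring are cut in the embryo
  expect_gt(af[["R1"]] + af[["R2"]], 0.3)
  # disabled by default: no embryo cutting from D/R1 mothers (their germline
  # has no S allele to cut either)
  m0 <- drive_model(locus_spec("zpg", "driver", germline_from_efficiency(0.92)))
  set.seed(8)
  res0 <- step_generation(seed_population(cfg, m0), m0, fert, cfg)
  expect_equal(unname(res0$stats$census_allele["zpg", "R2"]), 0)
})
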