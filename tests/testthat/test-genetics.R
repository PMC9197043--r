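# Germline gamete model and fertility table.

test_that("female fertility table is total and matches the phenotype summary", {
  expected <- c("S/S" = TRUE, "R1/S" = TRUE, "R1/R1" = TRUE, "R2/S" = TRUE,
                "R1/R2" = TRUE, "D/R1" = TRUE,
                "D/S" = FALSE, "D/D" = FALSE, "D/R2" = FALSE, "R2/R2" = FALSE)
  for (key in names(expected)) {
    pair <- strsplit(key, "/", fixed = TRUE)[[1]]
    expect_identical(female_is_fertile(pair), expected[[key]])
    # totality across argument order
    expect_identical(female_is_fertile(rev(pair)), expected[[key]])
  }
  expect_error(female_is_fertile(c("D", "X")), "unknown allele")
})

test_that("male weights are positive except for R2/R2", {
  for (pair in driver_pairs()) {
    w <- male_weights(pair)
    if (identical(pair, c("R2", "R2"))) {
      expect_equal(unname(w), c(0, 0))
    } else {
      expect_true(all(w > 0))
    }
  }
})

test_that("gamete distribution sums to one at every locus for every driver genotype", {
  m <- default_drive_model()
  for (pair in driver_pairs()) {
    d <- gamete_distribution(gt(zpg = pair, cp = c("E", "S")), m, "male")
    for (nm in names(d)) expect_equal(sum(d[[nm]]), 1, tolerance = 1e-12)
  }
})

test_that("driver/susceptible heterozygotes transmit at (1 + e)/2", {
  m <- default_drive_model(driver_e = 0.92)
  d <- gamete_distribution(gt(zpg = c("D", "S")), m, "male")
  expect_equal(unname(d$zpg["D"]), 0.96, tolerance = 1e-12)

  # closed form against independent brute-force enumeration of the fate tree
  for (p in list(c(0.98, 0.92 / 0.98, 1 / 3), c(0.5, 0.6, 0.2),
                 c(1, 1, 0.5), c(0, 0.5, 0.5))) {
    mm <- drive_model(
      locus_spec("zpg", "driver", germline_params(p[1], p[2], p[3])))
    got <- gamete_distribution(genotype(zpg = c("D", "S")), mm, "male")$zpg
    want <- enumerate_gamete_dist(c("D", "S"), active = p[1] > 0,
                                  p[1], p[2], p[3], "D")
    want <- want[want > 0 | names(want) == "S"]
    for (cls in names(got)) {
      expect_equal(unname(got[cls]), unname(want[cls]), tolerance = 1e-12)
    }
    expect_equal(unname(got["D"]), (1 + p[1] * p[2]) / 2, tolerance = 1e-12)
  }
})

test_that("resistant partner alleles make transmission exactly Mendelian", {
  m <- default_drive_model()
  for (partner in c("R1", "R2")) {
    d <- gamete_distribution(gt(zpg = c("D", partner)), m, "female")$zpg
    expect_equal(unname(d["D"]), 0.5, tolerance = 1e-15)
    expect_equal(unname(d[partner]), 0.5, tolerance = 1e-15)
  }
})

test_that("without cutting or without Cas9 the distribution is Mendelian", {
  m0 <- default_drive_model(driver_e = 0, payload_e = 0, p_cut = 0)
  d <- gamete_distribution(gt(zpg = c("D", "S")), m0, "male")$zpg
  expect_equal(unname(d[c("D", "S")]), c(0.5, 0.5))
  # payload heterozygote without a driver allele anywhere: no Cas9, no homing
  m <- default_drive_model()
  d2 <- gamete_distribution(gt(cp = c("E", "S")), m, "female")$cp
  expect_equal(unname(d2[c("E", "S")]), c(0.5, 0.5))
})

test_that("payload homing with Cas9 in trans reaches its homing efficiency", {
  m <- default_drive_model(payload_e = 0.98)
  g <- gt(zpg = c("D", "R1"), cp = c("E", "S"))
  d <- gamete_distribution(g, m, "female")
  expect_equal(unname(d$cp["E"]), 0.99, tolerance = 1e-12)
  expect_equal(unname(d$zpg["D"]), 0.5)
})

test_that("Monte Carlo gamete draws match the analytic distribution", {
  m <- default_drive_model()
  set.seed(401)
  for (pair in driver_pairs()) {
    g <- gt(zpg = pair)
    want <- gamete_distribution(g, m, "male")$zpg
    n <- 20000L
    draws <- replicate(200, form_gamete(g, m, "male")["zpg"])
    # direct single-draw sampler agrees loosely ...
    for (cls in names(want)) {
      se <- sqrt(want[cls] * (1 - want[cls]) / 200)
      expect_lt(abs(mean(draws == cls) - want[cls]), 3 * se + 1e-9)
    }
    # ... and the vectorised simulator path agrees at n = 20,000
    cfg <- cage_config(list(seed_group(2, "male", g)), population_size = 2,
                       generations = 0, sample_size = 1)
    pop <- seed_population(cfg, m)
    gam <- drivecage:::draw_gametes(pop, rep(1L, n), m, "male")[, "zpg"]
    for (cls in names(want)) {
      se <- sqrt(want[cls] * (1 - want[cls]) / n)
      expect_lt(abs(mean(gam == cls) - want[cls]), 3 * se + 1e-9)
    }
  }
})

test_that("genotype validation rejects constructs at the wrong locus", {
  m <- default_drive_model()
  expect_error(gamete_distribution(gt(zpg = c("E", "S")), m), "driver locus")
  expect_error(gamete_distribution(gt(cp = c("D", "S")), m), "payload locus")
  expect_error(genotype(zpg = c("D", "Q")), "unknown allele")
  expect_error(drive_model(locus_spec("a", "payload")), "exactly one driver")
})

test_that("homing efficiency decomposition round-trips", {
  gp <- germline_from_efficiency(0.92, p_cut = 0.98)
  expect_equal(gp$p_cut * gp$p_hdr, 0.92, tolerance = 1e-12)
  expect_error(germline_from_efficiency(0.99, p_cut = 0.5), "exceed p_cut")
})
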