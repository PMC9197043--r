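# Amplicon resistance-allele classification and generation contrasts.

site <- synthetic_target_site()
ref <- site$reference
setchar <- function(s, pos, val) {
  # pos is 0-based window coordinate
  v <- strsplit(s, "")[[1]]
  v[pos + 1] <- val
  paste(v, collapse = "")
}

test_that("the classifier truth table holds on constructed edits", {
  # reference itself: susceptible
  expect_false(classify_allele(ref, site)$resistant)
  # edit strictly outside spacer + PAM: susceptible
  distal <- setchar(ref, 10, if (substr(ref, 11, 11) == "A") "C" else "A")
  expect_false(classify_allele(distal, site)$resistant)
  # natural-style 4-SNP haplotype inside the spacer: resistant, R1
  pool <- synthetic_allele_pool(site)
  snp4 <- pool$aligned_sequence[pool$name == "snp4_r1"]
  call <- classify_allele(snp4, site)
  expect_true(call$resistant)
  expect_equal(call$r_class, "R1")
  expect_true(all(call$edits$type == "sub"))
  # 1 bp deletion at the cut site: frameshift, R2
  del1 <- setchar(ref, 116, "-")
  call2 <- classify_allele(del1, site)
  expect_true(call2$resistant)
  expect_equal(call2$r_class, "R2")
  # in-frame 3 bp deletion at the cut site: R1
  del3 <- ref
  for (p in 114:116) del3 <- setchar(del3, p, "-")
  expect_equal(classify_allele(del3, site)$r_class, "R1")
})

test_that("insertions anchored in the spacer are resistant with frame-dependent class", {
  ins3 <- classify_allele(ref, site, insertions = "116:TTT")
  expect_true(ins3$resistant)
  expect_equal(ins3$r_class, "R1")
  ins1 <- classify_allele(ref, site, insertions = "116:T")
  expect_equal(ins1$r_class, "R2")
  # anchored outside the spacer/PAM: not resistant
  expect_false(classify_allele(ref, site, insertions = "10:AAA")$resistant)
})

test_that("substitutions creating a stop codon or destroying the start codon are R2", {
  # codon spanning window positions 102-104 lies inside the spacer
  stopy <- ref
  for (i in 0:2) stopy <- setchar(stopy, 102 + i, c("T", "A", "A")[i + 1])
  call <- classify_allele(stopy, site)
  expect_true(call$resistant)
  expect_equal(call$r_class, "R2")
  # spacer SNP plus a destroyed ATG start codon
  pool <- synthetic_allele_pool(site)
  snp4 <- pool$aligned_sequence[pool$name == "snp4_r1"]
  nostart <- setchar(snp4, 1, "A")  # ATG -> AAG
  expect_equal(classify_allele(nostart, site)$r_class, "R2")
})

test_that("misaligned observations raise an alignment error", {
  expect_error(classify_allele(substr(ref, 1, 100), site), "misaligned")
  expect_error(classify_allele(ref, site, insertions = "400:A"),
               "outside reference window")
})

test_that("resistant read fractions aggregate per sample and scale-invariantly", {
  pool <- synthetic_allele_pool(site)
  tab <- data.frame(sample = "s1", aligned_sequence = pool$aligned_sequence,
                    insertions = pool$insertions,
                    n_reads = c(40, 20, 20, 20, 0) + c(0, 0, 0, 0, 1))
  # 60 resistant reads (snp4 + del3 + del1) of 101 total
  rf <- resistant_fraction(tab, site)
  expect_equal(rf$pct_resistant, 100 * 60 / 101)
  tab2 <- tab; tab2$n_reads <- tab$n_reads * 17L
  expect_equal(resistant_fraction(tab2, site)$pct_resistant,
               rf$pct_resistant)
  allref <- data.frame(sample = c("a", "b"), aligned_sequence = ref,
                       insertions = "", n_reads = 100)
  expect_equal(resistant_fraction(allref, site)$pct_resistant, c(0, 0))
  expect_error(resistant_fraction(allref[0, ], site), "empty")
})

test_that("top alleles are ranked by mean frequency with zero-filling and lexicographic ties", {
  pool <- synthetic_allele_pool(site)
  res_seqs <- pool$aligned_sequence[pool$resistant]
  # allele res_seqs[1] only present in G6; rarest allele must drop from top-2
  tab <- rbind(
    data.frame(sample = "G1", aligned_sequence = c(ref, res_seqs[2], res_seqs[3]),
               insertions = "", n_reads = c(70, 20, 10)),
    data.frame(sample = "G6", aligned_sequence = c(ref, res_seqs[1], res_seqs[2]),
               insertions = "", n_reads = c(40, 30, 30)))
  top <- top_alleles(tab, site, k = 2)
  expect_equal(nrow(top), 2)
  # zero-filled: the G6-only allele has frequency 0 at G1
  g6only <- top[top$aligned_sequence == res_seqs[1], ]
  expect_equal(g6only$pct_G1, 0)
  expect_equal(g6only$pct_G6, 30)
  # rarest (res_seqs[3], mean 5%) excluded from top 2
  expect_false(res_seqs[3] %in% top$aligned_sequence)
  # per-sample frequencies sum to at most 100
  pcts <- top[, grepl("^pct_", names(top))]
  expect_true(all(colSums(pcts) <= 100 + 1e-9))

  # ties break lexicographically on the sequence
  tie <- data.frame(sample = "s", aligned_sequence = c(res_seqs[1], res_seqs[2]),
                    insertions = "", n_reads = c(50, 50))
  tie <- rbind(tie, data.frame(sample = "s", aligned_sequence = ref,
                               insertions = "", n_reads = 100))
  tt <- top_alleles(tie, site, k = 2)
  expect_equal(tt$aligned_sequence, sort(c(res_seqs[1], res_seqs[2])))
  # single resistant allele: ranking of length 1
  one <- top_alleles(tie[c(1, 3), ], site, k = 5)
  expect_equal(nrow(one), 1)
})

test_that("generation contrasts handle identical, shifted and mismatched inputs", {
  x <- c(10, 20, 30, 40)
  same <- generation_contrast(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$fold_change, 1)
  shifted <- generation_contrast(x, x + 5)
  expect_true(shifted$zero_variance)
  expect_equal(shifted$t, Inf)
  expect_error(generation_contrast(x, x[1:3]), "differ in length")
  zero <- generation_contrast(c(0, 0, 0), c(1, 3, 2))
  expect_true(zero$fold_undefined)
  # ordinary case agrees with stats::t.test
  g1 <- c(12, 9, 15, 11); g6 <- c(30, 25, 40, 28)
  gc <- generation_contrast(g1, g6)
  ht <- t.test(g6, g1, paired = TRUE)
  expect_equal(gc$t, unname(ht$statistic))
  expect_equal(gc$p, ht$p.value)
  expect_equal(gc$fold_change, mean(g6) / mean(g1))
})

test_that("sequence-only haplotype prediction matches the classifier for substitution-only alleles", {
  pool <- synthetic_allele_pool(site)
  for (i in seq_len(nrow(pool))) {
    seqi <- pool$aligned_sequence[i]
    if (grepl("-", seqi, fixed = TRUE)) next
    pred <- predict_haplotype_resistance(seqi, site)
    expect_equal(pred == "resistant", pool$resistant[i])
  }
  # a mismatch 30 nt upstream of the spacer is susceptible
  up <- setchar(ref, 70, if (substr(ref, 71, 71) == "G") "T" else "G")
  expect_equal(predict_haplotype_resistance(up, site), "susceptible")
  # seed mode ignores PAM-distal spacer mismatches
  distal_spacer <- setchar(ref, 101, if (substr(ref, 102, 102) == "G") "T" else "G")
  expect_equal(predict_haplotype_resistance(distal_spacer, site), "resistant")
  expect_equal(predict_haplotype_resistance(distal_spacer, site, mode = "seed"),
               "susceptible")
  expect_error(predict_haplotype_resistance(substr(ref, 1, 10), site),
               "window length")
})

test_that("antisense-annotated sites are flipped into window coordinates at load", {
  L <- nchar(ref)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    locus = "syn_minus", reference = rc, strand = "-",
    spacer_start = L - site$spacer_end, spacer_end = L - site$spacer_start,
    pam_start = L - site$pam_end, pam_end = L - site$pam_start,
    cut_pos = L - site$cut_pos, frame_offset = L - 1 - site$frame_offset,
    translation_direction = "-", start_codon_pos = L - 3 - site$start_codon_pos),
    path, auto_unbox = TRUE)
  loaded <- read_target_site(path)
  expect_equal(loaded$reference, ref)
  expect_equal(loaded$spacer_start, site$spacer_start)
  expect_equal(loaded$pam_end, site$pam_end)
  expect_equal(loaded$cut_pos, site$cut_pos)
  expect_equal(loaded$translation_direction, "+")
  expect_equal(loaded$start_codon_pos, site$start_codon_pos)
})
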