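test_that("founder panels are inbred, MAF-bounded and follow the marker-ID convention", {
  cfg <- sim_config(n_lines = 456, n_markers = 210, maf_range = c(0.05, 0.5),
                    seed = 1)
  g <- simulate_founders(cfg)
  expect_equal(dim(g), c(456L, 210L))
  expect_true(all(g$dosage %in% c(0, 2)))
  maf <- colMeans(g$dosage) / 2
  expect_true(all(maf >= 0.05 & maf <= 0.5))
  expect_true(all(grepl("^S[1-7][ABD]_[0-9]+$", colnames(g$dosage))))
  # round-robin chromosome assignment: 210 markers over 21 chromosomes
  expect_true(all(table(g$map$chrom) == 10))
  # determinism
  g2 <- simulate_founders(cfg)
  expect_identical(g$dosage, g2$dosage)
})

test_that("empirical allele frequency matches the binomial target at large n", {
  cfg <- sim_config(n_lines = 10000, n_markers = 21, n_chromosomes = 21,
                    n_qtl = 5, maf_range = c(0.3, 0.3), seed = 42)
  g <- simulate_founders(cfg)
  maf <- colMeans(g$dosage) / 2
  expect_true(all(abs(maf - 0.3) < 0.02))
})

test_that("founder generation rejects degenerate configurations", {
  expect_error(sim_config(n_markers = 5, n_chromosomes = 21), "n_markers")
  expect_error(sim_config(maf_range = c(0.5, 0.05)), "maf_range")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(block_size = 3, n_checks = 3), "block_size")
})

test_that("identical parents give progeny identical to the parents", {
  p <- toy_geno(rbind(c(0, 2, 2, 0), c(0, 2, 2, 0)))
  for (ty in c("DH", "F5")) {
    prog <- derive_biparental(p, 20, pop_type = ty, seed = 3)
    expect_true(all(prog$dosage == matrix(c(0, 2, 2, 0), 20, 4, byrow = TRUE)))
  }
})

test_that("DH progeny are homozygous with 50/50 Mendelian segregation", {
  cfg <- sim_config(n_lines = 2, n_markers = 40, n_chromosomes = 1,
                    maf_range = c(0.4, 0.5), seed = 5)
  p <- simulate_founders(cfg)
  # force full polymorphism between the parents
  p$dosage[1, ] <- 0; p$dosage[2, ] <- 2
  prog <- derive_biparental(p, 5000, pop_type = "DH", seed = 7)
  expect_true(all(prog$dosage %in% c(0, 2)))
  freq_p2 <- colMeans(prog$dosage) / 2
  expect_true(all(abs(freq_p2 - 0.5) < 0.02))
})

test_that("F5 progeny retain ~1/16 residual heterozygosity at segregating loci", {
  cfg <- sim_config(n_lines = 2, n_markers = 60, n_chromosomes = 3, seed = 5)
  p <- simulate_founders(cfg)
  p$dosage[1, ] <- 0; p$dosage[2, ] <- 2
  prog <- derive_biparental(p, 5000, pop_type = "F5", seed = 11)
  het <- mean(prog$dosage == 1)
  expect_lt(abs(het - 1 / 16), 0.01)
})

test_that("non-homozygous parents are rejected", {
  p <- toy_geno(rbind(c(0, 1), c(2, 0)))
  expect_error(derive_biparental(p, 5, "DH"), "homozygous")
})

test_that("noiseless trials reproduce genetic values exactly", {
  cfg <- small_cfg(h2_target = 1, seed = 2)
  g <- simulate_founders(cfg)
  tr <- simulate_trial(g, cfg)
  fb <- tr$fieldbook[!tr$fieldbook$is_check, ]
  # plot value minus block effect and grand mean equals the genetic value;
  # with h2 = 1 block effects are zero (20% of a zero residual SD)
  for (e in cfg$environments) {
    sub <- fb[fb$environment == e, ]
    expect_equal(sub$yield_t_ha - cfg$mu,
                 unname(tr$truth$true_genetic_values[sub$line_id, e]),
                 tolerance = 1e-12)
  }
  expect_equal(unname(tr$truth$realized_h2), c(1, 1))
})

test_that("perfect G-by-E correlation gives identical genetic value columns", {
  cfg <- small_cfg(gxe_corr = 1, seed = 3)
  g <- simulate_founders(cfg)
  tr <- simulate_trial(g, cfg)
  gv <- tr$truth$true_genetic_values
  expect_equal(gv[, 1], gv[, 2], tolerance = 1e-10)
})

test_that("ACBD layout: checks in every block, tests unreplicated per environment", {
  cfg <- small_cfg(seed = 4)
  g <- simulate_founders(cfg)
  fb <- simulate_trial(g, cfg)$fieldbook
  for (e in cfg$environments) {
    sub <- fb[fb$environment == e, ]
    per_block <- table(sub$block[sub$is_check], sub$line_id[sub$is_check])
    expect_true(all(per_block == 1))        # every check once in every block
    tests <- sub$line_id[!sub$is_check]
    expect_equal(anyDuplicated(tests), 0L)  # tests unreplicated
    expect_setequal(tests, rownames(g$dosage))
  }
})

test_that("realized heritability is calibrated to the target", {
  h2s <- vapply(1:60, function(s) {
    cfg <- small_cfg(n_lines = 500, n_markers = 60, n_qtl = 20,
                     h2_target = 0.5, seed = s)
    g <- simulate_founders(cfg)
    mean(simulate_trial(g, cfg)$truth$realized_h2)
  }, numeric(1))
  expect_gt(mean(h2s), 0.45)
  expect_lt(mean(h2s), 0.55)
})

test_that("genetic-value correlation between environments converges to gxe_corr", {
  # many QTL so the realized effect correlation concentrates around the target
  cfg <- small_cfg(n_lines = 2000, n_markers = 1050, n_qtl = 1000,
                   gxe_corr = 0.3, seed = 6)
  g <- simulate_founders(cfg)
  gv <- simulate_trial(g, cfg)$truth$true_genetic_values
  expect_lt(abs(cor(gv[, 1], gv[, 2]) - 0.3), 0.05)
})

test_that("same seed gives identical field books; h2 contradictions are rejected", {
  cfg <- small_cfg(seed = 9)
  g <- simulate_founders(cfg)
  expect_identical(simulate_trial(g, cfg)$fieldbook,
                   simulate_trial(g, cfg)$fieldbook)
  cfg0 <- small_cfg(seed = 9); cfg0$h2_target <- 0
  expect_error(simulate_trial(g, cfg0), "h2_target")
})

test_that("genotype and field-book CSV round-trips are lossless", {
  cfg <- small_cfg(n_lines = 5, n_markers = 8, seed = 10)
  g <- simulate_founders(cfg)
  f <- tempfile(fileext = ".csv")
  write_genotype_csv(g, f)
  g2 <- read_genotype_csv(f)
  expect_identical(g$dosage, g2$dosage)
  fb <- simulate_trial(g, cfg)$fieldbook
  f2 <- tempfile(fileext = ".csv")
  write_fieldbook_csv(fb, f2)
  fb2 <- read_fieldbook_csv(f2)
  expect_equal(fb$yield_t_ha, fb2$yield_t_ha, tolerance = 1e-10)
  expect_identical(fb$line_id, fb2$line_id)
  # minimal VCF is writable and carries one row per marker
  f3 <- tempfile(fileext = ".vcf")
  write_genotype_vcf(g, f3)
  expect_equal(sum(!startsWith(readLines(f3), "#")), ncol(g$dosage))
})
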