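test_that("the same config and seed give byte-identical serialized output", {
  cfg <- small_cfg(seed = 9)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_dataset(simulate_dataset(cfg), d1)
  p2 <- write_dataset(simulate_dataset(cfg), d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     info = paste("file:", f))
  }
})

test_that("realized FNP frequencies stay within 3 binomial SE of targets", {
  for (seed in 1:5) {
    sim <- simulate_dataset(sim_config(seed = seed))
    ff <- sim$truth$fnp_freq
    se <- sqrt(pmax(ff$target * (1 - ff$target), 1e-9) / ff$n)
    expect_true(all(abs(ff$realized - ff$target) <= pmax(3 * se, 1e-9) + 1e-9),
                info = paste("seed", seed))
  }
})

test_that("a 0.97 wild-ecotype target with n = 100 lands in [0.92, 1]", {
  cfg <- sim_config(
    n_samples = c(outgroup = 10, wild_A = 20, wild_B = 100,
                  cultivar_A = 16, cultivar_B = 16),
    fnp_freq = c(outgroup = 0, wild_A = 0.84, wild_B = 0.97,
                 cultivar_A = 0.995, cultivar_B = 0.005),
    seed = 5
  )
  sim <- simulate_dataset(cfg)
  got <- sim$truth$fnp_freq$realized[sim$truth$fnp_freq$subpop == "wild_B"]
  expect_gte(got, 0.92)
  expect_lte(got, 1)
})

test_that("cultivar heterozygosity stays near the configured rate", {
  sim <- simulate_dataset(sim_config(seed = 3))
  cult <- sim$gt$samples$subpop %in% c("cultivar_A", "cultivar_B")
  g <- sim$gt$geno[cult, ]
  het <- sum(g == 2L) / sum(g != -1L)
  rate <- sim$config$het_rate
  se <- sqrt(rate * (1 - rate) / sum(g != -1L))
  expect_lte(het, rate + 3 * se)
})

test_that("the FNP is the focal gene's only coding variant and translates Glu>Lys", {
  sim <- simulate_dataset(sim_config(seed = 7))
  aa <- build_aa_matrix(sim$gt, sim$genes, sim$ref)
  focal <- aa$variants[aa$variants$gene == "gene_focal", ]
  expect_equal(nrow(focal), 1)
  expect_equal(focal$coding_pos, 511L)
  expect_equal(focal$codon_index, 171L)
  expect_equal(focal$ref_aa, "Glu")
  expect_equal(focal$alt_aa, "Lys")
})

test_that("sweep intensity 1 leaves the matrix unchanged", {
  sim <- simulate_dataset(small_cfg(seed = 2, sweep_intensity = 1))
  gt2 <- inject_sweep(sim$gt, c(25000, 35000), 1, sim$truth$fnp$pos)
  expect_identical(gt2$geno, sim$gt$geno)
})

test_that("a region without SNPs warns and returns the input", {
  sim <- simulate_dataset(small_cfg(seed = 2))
  # an empty 1-bp slice between sites
  gap <- setdiff(seq_len(60000), sim$gt$sites$pos)[1]
  expect_warning(
    gt2 <- inject_sweep(sim$gt, c(gap, gap + 1), 0.1, sim$truth$fnp$pos),
    "no SNPs"
  )
  expect_identical(gt2$geno, sim$gt$geno)
})

test_that("invalid sweep calls error", {
  sim <- simulate_dataset(small_cfg(seed = 2))
  fnp <- sim$truth$fnp$pos
  expect_error(inject_sweep(sim$gt, c(35000, 25000), 0.1, fnp), "interval")
  expect_error(inject_sweep(sim$gt, c(25000, 35000), 0, fnp), "intensity")
  expect_error(
    inject_sweep(sim$gt, c(25000, 35000), 0.1, fnp, allele = "alt",
                 samples = sim$gt$samples$sample[sim$gt$samples$subpop == "outgroup"]),
    "no carrier"
  )
})

test_that("intensity 0.1 reduces carrier diversity to <= 0.15 of input", {
  set.seed(201)
  # ~100 carriers of a polymorphic background, all carrying the alt FNP
  s <- 120
  pos <- sort(sample(9000, s))
  fnp_pos <- pos[60]
  codes <- matrix(rbinom(100 * s, 1L, rep(runif(s, 0.05, 0.5), each = 100)),
                  100, s)
  codes[, 60] <- 1L
  gt <- make_gt(codes, pos = pos)
  region <- c(1, 10001)
  before <- window_pi(gt, region = region, window = 10000)$pi
  gt2 <- inject_sweep(gt, region, 0.1, fnp_pos, allele = "alt")
  after <- window_pi(gt2, region = region, window = 10000)$pi
  expect_lte(after, 0.15 * before)
  # sites outside the region untouched (none here, so check geometry instead)
  expect_identical(gt2$sites, gt$sites)
})

test_that("sites outside the swept region are untouched", {
  sim <- simulate_dataset(small_cfg(seed = 4, sweep_intensity = 1))
  region <- c(28000, 32000)
  gt2 <- inject_sweep(sim$gt, region, 0.1, sim$truth$fnp$pos)
  outside <- sim$gt$sites$pos < region[1] | sim$gt$sites$pos >= region[2]
  expect_identical(gt2$geno[, outside], sim$gt$geno[, outside])
})

test_that("a noiseless phenotype is exactly additive and truncated", {
  sim <- simulate_dataset(small_cfg(seed = 6))
  fnp <- sim$truth$fnp$pos
  ph <- simulate_phenotype(sim$gt, fnp, effect = 20, noise_sd = 0,
                           baseline = 50)
  j <- match(fnp, sim$gt$sites$pos)
  hom <- sim$gt$geno[, j] %in% c(0L, 1L)
  vals <- sort(unique(ph$ltss[hom]))
  expect_equal(vals, c(50, 70))

  ph2 <- simulate_phenotype(sim$gt, fnp, effect = 80, noise_sd = 0,
                            baseline = 90)
  expect_true(all(ph2$ltss <= 100, na.rm = TRUE))
  ph3 <- simulate_phenotype(sim$gt, fnp, effect = -80, noise_sd = 0,
                            baseline = 20)
  expect_true(all(ph3$ltss >= 0, na.rm = TRUE))
})

test_that("a monomorphic FNP warns that association will be unpowered", {
  gt <- make_gt(matrix(0L, 6, 3), pos = c(10L, 20L, 30L))
  expect_warning(simulate_phenotype(gt, 20, effect = 20, noise_sd = 1),
                 "monomorphic")
})

test_that("a zero effect leaves the marker slope centred on zero", {
  set.seed(211)
  slopes <- replicate(50, {
    codes <- matrix(rbinom(80 * 5, 1L, 0.5), 80, 5)
    gt <- make_gt(codes, pos = c(10L, 20L, 30L, 40L, 50L))
    ph <- simulate_phenotype(gt, 30, effect = 0, noise_sd = 8, baseline = 50)
    x <- ifelse(codes[, 3] == 1L, 1, 0)
    coef(lm(ph$ltss ~ x))[2]
  })
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(50))
})

test_that("without a sweep, focal diversity matches the background", {
  # over replicates the focal-region pi of the in-species panel stays
  # within 2 SD of the flank values when no sweep is injected
  # a short CDS so the variant-free coding span cannot shadow the
  # focal-vs-flank comparison
  pis <- sapply(1:20, function(sd) {
    cfg <- small_cfg(seed = 500 + sd, sweep_intensity = 1, hap_div_frac = 0,
                     focal_cds_start = 29721, focal_cds_length = 60,
                     fnp_coding_pos = 31)
    sim <- simulate_dataset(cfg)
    ids <- sim$gt$samples$sample[sim$gt$samples$subpop == "cultivar_A"]
    regs <- focal_regions(cfg)
    vapply(seq_len(3), function(i) {
      window_pi(sim$gt, samples = ids,
                region = c(regs$start[i], regs$end[i]),
                window = regs$end[i] - regs$start[i])$pi
    }, numeric(1))
  })
  focal <- pis[2, ]
  flank <- c(pis[1, ], pis[3, ])
  expect_lt(abs(mean(focal) - mean(flank)), 2 * sd(flank))
})

test_that("under a sweep the carrier focal pi drops below the flanks", {
  wins <- sapply(1:50, function(sd) {
    cfg <- small_cfg(seed = 700 + sd, sweep_intensity = 0.1)
    sim <- simulate_dataset(cfg)
    ids <- sim$gt$samples$sample[sim$gt$samples$subpop == "cultivar_A"]
    regs <- focal_regions(cfg)
    pi3 <- vapply(seq_len(3), function(i) {
      window_pi(sim$gt, samples = ids,
                region = c(regs$start[i], regs$end[i]),
                window = regs$end[i] - regs$start[i])$pi
    }, numeric(1))
    pi3[2] < pi3[1] && pi3[2] < pi3[3]
  })
  expect_gte(mean(wins), 0.9)
})
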