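test_that("scores are the mean base score over a sample's usable markers", {
  # three markers, bases A/C/G for sample 1 -> (1 + 3 + 4) / 3
  codes <- rbind(c(0L, 0L, 0L), c(1L, 1L, 1L),
                 c(0L, 1L, 0L), c(1L, 0L, 1L))
  gt <- make_gt(codes, pos = c(10L, 20L, 30L),
                ref = c("A", "C", "G"), alt = c("T", "G", "C"))
  st <- haplotype_scores(gt, c(1, 40), maf_min = 0.2)
  expect_equal(st$score[1], (1 + 3 + 4) / 3, tolerance = 1e-12)
  expect_equal(st$score[2], (2 + 4 + 3) / 3, tolerance = 1e-12)
  expect_equal(st$n_markers_used, rep(3L, 4))
})

test_that("all-A and all-G samples sit at the score range endpoints", {
  codes <- rbind(rep(0L, 4), rep(1L, 4), c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L))
  gt <- make_gt(codes, ref = rep("A", 4), alt = rep("G", 4))
  st <- haplotype_scores(gt, c(1, 100), maf_min = 0.2)
  expect_equal(st$score[1], 1)
  expect_equal(st$score[2], 4)
  expect_true(all(st$score >= 1 & st$score <= 4))
})

test_that("markers below the MAF threshold are excluded from scoring", {
  rare <- c(1L, rep(0L, 9))
  common <- rep(c(0L, 1L), 5)
  gt <- make_gt(cbind(rare, common), ref = c("A", "A"), alt = c("G", "G"))
  st <- haplotype_scores(gt, c(1, 100), maf_min = 0.2)
  expect_equal(length(attr(st, "markers")), 1)
  # the rare marker (freq 0.1) contributes to nobody's mean
  expect_equal(st$score, ifelse(common == 1L, 4, 1))
})

test_that("no qualifying marker is an error citing the threshold", {
  gt <- make_gt(cbind(c(1L, rep(0L, 9))))
  expect_error(haplotype_scores(gt, c(1, 100), maf_min = 0.2), "0.2")
})

test_that("heterozygous and missing calls drop out of a sample's mean", {
  codes <- rbind(c(0L, 2L), c(1L, -1L), c(0L, 1L), c(1L, 0L), c(0L, 1L))
  gt <- make_gt(codes, ref = c("A", "T"), alt = c("G", "C"))
  st <- suppressMessages(haplotype_scores(gt, c(1, 100), maf_min = 0.2))
  expect_equal(st$score[1], 1)      # only marker 1 usable (A)
  expect_equal(st$score[2], 4)      # only marker 1 usable (G)
  expect_equal(st$n_markers_used[1:2], c(1L, 1L))
})

test_that("scores are invariant to marker order and sample duplication", {
  set.seed(251)
  codes <- matrix(rbinom(20 * 6, 1L, 0.5), 20, 6)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 6, TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "x")
  gt1 <- make_gt(codes, pos = c(10L, 20L, 30L, 40L, 50L, 60L),
                 ref = ref, alt = alt)
  perm <- c(3, 1, 6, 2, 5, 4)
  gt2 <- make_gt(codes[, perm], pos = c(10L, 20L, 30L, 40L, 50L, 60L),
                 ref = ref[perm], alt = alt[perm])
  s1 <- haplotype_scores(gt1, c(1, 100))
  s2 <- haplotype_scores(gt2, c(1, 100))
  expect_equal(s1$score, s2$score)

  gt3 <- make_gt(rbind(codes, codes), pos = c(10L, 20L, 30L, 40L, 50L, 60L),
                 ref = ref, alt = alt)
  s3 <- haplotype_scores(gt3, c(1, 100))
  expect_equal(s3$score[1:20], s1$score)
})

test_that("two separated clusters are called bimodal, with the coefficient reported", {
  set.seed(261)
  scores <- c(rnorm(50, 1.2, 0.05), rnorm(50, 3.8, 0.05))
  out <- assess_modality(list(mix = scores))
  expect_gt(out$bimodality, 5 / 9)
  expect_equal(out$verdict, "bimodal")
})

test_that("a uniform sample sits near the 5/9 boundary", {
  set.seed(271)
  out <- assess_modality(list(u = runif(5000, 1, 4)))
  expect_equal(out$bimodality, 5 / 9, tolerance = 0.05)
})

test_that("groups below five scores are rejected", {
  expect_error(assess_modality(list(tiny = c(1, 2, 3, 4))), "n = 4 < 5")
})

test_that("allele frequencies, heterozygosity and ancestral state are summarised", {
  codes <- c(rep(0L, 97), rep(1L, 3),          # pop 97% ref
             rep(0L, 10))                      # outgroup unanimous ref
  gt <- make_gt(cbind(codes), pos = 511L, ref = "G", alt = "A",
                subpop = rep(c("rufipogon_III", "outgroup"), c(100, 10)))
  fs <- fnp_summary(gt, 511, outgroup = "outgroup")
  expect_equal(fs$ancestral, "G")
  expect_equal(fs$support, 10L)
  row <- fs$by_subpop[fs$by_subpop$subpop == "rufipogon_III", ]
  expect_equal(1 - row$alt_freq, 0.97)          # G frequency
  expect_equal(row$derived_freq, 0.03)
  expect_equal(row$heterozygosity, 0)
})

test_that("heterozygotes contribute half an allele and full heterozygosity", {
  gt <- make_gt(cbind(c(0L, 1L, 2L, 2L)), pos = 100L,
                subpop = c("p", "p", "p", "outgroup"))
  fs <- fnp_summary(gt, 100)
  row <- fs$by_subpop[fs$by_subpop$subpop == "p", ]
  expect_equal(row$alt_freq, (1 + 0.5) / 3)
  expect_equal(row$heterozygosity, 1 / 3)
})

test_that("an ungenotyped outgroup leaves the ancestral state undetermined", {
  gt <- make_gt(cbind(c(0L, 1L, -1L)), pos = 50L,
                subpop = c("p", "p", "outgroup"))
  fs <- fnp_summary(gt, 50)
  expect_equal(fs$ancestral, "undetermined")
  expect_true(all(is.na(fs$by_subpop$derived_freq)))
})
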