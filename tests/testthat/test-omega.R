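test_that("the omega formula evaluates crafted LD configurations", {
  r2 <- matrix(0.25, 4, 4)
  r2[1, 2] <- r2[2, 1] <- 1
  r2[3, 4] <- r2[4, 3] <- 1
  diag(r2) <- 1
  expect_equal(omega_statistic(r2, 1:2, 3:4), 4.0)

  flat <- matrix(0.3, 5, 5)
  expect_equal(omega_statistic(flat, 1:2, 3:5), 1.0)

  zero_bt <- matrix(0, 4, 4)
  zero_bt[1, 2] <- zero_bt[2, 1] <- 0.5
  zero_bt[3, 4] <- zero_bt[4, 3] <- 0.5
  expect_true(is.na(omega_statistic(zero_bt, 1:2, 3:4)))

  expect_error(omega_statistic(r2, 1:2, 2:3), "overlap")
  expect_true(is.na(omega_statistic(r2, 1, 2:4)))   # flank too small
})

test_that("the grid spans the chromosome at the configured spacing", {
  set.seed(101)
  gt <- random_gt(12, 30, pos = sort(sample(1e6, 30)))
  track <- omega_scan(gt, omega_config(), chrom_length = c(chr1 = 1e6))
  expect_equal(nrow(track), 200)
  expect_equal(track$pos, seq(5000, 1e6, by = 5000))
})

test_that("grid points inside an extended mask carry no omega", {
  set.seed(111)
  gt <- random_gt(20, 60, pos = sort(sample(2e5, 60)))
  cfg <- omega_config(
    mask = tibble::tibble(chrom = "chr1", start = 90000, end = 95000),
    mask_flank = 20000
  )
  track <- omega_scan(gt, cfg, chrom_length = c(chr1 = 2e5))
  masked <- track$pos >= 70000 & track$pos <= 115000
  expect_true(all(track$masked[masked]))
  expect_true(all(is.na(track$omega[masked])))
  expect_false(any(track$masked[!masked]))
})

test_that("the scan equals brute-force split enumeration on small instances", {
  set.seed(121)
  for (rep in 1:6) {
    s <- sample(12:20, 1)
    pos <- sort(sample(2000, s))
    gt <- random_gt(25, s, pos = pos, missing = 0.05)
    cfg <- omega_config(grid_spacing = 250, minwin = 40, maxwin = 700)
    track <- omega_scan(gt, cfg, chrom_length = c(chr1 = 2000))
    r2 <- r2_matrix(gt)
    maf <- site_maf(gt)
    poly <- !is.na(maf) & maf > 0
    for (k in seq_len(nrow(track))) {
      want <- omega_point_oracle(r2[poly, poly, drop = FALSE], pos[poly],
                                 track$pos[k], cfg$minwin, cfg$maxwin)
      expect_equal(track$omega[k], want, tolerance = 1e-10,
                   info = sprintf("rep %d grid %d", rep, track$pos[k]))
    }
  }
})

test_that("omega is invariant to ref/alt relabeling at any site", {
  set.seed(131)
  pos <- sort(sample(3000, 15))
  gt <- random_gt(20, 15, pos = pos)
  cfg <- omega_config(grid_spacing = 500, minwin = 50, maxwin = 1000)
  t1 <- omega_scan(gt, cfg, chrom_length = c(chr1 = 3000))
  flip <- sample(15, 5)
  gt2 <- gt
  gt2$geno[, flip] <- ifelse(gt$geno[, flip] == 0L, 1L,
                             ifelse(gt$geno[, flip] == 1L, 0L,
                                    gt$geno[, flip]))
  t2 <- omega_scan(gt2, cfg, chrom_length = c(chr1 = 3000))
  expect_equal(t1$omega, t2$omega)
})

test_that("exactly the top fraction of a tie-free 200-point track is flagged", {
  set.seed(141)
  om <- sample(seq(0.5, 40, length.out = 200))
  track <- tibble::tibble(chrom = "chr1", pos = seq(5000, 1e6, 5000),
                          omega = om, masked = FALSE)
  class(track) <- c("omega_track", class(track))
  calls <- call_sweep_regions(track, top_fraction = 0.05)
  expect_equal(sum(calls$track$flagged), 10)
  expect_equal(calls$thresholds$n_flagged, 10)
})

test_that("threshold ties are all flagged, possibly exceeding the fraction", {
  om <- c(rep(1, 90), rep(7, 10))   # 10th largest = 7, with 10-way tie
  om[95:100] <- 7
  track <- tibble::tibble(chrom = "chr1", pos = seq(5000, 5e5, 5000),
                          omega = om, masked = FALSE)
  class(track) <- c("omega_track", class(track))
  calls <- call_sweep_regions(track, top_fraction = 0.05)
  expect_equal(sum(calls$track$flagged), sum(om == 7))
  expect_gte(sum(calls$track$flagged), 5)
})

test_that("genes are flagged by half-open interval intersection only", {
  om <- rep(1, 100)
  om[c(20, 60)] <- 50                 # two non-adjacent flagged points
  track <- tibble::tibble(chrom = "chr1", pos = seq(5000, 5e5, 5000),
                          omega = om, masked = FALSE)
  class(track) <- c("omega_track", class(track))
  genes <- list(
    inside = gene_model("inside", "chr1", "+",
                        tibble::tibble(start = 99001, end = 99900)),
    between = gene_model("between", "chr1", "+",
                         tibble::tibble(start = 200001, end = 200900)),
    edge_out = gene_model("edge_out", "chr1", "+",
                          tibble::tibble(start = 102500, end = 103399)),
    edge_in = gene_model("edge_in", "chr1", "+",
                         tibble::tibble(start = 96601, end = 97500))
  )
  calls <- call_sweep_regions(track, genes, top_fraction = 0.02)
  got <- setNames(calls$genes$sweep_overlap, calls$genes$gene)
  expect_true(got[["inside"]])        # overlaps [97500, 102500)
  expect_false(got[["between"]])      # strictly between flagged points
  expect_false(got[["edge_out"]])     # starts exactly at the half-open end
  expect_true(got[["edge_in"]])       # ends exactly at the region start
})

test_that("an all-undefined track yields an empty result with a warning", {
  track <- tibble::tibble(chrom = "chr1", pos = seq(5000, 5e4, 5000),
                          omega = NA_real_, masked = FALSE)
  class(track) <- c("omega_track", class(track))
  expect_warning(calls <- call_sweep_regions(track), "no defined")
  expect_equal(nrow(calls$regions), 0)
})
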