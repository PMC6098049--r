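aln_from_strings <- function(x) {
  m <- do.call(rbind, strsplit(x, ""))
  rownames(m) <- names(x) %||% sprintf("q%02d", seq_along(x))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("identical sequences collapse to one haplotype with full count", {
  hs <- prepare_haplotypes(aln_from_strings(c("ACGT", "ACGT", "ACGT")))
  expect_equal(nrow(hs$haps), 1)
  expect_equal(hs$haps$count, 3)
  expect_equal(sort(unlist(hs$haps$members)), c("q01", "q02", "q03"))
})

test_that("sequences above the missing ceiling are dropped and logged", {
  aln <- aln_from_strings(c(a = "ACGTACGTAC", b = "ACGTACGTAC",
                            c = "NNNNACGTAC"))
  expect_message(
    hs <- prepare_haplotypes(aln, site_missing_max = 0.5,
                             seq_missing_max = 0.3),
    "dropped 1 sequence"
  )
  expect_equal(sum(hs$haps$count), 2)
  expect_equal(hs$n_dropped_seqs, 1)
})

test_that("everything dropped is an error citing the thresholds", {
  aln <- aln_from_strings(c("NNNN", "NNNN"))
  expect_error(
    suppressMessages(prepare_haplotypes(aln)),
    "ceiling"
  )
})

test_that("imputation follows the k-nearest-sequence majority vote", {
  set.seed(221)
  for (rep in 1:10) {
    n <- 8
    s <- 12
    m <- matrix(sample(c("A", "C", "G", "T"), n * s, replace = TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)), n, s)
    rownames(m) <- sprintf("q%02d", 1:n)
    holes <- cbind(sample(n, 3), sample(s, 3))
    m[holes] <- "N"
    hs <- prepare_haplotypes(m, site_missing_max = 0.5, seq_missing_max = 0.5,
                             impute_k = 3)
    filled <- do.call(rbind, strsplit(hs$haps$seq, ""))
    # reconstruct each original row from its collapsed haplotype
    for (h in seq_len(nrow(hs$haps))) {
      for (member in hs$haps$members[[h]]) {
        i <- match(member, rownames(m))
        for (col in which(m[i, ] == "N")) {
          want <- impute_oracle(m, i, col, k = 3)
          expect_equal(filled[h, col], want)
        }
      }
    }
  }
})

test_that("a two-step chain yields the unique minimum spanning tree", {
  hs <- prepare_haplotypes(aln_from_strings(c("AAAA", "AAAT", "AATT")))
  net <- build_msn(hs)
  expect_equal(nrow(net$edges), 2)
  expect_equal(sort(net$edges$weight), c(1, 1))
})

test_that("an equilateral triangle keeps all three edges", {
  hs <- prepare_haplotypes(aln_from_strings(c("AAC", "ACA", "CAA")))
  net <- build_msn(hs)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 2))
})

test_that("the network equals the union of all enumerated MSTs", {
  set.seed(231)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    s <- 10
    seqs <- unique(apply(
      matrix(sample(c("A", "G"), n * s, replace = TRUE), n, s),
      1, paste, collapse = ""
    ))
    if (length(seqs) < 3) next
    hs <- prepare_haplotypes(aln_from_strings(seqs))
    net <- build_msn(hs)
    mats <- do.call(rbind, strsplit(hs$haps$seq, ""))
    D <- as.matrix(stats::dist(apply(mats, 2, function(col) col == "A"),
                               method = "manhattan"))
    expect_identical(net_edge_keys(net), msn_union_oracle(D))
  }
})

test_that("the network always contains a spanning tree and ignores input order", {
  set.seed(241)
  seqs <- unique(replicate(6, paste(sample(c("A", "T", "G"), 8, TRUE),
                                    collapse = "")))
  hs1 <- prepare_haplotypes(aln_from_strings(seqs))
  hs2 <- prepare_haplotypes(aln_from_strings(rev(seqs)))
  n1 <- build_msn(hs1)
  n2 <- build_msn(hs2)
  expect_gte(nrow(n1$edges), nrow(n1$nodes) - 1)
  expect_equal(igraph::components(n1$graph)$no, 1)
  expect_identical(n1$edges, n2$edges)   # lexicographic node order
})

test_that("collapsing then expanding reproduces the retained sample count", {
  sim <- simulate_dataset(small_cfg(seed = 8))
  aln <- genotypes_to_alignment(sim$gt, c(27000, 33000))
  hs <- suppressMessages(prepare_haplotypes(aln, labels = sim$gt$samples))
  expect_equal(sum(hs$haps$count), length(unlist(hs$haps$members)))
  expect_equal(sum(hs$composition$n), sum(hs$haps$count))
})

test_that("GraphML export carries counts and population fractions", {
  sim <- simulate_dataset(small_cfg(seed = 8))
  aln <- genotypes_to_alignment(sim$gt, c(27000, 33000))
  hs <- suppressMessages(prepare_haplotypes(aln, labels = sim$gt$samples))
  net <- build_msn(hs)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_hapnet_graphml(net, path, hapset = hs)
  txt <- readLines(path)
  expect_true(any(grepl("graphml", txt)))
  expect_true(any(grepl("frac_cultivar_A", txt)))
})
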