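test_that("genomic-to-coding mapping is strand aware and joins intervals", {
  g_plus <- gene_model("gp", "chr1", "+",
                       tibble::tibble(start = c(101, 301), end = c(200, 400)))
  expect_equal(map_to_cds(g_plus, 105), 5L)
  expect_equal(map_to_cds(g_plus, 301), 101L)
  expect_true(is.na(map_to_cds(g_plus, 250)))   # intron: non-coding, no error

  g_minus <- gene_model("gm", "chr1", "-",
                        tibble::tibble(start = 101, end = 200))
  expect_equal(map_to_cds(g_minus, 200), 1L)
  expect_equal(map_to_cds(g_minus, 101), 100L)
})

test_that("coding mapping is a bijection onto 1..CDS length", {
  set.seed(11)
  for (rep in 1:15) {
    n_iv <- sample(1:3, 1)
    starts <- sort(sample(seq(100, 900, by = 50), n_iv))
    lens <- sample(seq(9, 60, by = 3), n_iv)
    ends <- pmin(starts + lens - 1, c(starts[-1] - 10, 1000))
    total <- sum(ends - starts + 1)
    if (total %% 3 != 0) {
      ends[n_iv] <- ends[n_iv] - total %% 3
    }
    g <- gene_model("r", "chr1", sample(c("+", "-"), 1),
                    tibble::tibble(start = starts, end = ends))
    gpos <- unlist(Map(seq, g$cds$start, g$cds$end))
    cpos <- map_to_cds(g, gpos)
    expect_setequal(cpos, seq_len(cds_length(g)))
    expect_equal(cds_to_genomic(g, cpos), gpos)
  }
})

test_that("a G>A change at coding position 511 in a poly-Glu CDS hits codon 171", {
  cds <- strrep("GAG", 200)
  ann <- annotate_snp(cds, 511, "G", "A")
  expect_equal(ann$codon_index, 171L)
  expect_equal(ann$ref_aa, "Glu")
  expect_equal(ann$alt_aa, "Lys")
  expect_equal(ann$consequence, "nonsynonymous")
  expect_match(ann$label, "\\+511 G>A; \\+171 Glu>Lys")
})

test_that("silent and nonsense changes are classified", {
  wobble <- annotate_snp("GAA", 3, "A", "G")       # Glu -> Glu
  expect_equal(wobble$consequence, "synonymous")
  stopper <- annotate_snp("TGG", 3, "G", "A")      # Trp -> stop
  expect_equal(stopper$consequence, "nonsense")
  expect_equal(stopper$alt_aa, "stop")
})

test_that("reference mismatches and out-of-range positions are errors", {
  expect_error(annotate_snp("GAGGAG", 2, "G", "A"), "CDS has A.*claims G")
  expect_error(annotate_snp("GAGGAG", 7, "G", "A"), "beyond CDS")
  expect_error(annotate_snp("GAGG", 1, "G", "A"), "divisible by 3")
})

test_that("the marker matrix keeps nonsynonymous SNPs and drops the rest", {
  # CDS 1..9 on +: ATG GAG TGG; SNPs: pos 4 G>A (Glu>Lys, nonsyn),
  # pos 6 G>A (GAG>GAA Glu, syn), pos 20 outside CDS
  ref <- c(chr1 = paste0("ATGGAGTGG", strrep("A", 15)))
  genes <- list(g1 = gene_model("g1", "chr1", "+",
                                tibble::tibble(start = 1, end = 9)))
  codes <- rbind(c(0L, 1L, 0L), c(1L, 0L, 1L), c(2L, -1L, 0L), c(-1L, 0L, 1L))
  gt <- make_gt(codes, pos = c(4L, 6L, 20L),
                ref = c("G", "G", "A"), alt = c("A", "A", "G"))
  aa <- build_aa_matrix(gt, genes, ref)
  expect_equal(ncol(aa$markers), 1)
  expect_equal(aa$variants$coding_pos, 4L)
  # het and missing both become NA marker codes
  expect_equal(unname(aa$markers[, 1]), c(0, 1, NA, NA))
})

test_that("sites at or above the missing-rate ceiling are excluded", {
  ref <- c(chr1 = paste0("ATGGAGTGG", strrep("A", 15)))
  genes <- list(g1 = gene_model("g1", "chr1", "+",
                                tibble::tibble(start = 1, end = 9)))
  # 17 of 20 missing = 85% at the first site; 0% at the second
  codes <- cbind(c(rep(-1L, 17), 0L, 1L, 0L), rep(c(0L, 1L), 10))
  gt <- make_gt(codes, pos = c(4L, 7L), ref = c("G", "T"), alt = c("A", "C"))
  aa <- build_aa_matrix(gt, genes, ref, missing_max = 0.8)
  expect_equal(aa$variants$coding_pos, 7L)
})

test_that("a gene on a chromosome without reference errors by name", {
  genes <- list(gx = gene_model("gx", "chrX", "+",
                                tibble::tibble(start = 1, end = 9)))
  gt <- make_gt(rbind(0L, 1L), pos = 4L, chrom = "chrX")
  expect_error(build_aa_matrix(gt, genes, c(chr1 = "AAA")), "chrX.*gx")
})

test_that("translation agrees with a brute-force genetic-code oracle", {
  # independent translation direct from the codon table
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  cds <- paste(sample(bases, 60, replace = TRUE), collapse = "")
  for (k in 1:25) {
    pos <- sample(60, 1)
    ref_b <- substr(cds, pos, pos)
    alt_b <- sample(setdiff(bases, ref_b), 1)
    ann <- annotate_snp(cds, pos, ref_b, alt_b)
    ci <- ceiling(pos / 3)
    codon <- substr(cds, ci * 3 - 2, ci * 3)
    alt_codon <- codon
    substr(alt_codon, pos - (ci - 1) * 3, pos - (ci - 1) * 3) <- alt_b
    aa1 <- Biostrings::GENETIC_CODE[[codon]]
    aa2 <- Biostrings::GENETIC_CODE[[alt_codon]]
    want <- if (aa1 == aa2) "synonymous" else if (aa2 == "*") "nonsense"
            else "nonsynonymous"
    expect_equal(ann$consequence, want)
    expect_equal(ann$codon_index, ci)
  }
})
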