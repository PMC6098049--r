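#' Genomic / coding coordinate arithmetic
#'
#' Coding positions are 1-based with the first base of the coding region
#' as +1, counted 5'->3' on the coding strand: plus-strand genes count
#' from the genomically-leftmost CDS base, minus-strand genes from the
#' genomically-rightmost. `map_to_cds()` returns `NA` (a distinguished
#' "non-coding" result, not an error) for positions in introns, UTRs or
#' outside the gene. `cds_to_genomic()` is its inverse.
#'
#' @param gene a [gene_model()].
#' @param genomic_pos genomic position (1-based).
#' @return 1-based coding position, or `NA_integer_` if non-coding.
#' @export
map_to_cds <- function(gene, genomic_pos) {
  vapply(genomic_pos, function(p) {
    hit <- which(gene$cds$start <= p & p <= gene$cds$end)
    if (length(hit) == 0) return(NA_integer_)
    if (gene$strand == "+") {
      before <- sum(pmax(
        pmin(gene$cds$end, p - 1) - gene$cds$start + 1, 0
      )[gene$cds$start <= p - 1])
      as.integer(before + 1)
    } else {
      after <- sum(pmax(
        gene$cds$end - pmax(gene$cds$start, p + 1) + 1, 0
      )[gene$cds$end >= p + 1])
      as.integer(after + 1)
    }
  }, integer(1))
}

#' @rdname map_to_cds
#' @param coding_pos 1-based coding position in `1..cds_length(gene)`.
#' @export
cds_to_genomic <- function(gene, coding_pos) {
  vapply(coding_pos, function(cp) {
    if (cp < 1 || cp > cds_length(gene)) {
      abort("coding position outside the CDS")
    }
    if (gene$strand == "+") {
      iv <- gene$cds
      off <- cp
      for (i in seq_len(nrow(iv))) {
        len <- iv$end[i] - iv$start[i] + 1
        if (off <= len) return(iv$start[i] + off - 1)
        off <- off - len
      }
    } else {
      iv <- gene$cds[rev(seq_len(nrow(gene$cds))), ]
      off <- cp
      for (i in seq_len(nrow(iv))) {
        len <- iv$end[i] - iv$start[i] + 1
        if (off <= len) return(iv$end[i] - off + 1)
        off <- off - len
      }
    }
    abort("unreachable")
  }, numeric(1))
}

#' Extract the coding sequence of a gene from a reference
#'
#' @param gene a [gene_model()].
#' @param ref named character vector of chromosome sequences.
#' @return character scalar, the 5'->3' coding sequence.
#' @export
cds_sequence <- function(gene, ref) {
  if (!gene$chrom %in% names(ref)) {
    abort(sprintf("no reference sequence for chromosome %s (gene %s)",
                  gene$chrom, gene$gene_id))
  }
  chrom_seq <- ref[[gene$chrom]]
  parts <- vapply(seq_len(nrow(gene$cds)), function(i) {
    substr(chrom_seq, gene$cds$start[i], gene$cds$end[i])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

.aa3 <- function(aa1) {
  ifelse(aa1 == "*", "stop",
         unname(Biostrings::AMINO_ACID_CODE[aa1]))
}

#' Annotate a coding SNP as an amino-acid variant
#'
#' Translates both alleles' codons with the standard genetic code and
#' classifies the consequence. Positions use the "+1 = first coding
#' base" convention, so a change at coding position 511 falls in codon
#' `ceiling(511 / 3) = 171`.
#'
#' @param cds_seq coding sequence (5'->3', length divisible by 3).
#' @param coding_pos 1-based coding position of the SNP.
#' @param ref_base,alt_base coding-strand alleles.
#' @param gene_id optional identifier carried through to the output.
#' @return one-row tibble: `gene`, `coding_pos`, `codon_index`,
#'   `ref_aa`, `alt_aa` (three-letter), `consequence` (`synonymous`,
#'   `nonsynonymous` or `nonsense`), and a human-readable `label` such
#'   as `"+511 G>A; +171 Glu>Lys"`.
#' @export
annotate_snp <- function(cds_seq, coding_pos, ref_base, alt_base,
                         gene_id = NA_character_) {
  n <- nchar(cds_seq)
  if (n %% 3 != 0) abort("CDS length not divisible by 3")
  if (coding_pos < 1 || coding_pos > n) {
    abort(sprintf("coding position %d beyond CDS of length %d", coding_pos, n))
  }
  have <- substr(cds_seq, coding_pos, coding_pos)
  if (have != ref_base) {
    abort(sprintf(
      "reference mismatch at coding position %d: CDS has %s, variant claims %s",
      coding_pos, have, ref_base))
  }
  codon_index <- ceiling(coding_pos / 3)
  cstart <- (codon_index - 1) * 3 + 1
  ref_codon <- substr(cds_seq, cstart, cstart + 2)
  within <- coding_pos - cstart + 1
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_base
  ref_aa1 <- unname(Biostrings::GENETIC_CODE[ref_codon])
  alt_aa1 <- unname(Biostrings::GENETIC_CODE[alt_codon])
  consequence <- if (ref_aa1 == alt_aa1) {
    "synonymous"
  } else if (alt_aa1 == "*") {
    "nonsense"
  } else {
    "nonsynonymous"
  }
  tibble(
    gene = gene_id,
    coding_pos = as.integer(coding_pos),
    codon_index = as.integer(codon_index),
    ref_aa = .aa3(ref_aa1),
    alt_aa = .aa3(alt_aa1),
    consequence = consequence,
    label = sprintf("+%d %s>%s; +%d %s>%s", coding_pos, ref_base, alt_base,
                    codon_index, .aa3(ref_aa1), .aa3(alt_aa1))
  )
}

#' Build the amino-acid association-marker matrix
#'
#' Maps every genotyped SNP falling in a CDS to its coding position,
#' annotates it, and emits one binary marker per nonsynonymous (or
#' nonsense) SNP: 0 = reference amino acid, 1 = alternate, `NA` =
#' missing or heterozygous call (the panels targeted here are
#' effectively homozygous, so heterozygotes carry no usable amino-acid
#' state). Synonymous SNPs are excluded, as are sites whose missing-call
#' rate reaches `missing_max`.
#'
#' @param gt a [geno_matrix()].
#' @param genes named list of [gene_model()].
#' @param ref named character vector of chromosome sequences.
#' @param missing_max sites with missing rate >= this ceiling are
#'   dropped (default 0.8: sites with less than 80 percent missing data
#'   are retained).
#' @return list with `markers` (samples x markers numeric matrix, column
#'   names `gene:+pos`), and `variants` (tibble of per-marker
#'   annotations with genomic coordinates).
#' @export
build_aa_matrix <- function(gt, genes, ref, missing_max = 0.8) {
  miss_rate <- site_missing_rate(gt)
  variants <- list()
  cols <- list()
  for (g in genes) {
    cds_seq <- cds_sequence(g, ref)  # errors if reference absent
    cidx <- which(gt$sites$chrom == g$chrom)
    if (length(cidx) == 0) next
    cpos <- map_to_cds(g, gt$sites$pos[cidx])
    cidx <- cidx[!is.na(cpos)]
    cpos <- cpos[!is.na(cpos)]
    for (k in seq_along(cidx)) {
      j <- cidx[k]
      if (miss_rate[j] >= missing_max) next
      ref_b <- gt$sites$ref[j]
      alt_b <- gt$sites$alt[j]
      if (g$strand == "-") {
        ref_b <- chartr("ACGT", "TGCA", ref_b)
        alt_b <- chartr("ACGT", "TGCA", alt_b)
      }
      ann <- annotate_snp(cds_seq, cpos[k], ref_b, alt_b, gene_id = g$gene_id)
      if (ann$consequence == "synonymous") next
      ann$chrom <- gt$sites$chrom[j]
      ann$pos <- gt$sites$pos[j]
      ann$site_index <- j
      variants[[length(variants) + 1]] <- ann
      col <- gt$geno[, j]
      cols[[length(cols) + 1]] <-
        ifelse(col == 0L, 0, ifelse(col == 1L, 1, NA_real_))
    }
  }
  if (length(variants) == 0) {
    return(list(markers = matrix(numeric(), nrow(gt$geno), 0,
                                 dimnames = list(gt$samples$sample, NULL)),
                variants = tibble()))
  }
  variants <- bind_rows(variants)
  markers <- do.call(cbind, cols)
  # genomic order: the LD-pruning window contract assumes position-sorted markers
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  markers <- markers[, ord, drop = FALSE]
  colnames(markers) <- sprintf("%s:+%d", variants$gene, variants$coding_pos)
  rownames(markers) <- gt$samples$sample
  variants$marker <- colnames(markers)
  list(markers = markers, variants = variants)
}
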