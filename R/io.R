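#' Gene model
#'
#' A strand-aware set of CDS intervals for one gene. All coordinates are
#' 1-based and inclusive at both ends; intervals are stored sorted in
#' genomic order and must not overlap.
#'
#' @param gene_id character scalar.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds tibble/data frame with columns `start`, `end`. Frame
#'   integrity (total length divisible by 3) is checked where it
#'   matters -- on GFF3 read and at translation -- not here, so purely
#'   positional work (coordinate mapping, overlap tests) accepts any
#'   interval set.
#' @param span optional length-2 vector, the gene span (defaults to the
#'   CDS extent).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds, span = NULL) {
  stopifnot(strand %in% c("+", "-"))
  cds <- as_tibble(cds)[, c("start", "end")] |> arrange(.data$start)
  if (any(cds$end < cds$start)) abort("CDS interval with end < start")
  if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)])) {
    abort(sprintf("gene %s: overlapping CDS intervals", gene_id))
  }
  if (is.null(span)) span <- c(min(cds$start), max(cds$end))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds = cds, span = as.numeric(span)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d CDS segment(s), %d coding bp\n",
              x$gene_id, x$chrom, x$span[1], x$span[2], x$strand,
              nrow(x$cds), cds_length(x)))
  invisible(x)
}

#' @rdname gene_model
#' @param gene a `gene_model`.
#' @export
cds_length <- function(gene) sum(gene$cds$end - gene$cds$start + 1)

# genotype code -> VCF GT string and back
.gt_to_vcf <- c(`0` = "0/0", `1` = "1/1", `2` = "0/1", `-1` = "./.")

#' Write genotypes as VCF v4.2
#'
#' Plain-text writer with 1-based positions and unphased diploid GT
#' calls. Output is byte-deterministic for a given matrix, which the
#' simulator relies on for reproducibility checks.
#'
#' @param gt a [geno_matrix()].
#' @param path output file.
#' @param source_tag value of the `##source=` header line.
#' @param extra_header character vector of extra `##` header lines
#'   (e.g. the simulation seed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path, source_tag = "hapsweep",
                      extra_header = character()) {
  g <- gt$geno
  body <- matrix(.gt_to_vcf[as.character(g)], nrow(g), ncol(g))
  recs <- vapply(seq_len(ncol(g)), function(j) {
    paste(c(gt$sites$chrom[j], gt$sites$pos[j], ".",
            gt$sites$ref[j], gt$sites$alt[j], ".", "PASS", ".", "GT",
            body[, j]), collapse = "\t")
  }, character(1))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", source_tag),
           extra_header,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gt$samples$sample), collapse = "\t"))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read genotypes from VCF plus a subpopulation-label table
#'
#' Biallelic SNP records are kept; multi-allelic and non-SNP records are
#' skipped with a logged count. Positions must be strictly increasing
#' within each chromosome, and every VCF sample must appear in the label
#' table.
#'
#' @param vcf_path VCF v4.x file (plain or bgzipped).
#' @param labels_path two-column TSV with header `sample`, `subpop`.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(vcf_path, labels_path) {
  if (!file.exists(vcf_path)) abort(paste("VCF not found:", vcf_path))
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT, fixed = TRUE)
  n_skip <- sum(!snp)
  if (n_skip > 0) {
    inform(sprintf("read_genotypes: skipped %d non-biallelic-SNP record(s)", n_skip))
  }
  gt_str <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  code <- matrix(-1L, nrow = ncol(gt_str), ncol = nrow(gt_str),
                 dimnames = list(colnames(gt_str), NULL))
  norm <- gsub("|", "/", gt_str, fixed = TRUE)
  code[t(norm == "0/0")] <- 0L
  code[t(norm == "1/1")] <- 1L
  code[t(norm == "0/1" | norm == "1/0")] <- 2L
  labels <- readr::read_tsv(labels_path, show_col_types = FALSE)
  miss <- setdiff(rownames(code), labels$sample)
  if (length(miss) > 0) {
    abort(paste("sample(s) in VCF absent from label table:",
                paste(miss, collapse = ", ")))
  }
  samples <- tibble(sample = rownames(code)) |>
    left_join(labels, by = "sample")
  sites <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT)
  out <- geno_matrix(code, samples, sites)
  attr(out, "n_skipped") <- n_skip
  out
}

#' Write and read subpopulation labels
#' @param samples tibble with `sample`, `subpop`.
#' @param path TSV path.
#' @return `path` / a tibble.
#' @export
write_labels <- function(samples, path) {
  readr::write_tsv(samples[, c("sample", "subpop")], path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects `gene` and `CDS` features; CDS features are attached to genes
#' by their `Parent` (or `ID` prefix) attribute falling inside the gene
#' span on the same chromosome.
#'
#' A gene whose total CDS length is not divisible by 3 is rejected by
#' name.
#'
#' @param gff_path GFF3 file.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  cds <- gr[gr$type == "CDS"]
  cds_parent <- as.character(unlist(cds$Parent %||% cds$ID))
  out <- lapply(seq_along(genes), function(i) {
    gid <- as.character(genes$ID[i])
    mine <- cds[cds_parent == gid]
    if (length(mine) == 0) abort(sprintf("gene %s has no CDS features", gid))
    len <- sum(GenomicRanges::width(mine))
    if (len %% 3 != 0) {
      abort(sprintf("gene %s: CDS length %d not divisible by 3", gid, len))
    }
    gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(genes)[i]),
      strand = as.character(GenomicRanges::strand(genes)[i]),
      cds = tibble(start = GenomicRanges::start(mine),
                   end = GenomicRanges::end(mine)),
      span = c(GenomicRanges::start(genes)[i], GenomicRanges::end(genes)[i])
    )
  })
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  out
}

#' Write gene models as GFF3
#' @param genes list of [gene_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    lines <- c(lines,
      paste(g$chrom, "hapsweep", "gene", g$span[1], g$span[2], ".",
            g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"),
      vapply(seq_len(nrow(g$cds)), function(i) {
        paste(g$chrom, "hapsweep", "CDS", g$cds$start[i], g$cds$end[i], ".",
              g$strand, "0",
              paste0("ID=", g$gene_id, ".cds", i, ";Parent=", g$gene_id),
              sep = "\t")
      }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column TSV with header: sample id and low-temperature seedling
#' survivability (LTSS) in percent. Values must be in \[0, 100\] or `NA`;
#' duplicated samples are an error.
#'
#' @param tsv_path input TSV.
#' @return tibble with columns `sample`, `ltss`.
#' @export
read_phenotypes <- function(tsv_path) {
  ph <- readr::read_tsv(tsv_path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  names(ph)[1:2] <- c("sample", "ltss")
  ph$ltss <- suppressWarnings(as.numeric(ifelse(ph$ltss %in% c("NA", ""),
                                                NA, ph$ltss)))
  if (anyDuplicated(ph$sample)) {
    abort(paste("duplicate sample in phenotype table:",
                ph$sample[duplicated(ph$sample)][1]))
  }
  bad <- which(!is.na(ph$ltss) & (ph$ltss < 0 | ph$ltss > 100))
  if (length(bad) > 0) {
    abort(sprintf("phenotype value %g outside [0, 100] at line %d",
                  ph$ltss[bad[1]], bad[1] + 1L))
  }
  as_tibble(ph[, c("sample", "ltss")])
}

#' @rdname read_phenotypes
#' @param pheno tibble with `sample`, `ltss`.
#' @param path output TSV.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno[, c("sample", "ltss")], path)
  invisible(path)
}

#' Read a BED interval mask
#'
#' BED is 0-based half-open on disk; intervals are converted on read to
#' the package's internal 1-based inclusive convention.
#'
#' @param bed_path BED file (e.g. a centromere mask).
#' @return tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed_mask <- function(bed_path) {
  gr <- rtracklayer::import(bed_path, format = "bed")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr))
}

#' @rdname read_bed_mask
#' @param intervals tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param path output BED.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start, intervals$end)
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write / read reference sequences as FASTA
#' @param seqs named character vector of sequences.
#' @param path FASTA path.
#' @return `path` / named character vector.
#' @export
write_ref_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_ref_fasta
#' @export
read_ref_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub(" .*", "", names(x)))
}
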