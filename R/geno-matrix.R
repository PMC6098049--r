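#' Genotype matrix container
#'
#' The substrate of every statistic in the package: a samples-by-sites
#' integer matrix of biallelic SNP genotype codes plus sample and site
#' metadata. Codes are `0` = ref/ref, `1` = alt/alt, `2` = heterozygous,
#' `-1` = missing. The panels this package targets are highly inbred, so
#' most statistics treat the data as effectively haploid and drop
#' heterozygous calls site-wise (see [geno01()]).
#'
#' @param geno integer matrix, samples in rows (rownames = sample ids),
#'   sites in columns.
#' @param samples tibble with columns `sample`, `subpop` (one row per
#'   matrix row, same order).
#' @param sites tibble with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (single upper-case nucleotides), one row per matrix column.
#'
#' @return An object of class `geno_matrix`: a list with elements
#'   `geno`, `samples`, `sites`.
#' @export
geno_matrix <- function(geno, samples, sites) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  samples <- as_tibble(samples)
  sites <- as_tibble(sites)
  if (nrow(samples) != nrow(geno)) {
    abort("`samples` must have one row per matrix row")
  }
  if (nrow(sites) != ncol(geno)) {
    abort("`sites` must have one row per matrix column")
  }
  if (!all(c("sample", "subpop") %in% names(samples))) {
    abort("`samples` needs columns `sample` and `subpop`")
  }
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites))) {
    abort("`sites` needs columns `chrom`, `pos`, `ref`, `alt`")
  }
  if (anyNA(samples$subpop)) abort("every sample needs a subpopulation label")
  if (!all(geno %in% c(-1L, 0L, 1L, 2L))) {
    abort("genotype codes must be in {-1, 0, 1, 2}")
  }
  bases <- c("A", "C", "G", "T")
  if (!all(sites$ref %in% bases) || !all(sites$alt %in% bases)) {
    abort("ref/alt alleles must be single nucleotides in {A,C,G,T}")
  }
  ord_ok <- sites |>
    group_by(.data$chrom) |>
    summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(ord_ok$ok)) {
    abort("unsorted: site positions must be strictly increasing within a chromosome")
  }
  rownames(geno) <- samples$sample
  structure(list(geno = geno, samples = samples, sites = sites),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d sites on %s\n",
    nrow(x$geno), ncol(x$geno),
    paste(unique(x$sites$chrom), collapse = ", ")
  ))
  cat("subpopulations:",
      paste(sprintf("%s (%d)", names(table(x$samples$subpop)),
                    table(x$samples$subpop)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Effectively-haploid 0/1 allele codes
#'
#' Recode genotypes for statistics that assume effective haploidy:
#' ref homozygote -> 0, alt homozygote -> 1, heterozygous and missing -> NA.
#'
#' @param gt a [geno_matrix()].
#' @return numeric matrix, same shape as `gt$geno`.
#' @export
geno01 <- function(gt) {
  g <- gt$geno
  out <- matrix(NA_real_, nrow(g), ncol(g), dimnames = dimnames(g))
  out[g == 0L] <- 0
  out[g == 1L] <- 1
  out
}

#' Subset a genotype matrix
#'
#' @param gt a [geno_matrix()].
#' @param samples character sample ids or logical/integer row index.
#' @param sites logical/integer column index into the site table.
#' @return a [geno_matrix()].
#' @export
gt_subset <- function(gt, samples = NULL, sites = NULL) {
  ri <- seq_len(nrow(gt$geno))
  ci <- seq_len(ncol(gt$geno))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, gt$samples$sample) else ri[samples]
    if (anyNA(ri)) abort("unknown sample id in `samples`")
  }
  if (!is.null(sites)) ci <- ci[sites]
  geno_matrix(gt$geno[ri, ci, drop = FALSE],
              gt$samples[ri, ], gt$sites[ci, ])
}

#' Per-site and per-sample missing-call rates
#'
#' The single shared definition every filter in the pipeline cites:
#' the fraction of genotype codes equal to -1.
#'
#' @param gt a [geno_matrix()].
#' @return numeric vector of rates in \[0, 1\].
#' @export
site_missing_rate <- function(gt) colMeans(gt$geno == -1L)

#' @rdname site_missing_rate
#' @export
sample_missing_rate <- function(gt) rowMeans(gt$geno == -1L)

#' Alternate-allele frequency and minor-allele frequency
#'
#' Frequencies over non-missing calls; heterozygotes contribute half to
#' each allele. `site_maf()` folds to the minor allele. Monomorphic-after-
#' filtering sites return 0; sites with no usable call return NA.
#'
#' @param gt a [geno_matrix()].
#' @param samples optional sample subset (ids or index) to pool over.
#' @return numeric vector, one value per site.
#' @export
site_alt_freq <- function(gt, samples = NULL) {
  g <- gt$geno
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, gt$samples$sample) else samples
    g <- g[idx, , drop = FALSE]
  }
  alt <- colSums(g == 1L) + 0.5 * colSums(g == 2L)
  n <- colSums(g != -1L)
  ifelse(n > 0, alt / n, NA_real_)
}

#' @rdname site_alt_freq
#' @export
site_maf <- function(gt, samples = NULL) {
  p <- site_alt_freq(gt, samples)
  pmin(p, 1 - p)
}

#' @export
as_tibble.geno_matrix <- function(x, ...) {
  g <- x$geno
  tibble(
    sample = rep(x$samples$sample, times = ncol(g)),
    subpop = rep(x$samples$subpop, times = ncol(g)),
    chrom = rep(x$sites$chrom, each = nrow(g)),
    pos = rep(x$sites$pos, each = nrow(g)),
    code = as.integer(g)
  )
}
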