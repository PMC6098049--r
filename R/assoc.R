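#' Classical MDS stratification coordinates
#'
#' Population-structure covariates from classical (Torgerson)
#' multidimensional scaling of the pairwise allele-sharing distance
#' 1 - IBS, where IBS is the proportion of identical alleles over
#' complete, homozygous calls shared by a sample pair. Axes carry a
#' deterministic sign convention: the first nonzero loading of each axis
#' is positive.
#'
#' @param gt a [geno_matrix()].
#' @param dims number of leading coordinates to return.
#' @return tibble with `sample`, `subpop`, `MDS1..MDSk`.
#' @export
mds_coords <- function(gt, dims = 3) {
  n <- nrow(gt$geno)
  if (n < dims + 1) abort("need at least dims + 1 samples")
  g <- geno01(gt)
  x1 <- (g == 1)
  x0 <- (g == 0)
  x1[is.na(x1)] <- FALSE
  x0[is.na(x0)] <- FALSE
  matches <- tcrossprod(x1) + tcrossprod(x0)
  totals <- tcrossprod(!is.na(g))
  d <- 1 - matches / totals
  d[totals == 0] <- 0
  diag(d) <- 0
  if (all(d == 0)) {
    warn("mds_coords: degenerate (all-zero) distance matrix")
    coords <- matrix(0, n, dims)
  } else {
    coords <- suppressWarnings(cmdscale(as.dist(d), k = dims))
    if (ncol(coords) < dims) {
      coords <- cbind(coords, matrix(0, n, dims - ncol(coords)))
    }
    for (j in seq_len(ncol(coords))) {
      nz <- which(abs(coords[, j]) > 1e-12)
      if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
    }
  }
  colnames(coords) <- paste0("MDS", seq_len(dims))
  dplyr::bind_cols(gt$samples, as_tibble(coords))
}

#' Candidate-gene association scan on amino-acid markers
#'
#' Per-marker ordinary-least-squares fit of the phenotype on the 0/1
#' marker code plus the first two MDS stratification coordinates
#' (complete cases only, no imputation), a two-sided t-test on the
#' marker slope, Benjamini-Hochberg adjustment across all tested markers
#' jointly, and a gene-level call: a gene is significant when the
#' minimum adjusted p over its markers is below `alpha`.
#'
#' @param markers samples x markers matrix (0/1/NA), e.g. the pruned
#'   [build_aa_matrix()] output.
#' @param variants per-marker annotation tibble carrying at least
#'   `marker` and `gene` (from [build_aa_matrix()]).
#' @param pheno tibble `sample`, `ltss`.
#' @param covariates tibble with `sample` plus covariate columns
#'   (typically `MDS1`, `MDS2` from [mds_coords()]); `NULL` for an
#'   unadjusted fit.
#' @param alpha gene-level significance threshold on BH-adjusted p.
#' @param min_coverage warn when phenotype coverage of the marker rows
#'   falls below this fraction.
#' @return object of class `assoc_result`: list with tibbles `markers`
#'   (`marker`, `gene`, `n`, `estimate`, `se`, `p`, `p_adj`) and `genes`
#'   (`gene`, `n_markers`, `min_p_adj`, `significant`), plus `alpha` and
#'   the skipped-marker log.
#' @export
associate_genes <- function(markers, variants, pheno, covariates = NULL,
                            alpha = 0.05, min_coverage = 0.8) {
  stopifnot(is.matrix(markers))
  pheno_v <- pheno$ltss[match(rownames(markers), pheno$sample)]
  cov_m <- NULL
  if (!is.null(covariates)) {
    cc <- covariates[match(rownames(markers), covariates$sample), ]
    cov_m <- as.matrix(cc[, grep("^MDS", names(cc)), drop = FALSE])
    if (ncol(cov_m) > 2) cov_m <- cov_m[, 1:2, drop = FALSE]
  }
  coverage <- mean(!is.na(pheno_v))
  if (coverage < min_coverage) {
    warn(sprintf("phenotype coverage %.0f%% below %.0f%%",
                 100 * coverage, 100 * min_coverage))
  }
  skipped <- character()
  rows <- vector("list", ncol(markers))
  for (j in seq_len(ncol(markers))) {
    x <- markers[, j]
    df <- data.frame(y = pheno_v, x = x)
    if (!is.null(cov_m)) df <- cbind(df, cov_m)
    df <- df[complete.cases(df), , drop = FALSE]
    if (nrow(df) < 3 || length(unique(df$x)) < 2) {
      skipped <- c(skipped, colnames(markers)[j])
      next
    }
    fit <- lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    if (!"x" %in% rownames(sm)) {
      skipped <- c(skipped, colnames(markers)[j])
      next
    }
    rows[[j]] <- tibble(
      marker = colnames(markers)[j],
      n = nrow(df),
      estimate = sm["x", "Estimate"],
      se = sm["x", "Std. Error"],
      p = sm["x", "Pr(>|t|)"]
    )
  }
  if (length(skipped) > 0) {
    inform(sprintf("associate_genes: skipped %d monomorphic/degenerate marker(s)",
                   length(skipped)))
  }
  mk <- bind_rows(rows)
  if (nrow(mk) == 0) abort("no testable markers")
  mk$p_adj <- p.adjust(mk$p, method = "BH")
  mk <- left_join(mk, variants[, c("marker", "gene")], by = "marker") |>
    select("marker", "gene", dplyr::everything())
  genes <- mk |>
    group_by(.data$gene) |>
    summarise(n_markers = n(), min_p_adj = min(.data$p_adj),
              .groups = "drop") |>
    mutate(significant = .data$min_p_adj < alpha)
  structure(list(markers = mk, genes = genes, alpha = alpha,
                 skipped = skipped, coverage = coverage),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %d markers in %d genes; %d gene(s) significant at BH-adjusted p < %g\n",
              nrow(x$markers), nrow(x$genes), sum(x$genes$significant), x$alpha))
  invisible(x)
}

#' @export
tidy.assoc_result <- function(x, ...) x$markers

#' @export
glance.assoc_result <- function(x, ...) {
  tibble(n_markers = nrow(x$markers), n_genes = nrow(x$genes),
         n_significant = sum(x$genes$significant),
         n_skipped = length(x$skipped),
         coverage = x$coverage, alpha = x$alpha)
}

#' @export
autoplot.assoc_result <- function(object, ...) {
  df <- object$markers |> mutate(neglog = -log10(.data$p_adj))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker, y = .data$neglog,
                                   colour = .data$gene)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::labs(y = expression(-log[10] ~ "BH-adjusted p"), x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}
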