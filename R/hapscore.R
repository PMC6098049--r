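#' Per-sample haplotype scores
#'
#' Region SNPs with pooled minor allele frequency at or above `maf_min`
#' (computed over non-missing homozygous calls, all samples pooled)
#' serve as markers. Each base is scored A = 1, T = 2, C = 3, G = 4 and
#' a sample's haplotype score is the mean base score over its usable
#' markers; markers where the sample is missing or heterozygous are
#' excluded from that sample's mean. Scores therefore live in \[1, 4\];
#' bimodality of their distribution across a population signals two
#' co-maintained haplotype groups.
#'
#' @param gt a [geno_matrix()].
#' @param region half-open interval `c(start, end)` in bp.
#' @param maf_min pooled MAF threshold for markers.
#' @return tibble of class `score_table`: `sample`, `subpop`, `score`
#'   (`NA` if no usable marker), `n_markers_used`; the marker site
#'   indices are carried in attribute `"markers"`.
#' @export
haplotype_scores <- function(gt, region, maf_min = 0.2) {
  sel <- which(gt$sites$pos >= region[1] & gt$sites$pos < region[2])
  if (length(sel) == 0) abort("no SNP sites in region")
  # MAF over homozygous calls only (pipeline-wide haploid convention)
  g01 <- geno01(gt)[, sel, drop = FALSE]
  p <- colMeans(g01, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  markers <- sel[maf >= maf_min]
  if (length(markers) == 0) {
    abort(sprintf("no region marker reaches MAF >= %g", maf_min))
  }
  base_score <- c(A = 1, T = 2, C = 3, G = 4)
  g <- gt$geno[, markers, drop = FALSE]
  refs <- matrix(rep(base_score[gt$sites$ref[markers]], each = nrow(g)),
                 nrow(g))
  alts <- matrix(rep(base_score[gt$sites$alt[markers]], each = nrow(g)),
                 nrow(g))
  sc <- matrix(NA_real_, nrow(g), ncol(g))
  sc[g == 0L] <- refs[g == 0L]
  sc[g == 1L] <- alts[g == 1L]
  used <- rowSums(!is.na(sc))
  if (any(used == 0)) {
    inform(sprintf("haplotype_scores: %d sample(s) with no usable marker",
                   sum(used == 0)))
  }
  out <- tibble(
    sample = gt$samples$sample,
    subpop = gt$samples$subpop,
    score = ifelse(used > 0, rowMeans(sc, na.rm = TRUE), NA_real_),
    n_markers_used = as.integer(used)
  )
  class(out) <- c("score_table", class(out))
  attr(out, "markers") <- markers
  out
}

#' Sarle's bimodality coefficient and modality verdicts
#'
#' For each group, b = (g1^2 + 1) / (g2 + 3 (n-1)^2 / ((n-2)(n-3)))
#' with g1 the sample skewness and g2 the sample excess kurtosis
#' (moment estimators). Values above 5/9 -- the coefficient of the
#' uniform distribution -- are called bimodal; the raw coefficient is
#' always reported alongside the verdict since the 5/9 rule is a
#' heuristic boundary.
#'
#' @param scores a [haplotype_scores()] table (grouped by `subpop`), a
#'   named list of numeric vectors, or a single numeric vector.
#' @return tibble: `group`, `n`, `skewness`, `kurtosis`, `bimodality`,
#'   `verdict` (`"bimodal"` / `"unimodal"`).
#' @export
assess_modality <- function(scores) {
  groups <- if (is.data.frame(scores)) {
    split(scores$score[!is.na(scores$score)],
          scores$subpop[!is.na(scores$score)])
  } else if (is.list(scores)) {
    scores
  } else {
    list(all = scores)
  }
  out <- imap(groups, function(v, nm) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 5) abort(sprintf("group %s has n = %d < 5 scores", nm, n))
    m <- mean(v)
    s2 <- mean((v - m)^2)
    if (s2 == 0) {
      # a point mass: no spread, call unimodal with b = 0
      return(tibble(group = nm, n = n, skewness = 0, kurtosis = 0,
                    bimodality = 0, verdict = "unimodal"))
    }
    g1 <- mean((v - m)^3) / s2^1.5
    g2 <- mean((v - m)^4) / s2^2 - 3
    b <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
    tibble(group = nm, n = n, skewness = g1, kurtosis = g2,
           bimodality = b,
           verdict = if (b > 5 / 9) "bimodal" else "unimodal")
  })
  list_rbind(out)
}

#' Functional-site allele summary
#'
#' Per-subpopulation allele frequency (heterozygotes contribute half to
#' each allele), observed heterozygosity (het fraction among non-missing
#' calls), and the ancestral-state call: the allele carried by the
#' majority of genotyped outgroup samples, with its supporting count.
#' Derived-allele frequencies are reported relative to that call.
#'
#' @param gt a [geno_matrix()].
#' @param pos genomic position of the site.
#' @param outgroup subpopulation label(s) treated as outgroup.
#' @return object of class `fnp_site`: list with `site` (chrom, pos,
#'   ref, alt), `ancestral` (allele or `"undetermined"`), `support`
#'   (outgroup samples carrying it), and `by_subpop` (tibble `subpop`,
#'   `n`, `alt_freq`, `derived_freq`, `heterozygosity`).
#' @export
fnp_summary <- function(gt, pos, outgroup = "outgroup") {
  j <- match(pos, gt$sites$pos)
  if (is.na(j)) abort("site not present in the matrix")
  g <- gt$geno[, j]
  sp <- gt$samples$subpop
  by_subpop <- tibble(subpop = unique(sp)) |>
    mutate(
      n = map_int(.data$subpop, ~ sum(sp == .x & g != -1L)),
      alt_freq = map_dbl(.data$subpop, function(p) {
        gg <- g[sp == p & g != -1L]
        if (length(gg) == 0) return(NA_real_)
        (sum(gg == 1L) + 0.5 * sum(gg == 2L)) / length(gg)
      }),
      heterozygosity = map_dbl(.data$subpop, function(p) {
        gg <- g[sp == p & g != -1L]
        if (length(gg) == 0) return(NA_real_)
        mean(gg == 2L)
      })
    )
  og <- g[sp %in% outgroup & g != -1L]
  if (length(og) == 0) {
    ancestral <- "undetermined"
    support <- 0L
  } else {
    n_ref <- sum(og == 0L) + 0.5 * sum(og == 2L)
    n_alt <- sum(og == 1L) + 0.5 * sum(og == 2L)
    ancestral <- if (n_alt > n_ref) gt$sites$alt[j] else gt$sites$ref[j]
    support <- as.integer(if (n_alt > n_ref) {
      sum(og %in% c(1L, 2L))
    } else {
      sum(og %in% c(0L, 2L))
    })
  }
  derived_is_alt <- !identical(ancestral, gt$sites$alt[j])
  by_subpop$derived_freq <- if (identical(ancestral, "undetermined")) {
    NA_real_
  } else if (derived_is_alt) {
    by_subpop$alt_freq
  } else {
    1 - by_subpop$alt_freq
  }
  structure(list(
    site = tibble(chrom = gt$sites$chrom[j], pos = gt$sites$pos[j],
                  ref = gt$sites$ref[j], alt = gt$sites$alt[j]),
    ancestral = ancestral, support = support, by_subpop = by_subpop
  ), class = "fnp_site")
}

#' @export
print.fnp_site <- function(x, ...) {
  cat(sprintf("<fnp_site> %s:%d %s>%s; ancestral %s (support %d)\n",
              x$site$chrom, x$site$pos, x$site$ref, x$site$alt,
              x$ancestral, x$support))
  print(x$by_subpop)
  invisible(x)
}

#' @export
tidy.fnp_site <- function(x, ...) {
  mutate(x$by_subpop, ancestral = x$ancestral, support = x$support)
}

#' @export
autoplot.score_table <- function(object, binwidth = 0.1, ...) {
  df <- dplyr::filter(object, !is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 1,
                            fill = "grey30") +
    ggplot2::facet_wrap(~subpop, scales = "free_y") +
    ggplot2::labs(x = "haplotype score", y = "samples") +
    ggplot2::coord_cartesian(xlim = c(1, 4)) +
    ggplot2::theme_minimal()
}
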