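#' Pairwise linkage disequilibrium (r-squared)
#'
#' r-squared is the squared Pearson correlation of 0/1 allele codes over
#' samples with non-missing, homozygous calls at both sites (the
#' effective-haploid convention used pipeline-wide). It is undefined
#' (`NA`) when fewer than two complete samples remain or either site is
#' monomorphic among them.
#'
#' @param gt a [geno_matrix()].
#' @param site_i,site_j site (column) indices.
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
compute_r2 <- function(gt, site_i, site_j) {
  S <- ncol(gt$geno)
  if (any(c(site_i, site_j) < 1) || any(c(site_i, site_j) > S)) {
    abort("site index out of range")
  }
  g <- geno01(gt)
  x <- g[, site_i]
  y <- g[, site_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok])^2
}

#' Full pairwise r-squared matrix
#'
#' Vectorized pairwise-complete computation of [compute_r2()] over a set
#' of sites; entries with fewer than two complete samples or a
#' monomorphic member are `NA`.
#'
#' @param gt a [geno_matrix()].
#' @param sites optional site index subset.
#' @return symmetric numeric matrix of r-squared values.
#' @export
r2_matrix <- function(gt, sites = NULL) {
  g <- geno01(gt)
  if (!is.null(sites)) g <- g[, sites, drop = FALSE]
  if (ncol(g) == 0) return(matrix(numeric(), 0, 0))
  r <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))
  n_complete <- crossprod(!is.na(g))
  r2 <- r^2
  r2[!is.finite(r2)] <- NA_real_
  r2[n_complete < 2] <- NA_real_
  r2
}

#' Greedy LD pruning of association markers
#'
#' PLINK-style `--indep-pairwise`-like pruning on an arbitrary marker
#' matrix: markers with minor allele frequency at or below `maf_min` are
#' removed first; then a sliding window of `window` markers advancing by
#' `step` repeatedly removes, from the first offending pair (scanned in
#' order) whose r-squared exceeds `r2_max`, the member with the smaller
#' MAF (ties remove the later marker), until no retained within-window
#' pair offends. The final set is re-checked post hoc.
#'
#' @param markers numeric samples x markers matrix of 0/1 codes with
#'   `NA` for missing (e.g. [build_aa_matrix()] output or [geno01()]).
#' @param window,step window size and advance, in markers.
#' @param r2_max maximum tolerated pairwise r-squared.
#' @param maf_min markers with MAF <= this are dropped up front
#'   (frequency must exceed it, i.e. MAF > 1 percent by default).
#' @return integer vector of retained column indices (sorted).
#' @export
ld_prune <- function(markers, window = 5, step = 2, r2_max = 0.2,
                     maf_min = 0.01) {
  m <- ncol(markers)
  if (m == 0) return(integer())
  p <- colMeans(markers, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep_idx <- which(maf > maf_min)
  if (length(keep_idx) == 0) return(integer())
  removed <- rep(FALSE, length(keep_idx))
  r2_pair <- function(a, b) {
    x <- markers[, keep_idx[a]]
    y <- markers[, keep_idx[b]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])^2
  }
  starts <- seq(1, length(keep_idx), by = step)
  for (ws in starts) {
    win <- ws:min(ws + window - 1, length(keep_idx))
    repeat {
      live <- win[!removed[win]]
      if (length(live) < 2) break
      offended <- FALSE
      for (a in seq_len(length(live) - 1)) {
        for (b in (a + 1):length(live)) {
          r2 <- r2_pair(live[a], live[b])
          if (!is.na(r2) && r2 > r2_max) {
            ma <- maf[keep_idx[live[a]]]
            mb <- maf[keep_idx[live[b]]]
            drop <- if (ma < mb) live[a] else if (mb < ma) live[b] else live[b]
            removed[drop] <- TRUE
            offended <- TRUE
            break
          }
        }
        if (offended) break
      }
      if (!offended) break
    }
  }
  retained <- keep_idx[!removed]
  # post-hoc contract check: no retained within-window pair above r2_max
  ret_slot <- which(!removed)
  for (ws in starts) {
    win <- ws:min(ws + window - 1, length(keep_idx))
    live <- intersect(win, ret_slot)
    if (length(live) < 2) next
    for (a in seq_len(length(live) - 1)) {
      for (b in (a + 1):length(live)) {
        r2 <- r2_pair(live[a], live[b])
        if (!is.na(r2) && r2 > r2_max) {
          abort("ld_prune internal error: retained pair violates r2_max")
        }
      }
    }
  }
  retained
}
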