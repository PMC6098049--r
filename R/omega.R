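#' Configuration of the omega sweep scan
#'
#' @param grid_spacing grid spacing in bp (one evaluation point per
#'   5 kb by default; the grid is anchored at position = spacing).
#' @param minwin,maxwin minimum and maximum flank-window extent in bp.
#' @param mask optional tibble `chrom`, `start`, `end` (1-based
#'   inclusive) of regions to mask (e.g. centromeres).
#' @param mask_flank extension added to each side of every mask
#'   interval, bp.
#' @param top_fraction fraction of defined grid points flagged as
#'   sweeps per chromosome.
#' @return list of class `omega_config`.
#' @export
omega_config <- function(grid_spacing = 5000, minwin = 500, maxwin = 25000,
                         mask = NULL, mask_flank = 500000,
                         top_fraction = 0.05) {
  if (!(minwin > 0 && minwin < maxwin)) abort("need 0 < minwin < maxwin")
  if (!(top_fraction > 0 && top_fraction < 1)) {
    abort("top_fraction must be in (0, 1)")
  }
  structure(list(grid_spacing = grid_spacing, minwin = minwin,
                 maxwin = maxwin, mask = mask, mask_flank = mask_flank,
                 top_fraction = top_fraction),
            class = "omega_config")
}

#' The omega linkage-disequilibrium sweep statistic
#'
#' For a split of SNPs into a left and right flank around a putative
#' sweep centre,
#' omega = mean within-flank r-squared / mean between-flank r-squared,
#' where the within mean pools both flanks' pairs. High omega marks the
#' LD signature a completed sweep leaves: strong LD within each flank,
#' broken across the swept site. Sums use only pairs with defined
#' r-squared and the denominators count those pairs. Undefined (`NA`)
#' when either flank has fewer than two SNPs, no within or between pair
#' is defined, or the between-flank mean is zero.
#'
#' @param r2 symmetric r-squared matrix ([r2_matrix()]).
#' @param left_set,right_set disjoint index sets into `r2`.
#' @return omega value (>= 0) or `NA`.
#' @export
omega_statistic <- function(r2, left_set, right_set) {
  if (length(intersect(left_set, right_set)) > 0) {
    abort("left and right sets overlap")
  }
  if (length(left_set) < 2 || length(right_set) < 2) return(NA_real_)
  wl <- r2[left_set, left_set][upper.tri(diag(length(left_set)))]
  wr <- r2[right_set, right_set][upper.tri(diag(length(right_set)))]
  bt <- as.vector(r2[left_set, right_set, drop = FALSE])
  w <- c(wl, wr)
  if (all(is.na(w)) || all(is.na(bt))) return(NA_real_)
  num <- mean(w, na.rm = TRUE)
  den <- mean(bt, na.rm = TRUE)
  if (den == 0) return(NA_real_)
  num / den
}

# prefix machinery for one grid point: sites ordered nearest-first.
# SW[k]/CW[k]: sum/count of defined r2 among the first k sites.
.within_prefix <- function(r2m) {
  k <- nrow(r2m)
  SW <- CW <- numeric(k)
  if (k >= 2) {
    for (i in 2:k) {
      vals <- r2m[i, 1:(i - 1)]
      SW[i] <- SW[i - 1] + sum(vals, na.rm = TRUE)
      CW[i] <- CW[i - 1] + sum(!is.na(vals))
    }
  }
  list(S = SW, C = CW)
}

.omega_at_point <- function(r2, pos, point, minwin, maxwin) {
  li <- which(pos >= point - maxwin & pos < point)
  ri <- which(pos >= point & pos < point + maxwin)
  if (length(li) < 2 || length(ri) < 2) return(NA_real_)
  li <- li[order(point - pos[li])]          # nearest first
  ri <- ri[order(pos[ri] - point)]
  l0 <- max(2, sum(point - pos[li] <= minwin))
  r0 <- max(2, sum(pos[ri] - point < minwin))
  if (l0 > length(li) || r0 > length(ri)) return(NA_real_)
  WL <- .within_prefix(r2[li, li, drop = FALSE])
  WR <- .within_prefix(r2[ri, ri, drop = FALSE])
  B <- r2[li, ri, drop = FALSE]
  Bdef <- !is.na(B)
  B[!Bdef] <- 0
  # 2-D prefix sums over (left size, right size)
  BS <- apply(apply(B, 2, cumsum), 1, cumsum)      # BS[r, l]
  BC <- apply(apply(Bdef, 2, cumsum), 1, cumsum)
  ls <- l0:length(li)
  rs <- r0:length(ri)
  num <- outer(WL$S[ls], WR$S[rs], "+") / outer(WL$C[ls], WR$C[rs], "+")
  den <- t(BS[rs, ls, drop = FALSE]) / t(BC[rs, ls, drop = FALSE])
  om <- num / den
  om[!is.finite(om) | den == 0] <- NA_real_
  if (all(is.na(om))) return(NA_real_)
  max(om, na.rm = TRUE)
}

#' Grid-based omega sweep scan
#'
#' Evaluates the omega statistic on an arithmetic grid along each
#' chromosome, maximizing over all admissible flank extents between
#' `minwin` and `maxwin` realized by SNP positions (left flank =
#' SNPs in `[point - wL, point)`, right flank = SNPs in
#' `[point, point + wR)`). SNPs are encoded 0/1 with heterozygous and
#' missing calls excluded pairwise; no imputation. Grid points inside a
#' mask interval extended by `mask_flank` carry no omega.
#'
#' @param gt a [geno_matrix()].
#' @param config an [omega_config()].
#' @param chrom_length named vector of chromosome lengths; defaults to
#'   the last SNP position per chromosome.
#' @return tibble of class `omega_track`: `chrom`, `pos`, `omega`,
#'   `masked`.
#' @export
omega_scan <- function(gt, config = omega_config(), chrom_length = NULL) {
  chroms <- unique(gt$sites$chrom)
  out <- list()
  for (ch in chroms) {
    sites <- which(gt$sites$chrom == ch)
    pos <- gt$sites$pos[sites]
    len <- if (!is.null(chrom_length) && ch %in% names(chrom_length)) {
      chrom_length[[ch]]
    } else {
      max(pos)
    }
    grid <- seq(config$grid_spacing, len, by = config$grid_spacing)
    masked <- rep(FALSE, length(grid))
    if (!is.null(config$mask) && nrow(config$mask) > 0) {
      mk <- config$mask[config$mask$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(mk))) {
        masked <- masked |
          (grid >= mk$start[i] - config$mask_flank &
             grid <= mk$end[i] + config$mask_flank)
      }
    }
    maf <- site_maf(gt)[sites]
    poly <- which(!is.na(maf) & maf > 0)
    omega <- rep(NA_real_, length(grid))
    if (length(poly) >= 4) {
      r2 <- r2_matrix(gt, sites[poly])
      ppos <- pos[poly]
      for (gi in which(!masked)) {
        omega[gi] <- .omega_at_point(r2, ppos, grid[gi],
                                     config$minwin, config$maxwin)
      }
    }
    out[[ch]] <- tibble(chrom = ch, pos = grid, omega = omega,
                        masked = masked)
  }
  track <- bind_rows(out)
  class(track) <- c("omega_track", class(track))
  attr(track, "config") <- config
  track
}

#' Call sweep regions and flag overlapping genes
#'
#' Per chromosome, the defined grid points whose omega reaches the
#' empirical top `top_fraction` (k-th largest value with
#' k = max(1, floor(top_fraction x n)); ties are all flagged, so ties at
#' the threshold may exceed the nominal fraction) are marked, runs of
#' consecutive flagged points are merged into regions spanning
#' `[point - spacing/2, point + spacing/2)`, and a gene is flagged when
#' its span intersects any region (half-open interval intersection).
#'
#' @param track an [omega_scan()] result.
#' @param genes named list of [gene_model()] (may be empty).
#' @param top_fraction fraction flagged; defaults to the scan config.
#' @return object of class `sweep_calls`: list with `regions`
#'   (`chrom`, `start`, `end`, `n_points`, `max_omega`), `genes`
#'   (`gene`, `sweep_overlap`), `threshold` per chromosome, and the
#'   flagged track.
#' @export
call_sweep_regions <- function(track, genes = list(), top_fraction = NULL) {
  config <- attr(track, "config")
  spacing <- if (!is.null(config)) config$grid_spacing else {
    min(diff(sort(unique(track$pos))))
  }
  if (is.null(top_fraction)) {
    top_fraction <- if (!is.null(config)) config$top_fraction else 0.05
  }
  track$flagged <- FALSE
  thresholds <- list()
  regions <- list()
  for (ch in unique(track$chrom)) {
    ti <- which(track$chrom == ch)
    def <- ti[!track$masked[ti] & !is.na(track$omega[ti])]
    if (length(def) == 0) next
    k <- max(1, floor(top_fraction * length(def)))
    thr <- sort(track$omega[def], decreasing = TRUE)[k]
    flag <- def[track$omega[def] >= thr]
    track$flagged[flag] <- TRUE
    thresholds[[ch]] <- tibble(chrom = ch, threshold = thr,
                               n_defined = length(def), n_flagged = length(flag))
    fpos <- sort(track$pos[flag])
    run_id <- cumsum(c(1, diff(fpos) > spacing))
    for (r in unique(run_id)) {
      rp <- fpos[run_id == r]
      ri <- flag[match(rp, track$pos[flag])]
      regions[[length(regions) + 1]] <- tibble(
        chrom = ch,
        start = min(rp) - spacing / 2,
        end = max(rp) + spacing / 2,
        n_points = length(rp),
        max_omega = max(track$omega[ri])
      )
    }
  }
  if (length(regions) == 0) {
    warn("call_sweep_regions: no defined omega values; empty result")
  }
  regions <- bind_rows(regions)
  gene_flags <- tibble(
    gene = vapply(genes, `[[`, character(1), "gene_id"),
    sweep_overlap = vapply(genes, function(g) {
      if (nrow(regions) == 0) return(FALSE)
      any(regions$chrom == g$chrom &
            regions$start < g$span[2] + 1 &   # half-open vs inclusive span
            g$span[1] < regions$end)
    }, logical(1))
  )
  structure(list(regions = regions, genes = gene_flags,
                 thresholds = bind_rows(thresholds), track = track),
            class = "sweep_calls")
}

#' @export
print.sweep_calls <- function(x, ...) {
  cat(sprintf("<sweep_calls> %d region(s); %d/%d gene(s) overlap a sweep\n",
              nrow(x$regions), sum(x$genes$sweep_overlap), nrow(x$genes)))
  invisible(x)
}

#' @export
tidy.sweep_calls <- function(x, ...) x$regions

#' @export
glance.sweep_calls <- function(x, ...) {
  tibble(n_regions = nrow(x$regions),
         n_genes_flagged = sum(x$genes$sweep_overlap),
         n_genes = nrow(x$genes))
}

#' @export
autoplot.omega_track <- function(object, ...) {
  df <- dplyr::filter(object, !.data$masked)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1000, y = .data$omega)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (kb)", y = expression(omega)) +
    ggplot2::theme_minimal()
}
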