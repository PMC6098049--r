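#' Windowed nucleotide diversity (Tajima's pi)
#'
#' Per non-overlapping window, pi is the average pairwise nucleotide
#' difference per callable base: at each variant site with at least two
#' usable (non-missing, homozygous) calls the per-site mean pairwise
#' difference is `k(n - k) / choose(n, 2)` (k alt calls among n usable),
#' summed over sites and divided by the window's callable length in bp
#' (positions whose variant site has fewer than two usable calls are
#' subtracted; non-variant positions count as invariant). Samples whose
#' missing rate over the region's sites exceeds `sample_missing_max` are
#' excluded first.
#'
#' @param gt a [geno_matrix()].
#' @param samples optional sample-id / index subset (e.g. one
#'   subpopulation).
#' @param region half-open interval `c(start, end)` in bp; default spans
#'   the matrix.
#' @param window window size in bp (windows are non-overlapping; a
#'   region shorter than one window yields a single truncated window
#'   with a warning).
#' @param sample_missing_max per-sample missing-rate ceiling over the
#'   region.
#' @param estimator `"pairwise"` (default): mean pairwise difference,
#'   `k(n-k)/C(n,2) = 2pq n/(n-1)`; `"2pq"`: the plain heterozygosity
#'   estimate without the finite-sample factor.
#' @param chrom chromosome to use when the matrix has several.
#' @return tibble of class `pi_windows`: `chrom`, `start`, `end`, `pi`,
#'   `n_sites` (usable variant sites), `n_samples`. `pi` is `NA` when
#'   fewer than two usable sequences remain.
#' @export
window_pi <- function(gt, samples = NULL, region = NULL, window = 100,
                      sample_missing_max = 0.8,
                      estimator = c("pairwise", "2pq"), chrom = NULL) {
  estimator <- match.arg(estimator)
  if (is.null(chrom)) chrom <- gt$sites$chrom[1]
  keep_sites <- which(gt$sites$chrom == chrom)
  if (is.null(region)) {
    region <- c(min(gt$sites$pos[keep_sites]),
                max(gt$sites$pos[keep_sites]) + 1)
  }
  ri <- seq_len(nrow(gt$geno))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, gt$samples$sample) else ri[samples]
  }
  in_region <- keep_sites[gt$sites$pos[keep_sites] >= region[1] &
                            gt$sites$pos[keep_sites] < region[2]]
  g <- gt$geno[ri, in_region, drop = FALSE]
  if (ncol(g) > 0) {
    smiss <- rowMeans(g == -1L)
    ok <- smiss <= sample_missing_max
  } else {
    ok <- rep(TRUE, length(ri))
  }
  if (sum(ok) < 2) abort("fewer than 2 samples pass the missing-rate filter")
  g <- g[ok, , drop = FALSE]
  pos <- gt$sites$pos[in_region]

  if (region[2] - region[1] < window) {
    warn("region shorter than one window: single truncated window")
  }
  starts <- seq(region[1], region[2] - 1, by = window)
  ends <- pmin(starts + window, region[2])
  res <- map(seq_along(starts), function(w) {
    sel <- which(pos >= starts[w] & pos < ends[w])
    callable <- ends[w] - starts[w]
    tot <- 0
    usable <- 0L
    for (j in sel) {
      col <- g[, j]
      hom <- col[col %in% c(0L, 1L)]
      n <- length(hom)
      if (n < 2) {
        callable <- callable - 1
        next
      }
      k <- sum(hom == 1L)
      d <- if (estimator == "pairwise") {
        k * (n - k) / choose(n, 2)
      } else {
        p <- k / n
        2 * p * (1 - p)
      }
      tot <- tot + d
      usable <- usable + 1L
    }
    tibble(chrom = chrom, start = starts[w], end = ends[w],
           pi = if (callable > 0) tot / callable else NA_real_,
           n_sites = usable, n_samples = nrow(g))
  })
  out <- list_rbind(res)
  class(out) <- c("pi_windows", class(out))
  out
}

#' Focal-versus-flank diversity contrast
#'
#' One-way ANOVA over window-pi values of the focal, upstream and
#' downstream regions, followed by all three pairwise comparisons:
#' Fisher's LSD t-tests on the pooled ANOVA mean square error, or
#' pairwise Welch t-tests when Bartlett's variance-homogeneity test
#' rejects at 0.05. The verdict is `"focal_reduced"` when the focal mean
#' is below both flanks and both focal-flank comparisons are significant
#' at `alpha`.
#'
#' @param pi_focal,pi_up,pi_down numeric vectors of window pi, or
#'   [window_pi()] tibbles (their `pi` column is used; `NA` dropped).
#' @param alpha significance level.
#' @param log_transform apply `log(x + eps)` before testing (useful when
#'   variances scale with the mean).
#' @param eps offset for the log transform; default half the smallest
#'   positive value.
#' @return object of class `region_contrast`: list with `summary` (per
#'   region n/mean/sd), `anova` (F, df, p), `pairwise` (pair, estimate,
#'   p, method), `verdict` (`"focal_reduced"` or `"not_reduced"`),
#'   `alpha`.
#' @export
region_contrast <- function(pi_focal, pi_up, pi_down, alpha = 0.05,
                            log_transform = FALSE, eps = NULL) {
  getv <- function(x) {
    v <- if (is.data.frame(x)) x$pi else x
    v[!is.na(v)]
  }
  vals <- list(focal = getv(pi_focal), upstream = getv(pi_up),
               downstream = getv(pi_down))
  if (any(lengths(vals) < 2)) abort("need >= 2 windows per region")
  if (log_transform) {
    allv <- unlist(vals)
    if (is.null(eps)) {
      posv <- allv[allv > 0]
      eps <- if (length(posv) > 0) min(posv) / 2 else 1e-6
    }
    vals <- lapply(vals, function(v) log(v + eps))
  }
  df <- tibble(
    region = factor(rep(names(vals), lengths(vals)),
                    levels = c("focal", "upstream", "downstream")),
    pi = unlist(vals, use.names = FALSE)
  )
  summ <- df |>
    group_by(.data$region) |>
    summarise(n = n(), mean = mean(.data$pi), sd = sd(.data$pi),
              .groups = "drop")
  pairs <- list(c("focal", "upstream"), c("focal", "downstream"),
                c("upstream", "downstream"))
  if (all(summ$sd == 0)) {
    warn("zero within-group variance everywhere: comparing means directly")
    pw <- map(pairs, function(pr) {
      m <- summ$mean[match(pr, summ$region)]
      tibble(pair = paste(pr, collapse = " vs "),
             estimate = m[1] - m[2],
             p = if (m[1] == m[2]) 1 else 0,
             method = "exact")
    }) |> list_rbind()
    an <- tibble(F = NA_real_, df1 = 2L, df2 = nrow(df) - 3L, p = NA_real_)
  } else {
    fit <- aov(pi ~ region, data = df)
    antab <- summary(fit)[[1]]
    an <- tibble(F = antab$`F value`[1], df1 = antab$Df[1],
                 df2 = antab$Df[2], p = antab$`Pr(>F)`[1])
    mse <- antab$`Mean Sq`[2]
    bart_p <- tryCatch(bartlett.test(pi ~ region, data = df)$p.value,
                       error = function(e) 1)
    welch <- !is.na(bart_p) && bart_p < 0.05
    pw <- map(pairs, function(pr) {
      a <- df$pi[df$region == pr[1]]
      b <- df$pi[df$region == pr[2]]
      if (welch) {
        tt <- tryCatch(t.test(a, b), error = function(e) NULL)
        tibble(pair = paste(pr, collapse = " vs "),
               estimate = mean(a) - mean(b),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               method = "welch")
      } else {
        est <- mean(a) - mean(b)
        se <- sqrt(mse * (1 / length(a) + 1 / length(b)))
        p <- if (se == 0) {
          if (est == 0) 1 else 0
        } else {
          2 * pt(-abs(est / se), df = an$df2)
        }
        tibble(pair = paste(pr, collapse = " vs "),
               estimate = est, p = p, method = "lsd")
      }
    }) |> list_rbind()
  }
  mfoc <- summ$mean[summ$region == "focal"]
  mup <- summ$mean[summ$region == "upstream"]
  mdn <- summ$mean[summ$region == "downstream"]
  p_fu <- pw$p[pw$pair == "focal vs upstream"]
  p_fd <- pw$p[pw$pair == "focal vs downstream"]
  verdict <- if (!is.na(p_fu) && !is.na(p_fd) &&
                 mfoc < mup && mfoc < mdn && p_fu < alpha && p_fd < alpha) {
    "focal_reduced"
  } else {
    "not_reduced"
  }
  structure(list(summary = summ, anova = an, pairwise = pw,
                 verdict = verdict, alpha = alpha,
                 log_transform = log_transform),
            class = "region_contrast")
}

#' @export
print.region_contrast <- function(x, ...) {
  cat(sprintf("<region_contrast> verdict: %s (ANOVA p = %s)\n", x$verdict,
              format(x$anova$p, digits = 3)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.region_contrast <- function(x, ...) x$pairwise

#' @export
glance.region_contrast <- function(x, ...) {
  tibble(F = x$anova$F, p_anova = x$anova$p, verdict = x$verdict,
         alpha = x$alpha,
         focal_mean = x$summary$mean[x$summary$region == "focal"])
}

#' @export
autoplot.pi_windows <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2000,
                               y = .data$pi)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (kb)", y = expression(pi)) +
    ggplot2::theme_minimal()
}
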