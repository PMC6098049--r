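#' Region alignment from genotypes
#'
#' Expands a genomic region of the genotype matrix into a character
#' alignment (rows = samples, columns = region SNP sites): ref/alt
#' homozygotes give their base, heterozygous and missing calls give
#' `"N"` (the effective-haploid convention).
#'
#' @param gt a [geno_matrix()].
#' @param region half-open interval `c(start, end)` in bp.
#' @param samples optional sample-id / index subset.
#' @return character matrix with sample rownames and position colnames.
#' @export
genotypes_to_alignment <- function(gt, region, samples = NULL) {
  sel <- which(gt$sites$pos >= region[1] & gt$sites$pos < region[2])
  if (length(sel) == 0) abort("no SNP sites in region")
  ri <- seq_len(nrow(gt$geno))
  if (!is.null(samples)) {
    ri <- if (is.character(samples)) match(samples, gt$samples$sample) else ri[samples]
  }
  g <- gt$geno[ri, sel, drop = FALSE]
  aln <- matrix("N", nrow(g), ncol(g),
                dimnames = list(gt$samples$sample[ri], gt$sites$pos[sel]))
  refm <- matrix(rep(gt$sites$ref[sel], each = nrow(g)), nrow(g))
  altm <- matrix(rep(gt$sites$alt[sel], each = nrow(g)), nrow(g))
  aln[g == 0L] <- refm[g == 0L]
  aln[g == 1L] <- altm[g == 1L]
  aln
}

# Hamming distance over shared non-missing sites ("N" = missing)
.shared_hamming <- function(a, b) {
  ok <- a != "N" & b != "N"
  sum(a[ok] != b[ok])
}

#' Filter, impute and collapse sequences into haplotypes
#'
#' Sites whose missing rate exceeds `site_missing_max` are dropped, then
#' sequences whose missing rate over the retained sites exceeds
#' `seq_missing_max` are dropped. Each remaining missing call is imputed
#' by the majority allele among the `impute_k` nearest sequences
#' (Hamming distance over shared non-missing sites, computed on the
#' pre-imputation data; neighbours must carry a call at the site;
#' distance ties broken by row order, vote ties by the global major
#' allele). Identical imputed sequences are collapsed with counts and
#' subpopulation composition.
#'
#' @param aln character matrix alignment (rows = sequences), `"N"` for
#'   missing; e.g. from [genotypes_to_alignment()].
#' @param labels optional tibble `sample`, `subpop` for composition.
#' @param site_missing_max,seq_missing_max missing-rate ceilings.
#' @param impute_k neighbourhood size for imputation.
#' @return object of class `hap_set`: list with `haps` (tibble `hap`,
#'   `seq`, `count`, `members` list-column), `composition` (tibble
#'   `hap`, `subpop`, `n`), `n_sites`, `n_dropped_sites`,
#'   `n_dropped_seqs`.
#' @export
prepare_haplotypes <- function(aln, labels = NULL, site_missing_max = 0.2,
                               seq_missing_max = 0.3, impute_k = 3) {
  stopifnot(is.matrix(aln))
  site_keep <- colMeans(aln == "N") <= site_missing_max
  n_dropped_sites <- sum(!site_keep)
  aln2 <- aln[, site_keep, drop = FALSE]
  if (ncol(aln2) == 0) {
    abort(sprintf(
      "all sites dropped (site ceiling %.2f, sequence ceiling %.2f)",
      site_missing_max, seq_missing_max))
  }
  seq_keep <- rowMeans(aln2 == "N") <= seq_missing_max
  n_dropped_seqs <- sum(!seq_keep)
  if (n_dropped_seqs > 0) {
    inform(sprintf("prepare_haplotypes: dropped %d sequence(s) above %.0f%% missing",
                   n_dropped_seqs, 100 * seq_missing_max))
  }
  aln2 <- aln2[seq_keep, , drop = FALSE]
  if (nrow(aln2) == 0 || ncol(aln2) == 0) {
    abort(sprintf(
      "all sequences or sites dropped (site ceiling %.2f, sequence ceiling %.2f)",
      site_missing_max, seq_missing_max))
  }
  # impute from the pre-imputation matrix so order cannot matter
  orig <- aln2
  n <- nrow(orig)
  miss_idx <- which(orig == "N", arr.ind = TRUE)
  if (nrow(miss_idx) > 0) {
    D <- matrix(0L, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j > i) D[i, j] <- .shared_hamming(orig[i, ], orig[j, ])
      }
    }
    D <- D + t(D)
    for (r in seq_len(nrow(miss_idx))) {
      i <- miss_idx[r, 1]
      s <- miss_idx[r, 2]
      cand <- setdiff(which(orig[, s] != "N"), i)
      if (length(cand) == 0) {
        allele <- .major_allele(orig[, s])
      } else {
        nb <- cand[order(D[i, cand], cand)][seq_len(min(impute_k, length(cand)))]
        votes <- table(orig[nb, s])
        top <- names(votes)[votes == max(votes)]
        allele <- if (length(top) == 1) top else .major_allele(orig[, s])
      }
      aln2[i, s] <- allele
    }
  }
  seqs <- apply(aln2, 1, paste, collapse = "")
  uniq <- sort(unique(seqs))  # lexicographic node order, deterministic
  haps <- tibble(
    hap = sprintf("H%02d", seq_along(uniq)),
    seq = uniq,
    count = as.integer(table(factor(seqs, levels = uniq))),
    members = lapply(uniq, function(s) names(seqs)[seqs == s])
  )
  composition <- NULL
  if (!is.null(labels)) {
    composition <- haps |>
      select("hap", "members") |>
      tidyr::unnest_longer("members", values_to = "sample") |>
      left_join(labels[, c("sample", "subpop")], by = "sample") |>
      count(.data$hap, .data$subpop, name = "n")
  }
  structure(list(haps = haps, composition = composition,
                 n_sites = ncol(aln2),
                 n_dropped_sites = n_dropped_sites,
                 n_dropped_seqs = n_dropped_seqs),
            class = "hap_set")
}

.major_allele <- function(col) {
  tab <- table(col[col != "N"])
  if (length(tab) == 0) return("N")
  top <- names(tab)[tab == max(tab)]
  sort(top)[1]
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("<hap_set> %d haplotypes over %d sites (%d sequences)\n",
              nrow(x$haps), x$n_sites, sum(x$haps$count)))
  invisible(x)
}

#' Minimum spanning network of haplotypes
#'
#' The union of all minimum spanning trees of the complete
#' Hamming-distance graph on the haplotypes, built level by level:
#' edge weights are processed in increasing order, and at each weight
#' level every edge of that weight joining two components that were
#' distinct at the start of the level is added. With `epsilon > 0`,
#' edges within `epsilon` of a level's weight are admitted at that
#' level (a relaxation some network programs expose); the default 0
#' gives exactly the union of all MSTs. Distances are computed on
#' segregating sites only (invariant sites contribute nothing).
#'
#' @param hapset a [prepare_haplotypes()] result (needs >= 2
#'   haplotypes).
#' @param epsilon non-negative weight relaxation.
#' @return object of class `hap_network`: list with `nodes` (tibble
#'   `hap`, `count`), `edges` (tibble `from`, `to`, `weight`), and
#'   `graph` (igraph object with `count` vertex and `weight` edge
#'   attributes).
#' @export
build_msn <- function(hapset, epsilon = 0) {
  haps <- hapset$haps
  n <- nrow(haps)
  if (n < 2) abort("need at least 2 haplotypes")
  mats <- do.call(rbind, strsplit(haps$seq, ""))
  seg <- apply(mats, 2, function(col) length(unique(col)) > 1)
  mats <- mats[, seg, drop = FALSE]
  D <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- sum(mats[i, ] != mats[j, ])
    }
  }
  comp <- seq_len(n)
  edges <- list()
  levels <- sort(unique(D[upper.tri(D)]))
  for (w in levels) {
    if (length(unique(comp)) == 1) break
    start_comp <- comp
    idx <- which(D == w & upper.tri(D), arr.ind = TRUE)
    if (epsilon > 0) {
      idx <- which(D >= w & D <= w + epsilon & upper.tri(D), arr.ind = TRUE)
    }
    added <- idx[start_comp[idx[, 1]] != start_comp[idx[, 2]], , drop = FALSE]
    if (nrow(added) > 0) {
      edges[[length(edges) + 1]] <- tibble(
        from = haps$hap[added[, 1]], to = haps$hap[added[, 2]],
        weight = D[added]
      )
      for (r in seq_len(nrow(added))) {
        ci <- comp[added[r, 1]]
        cj <- comp[added[r, 2]]
        if (ci != cj) comp[comp == cj] <- ci
      }
    }
  }
  edges <- bind_rows(edges) |> arrange(.data$from, .data$to)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = haps$hap, count = haps$count)
  )
  if (igraph::components(g)$no != 1) {
    abort("build_msn internal error: network not connected")
  }
  structure(list(nodes = tibble(hap = haps$hap, count = haps$count),
                 edges = edges, graph = g, epsilon = epsilon),
            class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat(sprintf("<hap_network> %d nodes, %d edges (weights %s)\n",
              nrow(x$nodes), nrow(x$edges),
              paste(range(x$edges$weight), collapse = "-")))
  invisible(x)
}

#' @export
tidy.hap_network <- function(x, ...) x$edges

#' @export
glance.hap_network <- function(x, ...) {
  tibble(n_haplotypes = nrow(x$nodes), n_edges = nrow(x$edges),
         max_weight = max(x$edges$weight))
}

#' Write a haplotype network as GraphML
#'
#' Node attributes: `count` and, when a [prepare_haplotypes()]
#' composition is supplied, one fraction attribute per subpopulation.
#' Edge attribute: `weight` (Hamming distance).
#'
#' @param net a [build_msn()] result.
#' @param path output file.
#' @param hapset optional `hap_set` whose composition decorates nodes.
#' @return `path`, invisibly.
#' @export
write_hapnet_graphml <- function(net, path, hapset = NULL) {
  g <- net$graph
  if (!is.null(hapset) && !is.null(hapset$composition)) {
    comp <- hapset$composition |>
      group_by(.data$hap) |>
      mutate(frac = .data$n / sum(.data$n)) |>
      ungroup()
    for (sp in unique(comp$subpop)) {
      v <- setNames(rep(0, nrow(net$nodes)), net$nodes$hap)
      rows <- comp[comp$subpop == sp, ]
      v[rows$hap] <- rows$frac
      g <- igraph::set_vertex_attr(g, paste0("frac_", sp),
                                   value = unname(v[igraph::V(g)$name]))
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
autoplot.hap_network <- function(object, ...) {
  set.seed(1L)  # deterministic layout
  lay <- igraph::layout_with_fr(object$graph)
  nodes <- object$nodes |>
    mutate(x = lay[, 1], y = lay[, 2])
  edges <- object$edges |>
    left_join(nodes |> select(from = "hap", x1 = "x", y1 = "y"), by = "from") |>
    left_join(nodes |> select(to = "hap", x2 = "x", y2 = "y"), by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x1, y = .data$y1,
                                       xend = .data$x2, yend = .data$y2),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$count)) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::theme_void()
}
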