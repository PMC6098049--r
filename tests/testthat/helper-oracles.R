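# Independent oracles and tiny fixture builders shared across the suite.
# Each oracle is a deliberately naive re-derivation (brute force,
# enumeration, closed form) kept separate from the package code paths it
# checks.

# -- tiny genotype fixtures -------------------------------------------

make_gt <- function(codes, pos = NULL, chrom = "chr1",
                    ref = NULL, alt = NULL, subpop = NULL) {
  codes <- as.matrix(codes)
  n <- nrow(codes)
  s <- ncol(codes)
  if (is.null(pos)) pos <- seq_len(s) * 10L
  if (is.null(ref)) ref <- rep("A", s)
  if (is.null(alt)) alt <- rep("G", s)
  if (is.null(subpop)) subpop <- rep("pop1", n)
  geno_matrix(
    codes,
    tibble::tibble(sample = sprintf("s%02d", seq_len(n)), subpop = subpop),
    tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
  )
}

# random effectively-haploid genotype matrix
random_gt <- function(n, s, maf_range = c(0.1, 0.5), missing = 0,
                      pos = NULL) {
  p <- runif(s, maf_range[1], maf_range[2])
  codes <- matrix(rbinom(n * s, 1L, rep(p, each = n)), n, s)
  if (missing > 0) codes[runif(n * s) < missing] <- -1L
  make_gt(codes, pos = pos)
}

# -- pi: exhaustive mean pairwise Hamming ------------------------------

# average pairwise difference per bp over a window, haploid 0/1 rows
pi_pairwise_oracle <- function(codes, window_bp) {
  n <- nrow(codes)
  stopifnot(n >= 2)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(codes[i, ] != codes[j, ])
    }
  }
  tot / choose(n, 2) / window_bp
}

# -- BH: textbook step-up --------------------------------------------

bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, m * p[o[k]] / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# -- omega: brute-force split enumeration ------------------------------

omega_stat_oracle <- function(r2, left, right) {
  wl <- c()
  for (a in seq_along(left)) {
    for (b in seq_along(left)) {
      if (b > a) wl <- c(wl, r2[left[a], left[b]])
    }
  }
  wr <- c()
  for (a in seq_along(right)) {
    for (b in seq_along(right)) {
      if (b > a) wr <- c(wr, r2[right[a], right[b]])
    }
  }
  bt <- c()
  for (a in seq_along(left)) {
    for (b in seq_along(right)) bt <- c(bt, r2[left[a], right[b]])
  }
  w <- c(wl, wr)
  if (all(is.na(w)) || all(is.na(bt))) return(NA_real_)
  den <- mean(bt, na.rm = TRUE)
  if (is.na(den) || den == 0) return(NA_real_)
  mean(w, na.rm = TRUE) / den
}

# maximize over every admissible split at one grid point, by direct
# enumeration of all (left extent, right extent) pairs
omega_point_oracle <- function(r2, pos, point, minwin, maxwin) {
  best <- NA_real_
  lext <- sort(unique(c(minwin, (point - pos)[pos < point & point - pos <= maxwin])))
  rext <- sort(unique(c(minwin, (pos - point + 1)[pos >= point & pos - point < maxwin])))
  lext <- lext[lext >= minwin & lext <= maxwin]
  rext <- rext[rext >= minwin & rext <= maxwin]
  for (wl in lext) {
    for (wr in rext) {
      left <- which(pos >= point - wl & pos < point)
      right <- which(pos >= point & pos < point + wr)
      if (length(left) < 2 || length(right) < 2) next
      om <- omega_stat_oracle(r2, left, right)
      if (!is.na(om) && (is.na(best) || om > best)) best <- om
    }
  }
  best
}

# -- LD pruning: independent greedy implementation --------------------

prune_oracle <- function(markers, window = 5, step = 2, r2_max = 0.2,
                         maf_min = 0.01) {
  p <- colMeans(markers, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  idx <- which(maf > maf_min)
  if (length(idx) == 0) return(integer())
  alive <- rep(TRUE, length(idx))
  pair_r2 <- function(a, b) {
    x <- markers[, idx[a]]
    y <- markers[, idx[b]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 2) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  }
  for (ws in seq(1, length(idx), by = step)) {
    slots <- ws:min(ws + window - 1, length(idx))
    repeat {
      cur <- slots[alive[slots]]
      if (length(cur) < 2) break
      pairs <- t(utils::combn(cur, 2))
      hit <- NULL
      for (r in seq_len(nrow(pairs))) {
        v <- pair_r2(pairs[r, 1], pairs[r, 2])
        if (!is.na(v) && v > r2_max) {
          hit <- pairs[r, ]
          break
        }
      }
      if (is.null(hit)) break
      m1 <- maf[idx[hit[1]]]
      m2 <- maf[idx[hit[2]]]
      drop <- if (m1 < m2) hit[1] else hit[2]  # tie: the later site
      alive[drop] <- FALSE
    }
  }
  idx[alive]
}

# -- MSN: exhaustive MST enumeration via Pruefer sequences -------------

# all spanning trees of the complete graph on n labelled nodes
prufer_to_edges <- function(seq_, n) {
  degree <- rep(1L, n)
  for (x in seq_) degree[x] <- degree[x] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 1
  for (x in seq_) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, x)
    k <- k + 1
    degree[leaf] <- degree[leaf] - 1L
    degree[x] <- degree[x] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1, ] <- last
  edges
}

msn_union_oracle <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 3, n <= 8)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best_w <- Inf
  union_edges <- NULL
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_to_edges(seqs[r, ], n)
    w <- sum(D[ed])
    key <- apply(cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])),
                 1, paste, collapse = "-")
    if (w < best_w - 1e-9) {
      best_w <- w
      union_edges <- unique(key)
    } else if (abs(w - best_w) < 1e-9) {
      union_edges <- unique(c(union_edges, key))
    }
  }
  sort(union_edges)
}

# edge keys of a built network, in oracle format (indices into hap order)
net_edge_keys <- function(net) {
  id <- match(net$edges$from, net$nodes$hap)
  jd <- match(net$edges$to, net$nodes$hap)
  sort(apply(cbind(pmin(id, jd), pmax(id, jd)), 1, paste, collapse = "-"))
}

# -- k-NN imputation oracle -------------------------------------------

impute_oracle <- function(aln, i, s, k = 3) {
  cand <- setdiff(which(aln[, s] != "N"), i)
  if (length(cand) == 0) return(NA_character_)
  d <- vapply(cand, function(j) {
    ok <- aln[i, ] != "N" & aln[j, ] != "N"
    sum(aln[i, ok] != aln[j, ok])
  }, numeric(1))
  nb <- cand[order(d, cand)][seq_len(min(k, length(cand)))]
  votes <- table(aln[nb, s])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1) return(top)
  tab <- table(aln[aln[, s] != "N", s])
  mx <- names(tab)[tab == max(tab)]
  sort(mx)[1]
}

# -- shared replicate experiment for recovery tests --------------------

# one full signal-recovery replicate at the default study conditions;
# returns the per-criterion successes
recovery_replicate <- function(seed, sweep = TRUE) {
  cfg <- sim_config(seed = seed,
                    sweep_intensity = if (sweep) 0.1 else 1)
  sim <- simulate_dataset(cfg)
  gt <- sim$gt
  ids <- function(g) gt$samples$sample[gt$samples$subpop == g]
  flagged <- any(vapply(c("cultivar_A", "cultivar_B"), function(g) {
    tr <- omega_scan(gt_subset(gt, samples = ids(g)), omega_config(),
                     chrom_length = stats::setNames(cfg$chrom_length, cfg$chrom))
    calls <- call_sweep_regions(tr, sim$genes)
    calls$genes$sweep_overlap[calls$genes$gene == "gene_focal"]
  }, logical(1)))
  if (!sweep) return(list(sweep_flag = flagged))

  aa <- build_aa_matrix(gt, sim$genes, sim$ref)
  keep <- ld_prune(aa$markers)
  half <- 10000
  away <- gt$sites$pos < cfg$focal_mid - half |
    gt$sites$pos >= cfg$focal_mid + half
  mds <- mds_coords(gt_subset(gt, sites = away))
  ar <- suppressMessages(
    associate_genes(aa$markers[, keep, drop = FALSE], aa$variants,
                    sim$pheno, mds)
  )
  assoc_focal <- with(ar$genes, significant[gene == "gene_focal"])
  other_assoc <- with(ar$genes, gene[significant & gene != "gene_focal"])

  regs <- focal_regions(cfg)
  pw <- lapply(seq_len(3), function(i) {
    window_pi(gt, samples = ids("cultivar_A"),
              region = c(regs$start[i], regs$end[i]))
  })
  rc <- suppressWarnings(region_contrast(pw[[2]], pw[[1]], pw[[3]]))

  st <- suppressMessages(
    haplotype_scores(gt, c(cfg$focal_mid - 3000, cfg$focal_mid + 3000))
  )
  pooled <- st[st$subpop != "outgroup", ]
  pooled$subpop <- "pooled"
  mo <- assess_modality(rbind(st, pooled))

  # a second gene would have to be associated AND swept to break
  # uniqueness; sweep flags for other associated genes:
  unique_candidate <- assoc_focal && flagged && length(other_assoc) == 0
  if (assoc_focal && flagged && length(other_assoc) > 0) {
    others_swept <- vapply(c("cultivar_A", "cultivar_B"), function(g) {
      tr <- omega_scan(gt_subset(gt, samples = ids(g)), omega_config(),
                       chrom_length = stats::setNames(cfg$chrom_length, cfg$chrom))
      calls <- call_sweep_regions(tr, sim$genes)
      any(calls$genes$sweep_overlap[calls$genes$gene %in% other_assoc])
    }, logical(1))
    unique_candidate <- !any(others_swept)
  }
  list(
    sweep_flag = flagged,
    assoc_focal = isTRUE(assoc_focal),
    pi_reduced = rc$verdict == "focal_reduced",
    pooled_bimodal = mo$verdict[mo$group == "pooled"] == "bimodal",
    outgroup_unimodal = mo$verdict[mo$group == "outgroup"] == "unimodal",
    unique_candidate = unique_candidate
  )
}
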