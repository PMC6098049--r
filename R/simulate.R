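#' Simulation configuration
#'
#' Defines the synthetic study panel the generator emulates: a structured
#' rice-like population of five subpopulations (wild-relative outgroup,
#' two wild ecotypes, two cultivated subspecies), a chromosome carrying a
#' focal candidate gene with a single functional nucleotide polymorphism
#' (FNP) near-fixed for alternative alleles between the two lineages, a
#' diversity-reducing sweep of each lineage's allele around the gene, and
#' a cold-survival phenotype (LTSS, percent) driven by the FNP plus
#' subpopulation effects.
#'
#' Background variation is drawn site-wise from a hierarchical Beta
#' (F-model) allele-frequency tree (ancestral -> lineage -> subpopulation,
#' outgroup on its own branch), not a coalescent: sufficient to exercise
#' every downstream statistic at desk scale.
#'
#' @param n_samples named integer vector of sample counts for
#'   `outgroup`, `wild_A`, `wild_B`, `cultivar_A`, `cultivar_B`
#'   (each >= 2). Defaults total 200.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param snp_density expected background SNPs per kb (default 6,
#'   matching dense resequencing panels).
#' @param focal_cds_start,focal_cds_length,focal_strand focal gene CDS
#'   (single interval, length divisible by 3).
#' @param fnp_coding_pos 1-based coding position of the FNP (first coding
#'   base = +1). The reference codon there is forced to GAG (Glu) with a
#'   G>A alternate, the canonical Glu>Lys change.
#' @param fnp_freq named vector of target alt (derived, "indica-type")
#'   allele frequencies per subpopulation.
#' @param n_bg_genes,bg_cds_length background (non-causal) genes spread
#'   along the chromosome.
#' @param sweep_intensity diversity-reduction factor in (0, 1]; 1 = no
#'   sweep. Carriers receive the lineage donor haplotype around the
#'   selected site out to random per-side breakpoints; the mean escaped
#'   (original-haplotype) fraction over the region equals this value
#'   (see [inject_sweep()]).
#' @param sweep_span length-2 vector, half-open swept interval; default
#'   10 kb centred on the focal gene midpoint.
#' @param missing_rate,het_rate per-call missing and heterozygous
#'   injection rates (the panel is near-homozygous; the FNP itself is
#'   kept heterozygote-free, matching its observed zero heterozygosity).
#' @param baseline,effect,noise_sd phenotype model: LTSS = baseline +
#'   effect x alt-allele code + subpopulation offset + Gaussian noise,
#'   truncated to \[0, 100\]. Units are percent survival.
#' @param pheno_offsets named per-subpopulation phenotype offsets.
#' @param f_lineage,f_subpop,beta_shape drift parameters of the
#'   allele-frequency tree.
#' @param outgroup_div per-site private divergence of each outgroup
#'   sample from the ancestral haplotype: the outgroup emulates
#'   independently diverged wild-relative species (a star phylogeny),
#'   not a panmictic population, so its variation is private to each
#'   sample rather than shared polymorphism.
#' @param hap_div_frac,hap_div_freq,hap_noise,score_bias geometry of the balanced
#'   locus: a fraction `hap_div_frac` of sweep-region sites belong to
#'   the two anciently diverged FNP-linked haplotypes, where a sample
#'   carries the coherent regional haplotype matching its FNP allele
#'   with probability `hap_div_freq`, deviating per site with
#'   probability `hap_noise`; at such sites the derived-haplotype base is chosen
#'   to score higher than the ancestral one (A=1 < T=2 < C=3 < G=4)
#'   with probability `score_bias`, so the two haplotype groups separate
#'   on the haplotype-score scale as deeply diverged balanced alleles
#'   do.
#' @param centromere optional tibble `chrom`,`start`,`end` mask.
#' @param seed integer random seed; fixed seed gives byte-identical
#'   serialized output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = c(outgroup = 30, wild_A = 44, wild_B = 44,
                                     cultivar_A = 41, cultivar_B = 41),
                       chrom = "chr1",
                       chrom_length = 250000,
                       snp_density = 6,
                       focal_cds_start = 124251,
                       focal_cds_length = 1500,
                       focal_strand = "+",
                       fnp_coding_pos = 511,
                       fnp_freq = c(outgroup = 0, wild_A = 0.84,
                                    wild_B = 0.03, cultivar_A = 0.995,
                                    cultivar_B = 0.005),
                       n_bg_genes = 9,
                       bg_cds_length = 1500,
                       sweep_intensity = 0.1,
                       sweep_span = NULL,
                       missing_rate = 0.03,
                       het_rate = 0.005,
                       baseline = 55,
                       effect = -20,
                       noise_sd = 8,
                       pheno_offsets = c(outgroup = 0, wild_A = -5,
                                         wild_B = 5, cultivar_A = -5,
                                         cultivar_B = 5),
                       outgroup_div = 0.3,
                       f_lineage = 0.07,
                       f_subpop = 0.05,
                       beta_shape = 0.8,
                       hap_div_frac = 0.7,
                       hap_div_freq = 0.9,
                       hap_noise = 0.02,
                       score_bias = 0.9,
                       centromere = NULL,
                       seed = 1L) {
  pops <- c("outgroup", "wild_A", "wild_B", "cultivar_A", "cultivar_B")
  if (!all(pops %in% names(n_samples))) {
    abort("`n_samples` must name all five subpopulations")
  }
  n_samples <- n_samples[pops]
  if (any(n_samples < 2)) abort("each subpopulation needs n >= 2 samples")
  if (!all(pops %in% names(fnp_freq)) ||
      any(fnp_freq < 0 | fnp_freq > 1)) {
    abort("`fnp_freq` must give frequencies in [0, 1] for all subpopulations")
  }
  if (focal_cds_length %% 3 != 0) abort("focal CDS length must be divisible by 3")
  focal_end <- focal_cds_start + focal_cds_length - 1
  if (focal_cds_start < 1 || focal_end > chrom_length) {
    abort("focal gene span must lie inside the chromosome")
  }
  if (fnp_coding_pos < 1 || fnp_coding_pos > focal_cds_length) {
    abort("FNP coding position outside the focal CDS")
  }
  if (sweep_intensity <= 0 || sweep_intensity > 1) {
    abort("sweep intensity must be in (0, 1]")
  }
  if (missing_rate < 0 || missing_rate >= 1 || het_rate < 0 || het_rate >= 1) {
    abort("missing and heterozygosity rates must be in [0, 1)")
  }
  mid <- (focal_cds_start + focal_end) / 2
  if (is.null(sweep_span)) sweep_span <- c(mid - 5000, mid + 5000)
  structure(list(
    n_samples = n_samples, chrom = chrom, chrom_length = chrom_length,
    snp_density = snp_density, focal_cds_start = focal_cds_start,
    focal_cds_length = focal_cds_length, focal_strand = focal_strand,
    fnp_coding_pos = fnp_coding_pos, fnp_freq = fnp_freq[pops],
    n_bg_genes = n_bg_genes, bg_cds_length = bg_cds_length,
    sweep_intensity = sweep_intensity, sweep_span = as.numeric(sweep_span),
    missing_rate = missing_rate, het_rate = het_rate,
    baseline = baseline, effect = effect, noise_sd = noise_sd,
    pheno_offsets = pheno_offsets[pops],
    outgroup_div = outgroup_div, f_lineage = f_lineage, f_subpop = f_subpop,
    beta_shape = beta_shape, hap_div_frac = hap_div_frac,
    hap_div_freq = hap_div_freq, hap_noise = hap_noise,
    score_bias = score_bias,
    centromere = centromere,
    focal_mid = mid, seed = as.integer(seed)
  ), class = "sim_config")
}

# F-model: child frequency drawn around parent p with drift parameter f
.drift <- function(p, f) {
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  rbeta(length(p), pmax(a, 1e-8), pmax(b, 1e-8))
}

.sim_gene_set <- function(config) {
  L <- config$chrom_length
  focal <- gene_model(
    "gene_focal", config$chrom, config$focal_strand,
    tibble(start = config$focal_cds_start,
           end = config$focal_cds_start + config$focal_cds_length - 1),
    span = c(config$focal_cds_start - 250,
             config$focal_cds_start + config$focal_cds_length - 1 + 250)
  )
  genes <- list(gene_focal = focal)
  if (config$n_bg_genes > 0) {
    cand <- round(seq(0.08 * L, 0.92 * L, length.out = config$n_bg_genes + 2))
    cand <- cand[abs(cand - config$focal_mid) > 12000]
    cand <- head(cand, config$n_bg_genes)
    for (i in seq_along(cand)) {
      cs <- cand[i] - floor(config$bg_cds_length / 2)
      g <- gene_model(
        sprintf("gene_bg%02d", i), config$chrom,
        if (i %% 2 == 0) "-" else "+",
        tibble(start = cs, end = cs + config$bg_cds_length - 1),
        span = c(cs - 250, cs + config$bg_cds_length - 1 + 250)
      )
      genes[[g$gene_id]] <- g
    }
  }
  genes
}

#' Simulate a full synthetic dataset
#'
#' Draws the reference sequence, gene models, structured background
#' genotypes, the FNP at its per-subpopulation target frequencies, the
#' two lineage sweeps, the LTSS phenotype, and injects heterozygous and
#' missing calls. A truth record carries the generative parameters and
#' realized quantities for downstream power checks.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with elements `gt`
#'   ([geno_matrix()]), `genes` (named list of [gene_model()]; the causal
#'   gene is `gene_focal`), `pheno`, `ref` (named character, chromosome
#'   sequence), `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pops <- names(config$n_samples)
  L <- config$chrom_length

  # reference sequence; force the FNP codon to GAG (Glu) on the coding strand
  ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  genes <- .sim_gene_set(config)
  focal <- genes$gene_focal
  fnp_pos <- cds_to_genomic(focal, config$fnp_coding_pos)
  codon_start_coding <- config$fnp_coding_pos - (config$fnp_coding_pos - 1) %% 3
  codon_pos <- vapply(codon_start_coding + 0:2, function(cp) {
    cds_to_genomic(focal, cp)
  }, numeric(1))
  codon_bases <- c("G", "A", "G")
  if (focal$strand == "-") codon_bases <- rev(chartr("ACGT", "TGCA", codon_bases))
  ref[codon_pos] <- codon_bases

  # site positions: background density plus the forced FNP site. The
  # focal CDS carries no other variant: like the candidate gene it
  # emulates, its single coding SNP IS the functional polymorphism.
  n_bg <- round(config$snp_density * L / 1000)
  pos <- sample.int(L, n_bg)
  in_focal_cds <- pos >= focal$cds$start[1] & pos <= focal$cds$end[nrow(focal$cds)]
  pos <- sort(unique(c(pos[!in_focal_cds], fnp_pos)))
  S <- length(pos)
  fnp_idx <- match(fnp_pos, pos)
  ref_allele <- ref[pos]
  alt_allele <- vapply(ref_allele, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  fnp_alt <- if (focal$strand == "+") "A" else "T"  # G>A on the coding strand
  alt_allele[fnp_idx] <- fnp_alt

  # hierarchical allele-frequency tree
  p0 <- pmin(pmax(rbeta(S, config$beta_shape, config$beta_shape), 0.05), 0.95)
  anc <- rbinom(S, 1L, p0)                # ancestral haplotype
  p_linA <- .drift(p0, config$f_lineage)
  p_linB <- .drift(p0, config$f_lineage)
  freq <- rbind(
    wild_A = .drift(p_linA, config$f_subpop),
    wild_B = .drift(p_linB, config$f_subpop),
    cultivar_A = .drift(p_linA, config$f_subpop),
    cultivar_B = .drift(p_linB, config$f_subpop)
  )
  fnp_targets <- config$fnp_freq
  freq[, fnp_idx] <- fnp_targets[rownames(freq)]

  samples <- tibble(
    sample = sprintf("%s_%03d", rep(pops, config$n_samples),
                     unlist(lapply(config$n_samples, seq_len))),
    subpop = rep(pops, config$n_samples)
  )
  geno <- matrix(0L, nrow(samples), S)
  og <- which(samples$subpop == "outgroup")
  flips <- matrix(rbinom(length(og) * S, 1L, config$outgroup_div),
                  nrow = length(og))
  geno[og, ] <- abs(matrix(anc, length(og), S, byrow = TRUE) - flips)
  geno[og, fnp_idx] <- rbinom(length(og), 1L, fnp_targets[["outgroup"]])
  for (p in setdiff(pops, "outgroup")) {
    rows <- which(samples$subpop == p)
    geno[rows, ] <- matrix(
      rbinom(length(rows) * S, 1L, rep(freq[p, ], each = length(rows))),
      nrow = length(rows)
    )
  }
  gt <- geno_matrix(geno, samples,
                    tibble(chrom = config$chrom, pos = pos,
                           ref = ref_allele, alt = alt_allele))
  realized <- vapply(pops, function(p) {
    mean(gt$geno[samples$subpop == p, fnp_idx])
  }, numeric(1))

  # the balanced locus: two anciently diverged FNP-linked haplotypes
  # across the sweep region. The ancestral (reference-like) haplotype is
  # drawn from low-scoring bases and the derived one from high-scoring
  # bases with probability score_bias, so the two haplotype groups
  # separate on the 1-4 haplotype-score scale the way the deeply
  # diverged balanced alleles it emulates do.
  if (config$hap_div_frac > 0) {
    in_region <- which(pos >= config$sweep_span[1] &
                         pos < config$sweep_span[2] &
                         !pos %in% codon_pos & seq_along(pos) != fnp_idx)
    div <- in_region[runif(length(in_region)) < config$hap_div_frac]
    if (length(div) > 0) {
      for (j in div) {
        if (runif(1) < config$score_bias) {
          rb <- sample(c("A", "T"), 1)
          ab <- sample(c("C", "G"), 1)
        } else {
          rb <- sample(c("A", "C", "G", "T"), 1)
          ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
        }
        ref_allele[j] <- rb
        alt_allele[j] <- ab
        ref[pos[j]] <- rb
      }
      # each sample carries one coherent regional haplotype, linked to
      # its FNP allele, with small per-site noise
      nsmp <- nrow(gt$geno)
      p_der <- ifelse(gt$geno[, fnp_idx] == 1L,
                      config$hap_div_freq, 1 - config$hap_div_freq)
      # the outgroup lineage predates the derived haplotype: it can only
      # carry it through its (near-absent) derived FNP allele
      p_der[samples$subpop == "outgroup" & gt$geno[, fnp_idx] != 1L] <- 0
      H <- rbinom(nsmp, 1L, p_der)
      # in-species samples deviate from their haplotype at hap_noise;
      # outgroup species carry their own locus-wide divergence
      flip_p <- ifelse(samples$subpop == "outgroup",
                       config$outgroup_div, config$hap_noise)
      flips <- matrix(rbinom(nsmp * length(div), 1L, rep(flip_p, length(div))),
                      nrow = nsmp)
      gt$geno[, div] <- abs(matrix(H, nsmp, length(div)) - flips)
      gt$sites$ref <- ref_allele
      gt$sites$alt <- alt_allele
    }
  }

  # two successive lineage sweeps of the alternative FNP alleles;
  # the outgroup keeps its background diversity
  if (config$sweep_intensity < 1) {
    sel_A <- samples$sample[samples$subpop %in% c("wild_A", "cultivar_A")]
    sel_B <- samples$sample[samples$subpop %in% c("wild_B", "cultivar_B")]
    if (any(gt$geno[gt$samples$sample %in% sel_A, fnp_idx] == 1L)) {
      gt <- inject_sweep(gt, config$sweep_span, config$sweep_intensity,
                         fnp_pos, allele = "alt", samples = sel_A)
    }
    if (any(gt$geno[gt$samples$sample %in% sel_B, fnp_idx] == 0L)) {
      gt <- inject_sweep(gt, config$sweep_span, config$sweep_intensity,
                         fnp_pos, allele = "ref", samples = sel_B)
    }
  }

  pheno <- simulate_phenotype(gt, fnp_pos, config$effect, config$noise_sd,
                              baseline = config$baseline,
                              offsets = config$pheno_offsets)

  # near-zero heterozygosity and uniform missingness, FNP kept het-free
  ncell <- length(gt$geno)
  if (config$het_rate > 0) {
    het <- matrix(runif(ncell) < config$het_rate, nrow(gt$geno))
    het[, fnp_idx] <- FALSE
    gt$geno[het] <- 2L
  }
  if (config$missing_rate > 0) {
    mis <- matrix(runif(ncell) < config$missing_rate, nrow(gt$geno))
    gt$geno[mis] <- -1L
  }

  regions <- focal_regions(config)
  region_pi <- vapply(seq_len(nrow(regions)), function(i) {
    pw <- window_pi(gt, region = c(regions$start[i], regions$end[i]),
                    window = regions$end[i] - regions$start[i])
    pw$pi[1]
  }, numeric(1))

  truth <- list(
    causal_gene = "gene_focal",
    fnp = tibble(chrom = config$chrom, pos = fnp_pos,
                 coding_pos = config$fnp_coding_pos,
                 ref = ref_allele[fnp_idx], alt = fnp_alt),
    fnp_freq = tibble(subpop = pops, target = unname(config$fnp_freq),
                      realized = unname(realized),
                      n = unname(config$n_samples)),
    region_pi = mutate(regions, pi = region_pi),
    pheno_params = list(baseline = config$baseline, effect = config$effect,
                        noise_sd = config$noise_sd,
                        offsets = config$pheno_offsets),
    seed = config$seed
  )
  structure(list(gt = gt, genes = genes, pheno = pheno,
                 ref = setNames(list(paste(ref, collapse = "")),
                                config$chrom) |> unlist(),
                 truth = truth, config = config),
            class = "sim_dataset")
}

#' Focal/upstream/downstream region geometry
#'
#' The diversity contrast uses a 4-kb focal region centred on the focal
#' gene midpoint inside a 20-kb region set; the flanks are the remaining
#' 8 kb on each side. Intervals are half-open.
#'
#' @param config a [sim_config()].
#' @param focal_bp,set_bp region sizes in bp.
#' @return tibble with `region`, `start`, `end`.
#' @export
focal_regions <- function(config, focal_bp = 4000, set_bp = 20000) {
  mid <- config$focal_mid
  tibble(
    region = c("upstream", "focal", "downstream"),
    start = c(mid - set_bp / 2, mid - focal_bp / 2, mid + focal_bp / 2),
    end = c(mid - focal_bp / 2, mid + focal_bp / 2, mid + set_bp / 2)
  )
}

#' Overwrite carriers with a shared sweep haplotype
#'
#' Emulates the hitchhiking footprint of a (partial) selective sweep
#' with recombinant escape: every carrier of the selected allele
#' receives the lineage donor haplotype in a contiguous segment around
#' the selected site, out to an independent random breakpoint on each
#' side; beyond its breakpoints a carrier keeps its original alleles.
#' Breakpoints are drawn so that the probability a site at distance `d`
#' from the selected site escapes the sweep is `min(1, 2 intensity d/W)`
#' (`W` = that side's half-width), hence the mean escaped fraction over
#' the region -- and so the residual carrier diversity -- is the
#' `intensity` factor (for intensity <= 0.5; larger values saturate and
#' are not meaningful for this model, except 1 which returns the input
#' unchanged). The nested escape segments leave strong linkage
#' disequilibrium within each flank of the selected site but none
#' across it, the omega signature, while carrier diversity collapses
#' toward the donor -- the two signals the scan stages detect.
#'
#' @param gt a [geno_matrix()].
#' @param region half-open interval `c(start, end)` in bp.
#' @param intensity diversity-reduction factor in (0, 1]; 1 returns the
#'   input unchanged.
#' @param fnp_pos genomic position of the selected site (the sweep
#'   centre).
#' @param allele `"alt"` or `"ref"`: which allele is being swept.
#' @param samples optional sample-id subset in which carriers are sought.
#' @param donor optional 0/1 donor haplotype over the region sites;
#'   default is the carrier consensus (site-wise majority, ties to ref).
#' @return a [geno_matrix()] with swept carriers.
#' @export
inject_sweep <- function(gt, region, intensity, fnp_pos,
                         allele = c("alt", "ref"), samples = NULL,
                         donor = NULL) {
  allele <- match.arg(allele)
  if (length(region) != 2 || region[2] <= region[1]) {
    abort("`region` must be a non-empty half-open interval c(start, end)")
  }
  if (intensity <= 0 || intensity > 1) abort("intensity must be in (0, 1]")
  if (intensity == 1) return(gt)
  sites <- which(gt$sites$pos >= region[1] & gt$sites$pos < region[2])
  if (length(sites) == 0) {
    warn("inject_sweep: no SNPs in region; matrix returned unchanged")
    return(gt)
  }
  fnp_idx <- match(fnp_pos, gt$sites$pos)
  if (is.na(fnp_idx)) abort("`fnp_pos` is not a site in the matrix")
  rows <- seq_len(nrow(gt$geno))
  if (!is.null(samples)) rows <- which(gt$samples$sample %in% samples)
  want <- if (allele == "alt") 1L else 0L
  carriers <- rows[gt$geno[rows, fnp_idx] == want]
  if (length(carriers) == 0) abort("inject_sweep: no carrier samples")
  if (is.null(donor)) {
    donor <- as.integer(round(colMeans(gt$geno[carriers, sites, drop = FALSE] == 1L) > 0.5))
  }
  stopifnot(length(donor) == length(sites))
  nc <- length(carriers)
  pos <- gt$sites$pos[sites]
  wl <- max(fnp_pos - region[1], 1)
  wr <- max(region[2] - fnp_pos, 1)
  # per-carrier, per-side escape breakpoints
  t_left <- wl * runif(nc) / (2 * intensity)
  t_right <- wr * runif(nc) / (2 * intensity)
  dist <- pos - fnp_pos                     # signed distance
  thr <- outer(t_right, pmax(dist, 0), ">") &
    outer(t_left, pmax(-dist, 0), ">")      # TRUE = donor applied
  block <- gt$geno[carriers, sites, drop = FALSE]
  donor_block <- matrix(rep(donor, each = nc), nrow = nc)
  block[thr] <- donor_block[thr]
  gt$geno[carriers, sites] <- block
  gt
}

#' Simulate the LTSS phenotype
#'
#' LTSS = baseline + effect x alt-allele code + subpopulation offset +
#' Gaussian noise, truncated to \[0, 100\] percent (it is a survival
#' percentage). Heterozygous FNP calls count half an allele; missing FNP
#' calls give a missing phenotype.
#'
#' @param gt a [geno_matrix()].
#' @param fnp_pos genomic position of the functional SNP.
#' @param effect phenotype shift per alt allele, in percent survival.
#' @param noise_sd Gaussian noise standard deviation, percent.
#' @param baseline intercept, percent.
#' @param offsets optional named per-subpopulation offsets, percent.
#' @return tibble with `sample`, `ltss`.
#' @export
simulate_phenotype <- function(gt, fnp_pos, effect, noise_sd,
                               baseline = 55, offsets = NULL) {
  fnp_idx <- match(fnp_pos, gt$sites$pos)
  if (is.na(fnp_idx)) abort("`fnp_pos` is not a site in the matrix")
  g <- gt$geno[, fnp_idx]
  code <- ifelse(g == 0L, 0, ifelse(g == 1L, 1, ifelse(g == 2L, 0.5, NA)))
  if (length(unique(stats::na.omit(code))) < 2) {
    warn("FNP is monomorphic: association on this phenotype will be unpowered")
  }
  off <- rep(0, nrow(gt$samples))
  if (!is.null(offsets)) {
    off <- unname(offsets[gt$samples$subpop])
    off[is.na(off)] <- 0
  }
  y <- baseline + effect * code + off + rnorm(length(code), 0, noise_sd)
  tibble(sample = gt$samples$sample,
         ltss = pmin(pmax(y, 0), 100))
}

#' Serialize a simulated dataset to standard formats
#'
#' Writes VCF (with the seed recorded in a header line), GFF3 gene
#' models, TSV phenotype and label tables, reference FASTA, a BED
#' centromere mask (possibly empty) and a YAML config mirror.
#'
#' @param sim a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    gff = file.path(dir, "genes.gff3"),
    pheno = file.path(dir, "phenotypes.tsv"),
    labels = file.path(dir, "labels.tsv"),
    ref = file.path(dir, "reference.fa"),
    mask = file.path(dir, "centromere_mask.bed"),
    config = file.path(dir, "config.yml")
  )
  write_vcf(sim$gt, paths["vcf"],
            extra_header = sprintf("##hapsweep_seed=%d", sim$config$seed))
  write_gene_models(sim$genes, paths["gff"])
  write_phenotypes(sim$pheno, paths["pheno"])
  write_labels(sim$gt$samples, paths["labels"])
  write_ref_fasta(sim$ref, paths["ref"])
  write_bed(sim$config$centromere %||%
              tibble(chrom = character(), start = numeric(), end = numeric()),
            paths["mask"])
  cfg <- sim$config
  cfg_list <- lapply(unclass(cfg), function(x) {
    if (is.null(x)) NULL else if (inherits(x, "tbl_df")) as.list(x) else x
  })
  yaml::write_yaml(cfg_list, paths["config"])
  invisible(paths)
}
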