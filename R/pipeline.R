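#' Pipeline configuration
#'
#' One structured configuration governing every stage. All randomness
#' flows from the single root `seed`, expanded deterministically per
#' stage, so a rerun with the same configuration reproduces every
#' output byte-for-byte.
#'
#' @param sim a [sim_config()] (used when no input paths are given).
#' @param inputs optional named list of paths (`vcf`, `labels`, `gff`,
#'   `pheno`, `ref`, `mask`) to analyse instead of simulating.
#' @param assoc list of association settings: `maf_min`, `r2_max`,
#'   `window`, `step`, `mds_dims`, `alpha`, `missing_max`, and
#'   `mds_exclude_bp` -- the width of the window centred on the focal
#'   gene left out of the stratification-covariate computation, so the
#'   candidate locus cannot absorb its own association signal
#'   (leave-locus-out, 0 disables).
#' @param omega an [omega_config()].
#' @param omega_groups subpopulation labels scanned separately for
#'   sweeps (a sweep is a within-population signal; a gene overlapping a
#'   sweep region in any scanned group is flagged). Default: the
#'   cultivated subpopulations when present, else all samples pooled.
#' @param pi_opts list: `window`, `focal_bp`, `set_bp`, `alpha`,
#'   `sample_missing_max`, `log_transform`.
#' @param hapnet list: `site_missing_max`, `seq_missing_max`,
#'   `impute_k`, `region_bp` (region width centred on the focal gene).
#' @param hapscore list: `maf_min`, `region_bp`.
#' @param seed root seed; overrides `sim$seed` when simulating.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            inputs = NULL,
                            assoc = list(),
                            omega = omega_config(),
                            omega_groups = NULL,
                            pi_opts = list(),
                            hapnet = list(),
                            hapscore = list(),
                            seed = 1L) {
  assoc <- utils::modifyList(
    list(maf_min = 0.01, r2_max = 0.2, window = 5, step = 2,
         mds_dims = 3, alpha = 0.05, missing_max = 0.8,
         mds_exclude_bp = 20000), assoc)
  pi_opts <- utils::modifyList(
    list(window = 100, focal_bp = 4000, set_bp = 20000, alpha = 0.05,
         sample_missing_max = 0.8, log_transform = FALSE), pi_opts)
  hapnet <- utils::modifyList(
    list(site_missing_max = 0.2, seq_missing_max = 0.3, impute_k = 3,
         region_bp = 6000), hapnet)
  hapscore <- utils::modifyList(
    list(maf_min = 0.2, region_bp = 6000), hapscore)
  structure(list(sim = sim, inputs = inputs, assoc = assoc, omega = omega,
                 omega_groups = omega_groups, pi_opts = pi_opts,
                 hapnet = hapnet, hapscore = hapscore,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# per-stage seed expansion from the root seed (kept below 2^31)
.stage_seed <- function(seed, stage) {
  (seed * 101L + match(stage, c("simulate", "assoc", "omega", "pi",
                                "hapnet", "hapscore")) * 7919L) %% 2000000000L
}

#' Run the full candidate-gene selection pipeline
#'
#' Simulate (or load) the panel, translate coding SNPs to amino-acid
#' markers, associate them with the phenotype, scan for omega sweeps,
#' contrast focal-versus-flank diversity per subpopulation, build the
#' haplotype network, score haplotypes and summarise the FNP. A gene is
#' reported as a selection candidate when it is both
#' association-significant and sweep-overlapping. Every stage output is
#' written under `out_dir` and recorded, with an md5 checksum, in a
#' machine-readable run manifest (written last); a stage failure aborts
#' with the stage name after persisting the partial manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir results directory (created).
#' @return the manifest, invisibly (list of class `run_manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "hapsweep",
    version = as.character(utils::packageVersion("hapsweep")),
    seed = config$seed,
    config = .config_echo(config),
    stages = list(),
    warnings = list()
  )
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    warns <- character()
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        manifest$stages[[name]] <<- list(status = "error",
                                         message = conditionMessage(e))
        .write_manifest(manifest, out_dir)
        abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        warns <<- c(warns, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
    manifest$stages[[name]] <<- list(status = "ok",
                                     outputs = res$outputs %||% character())
    if (length(warns) > 0) manifest$warnings[[name]] <<- warns
    res
  }

  # -- stage 1: inputs ------------------------------------------------
  run_stage("simulate", function() {
    if (is.null(config$inputs)) {
      cfg <- config$sim
      cfg$seed <- .stage_seed(config$seed, "simulate")
      sim <- simulate_dataset(cfg)
      paths <- write_dataset(sim, file.path(out_dir, "inputs"))
      state$gt <- sim$gt
      state$genes <- sim$genes
      state$pheno <- sim$pheno
      state$ref <- sim$ref
      state$truth <- sim$truth
      state$sim_cfg <- cfg
      readr::write_tsv(sim$truth$fnp_freq,
                       file.path(out_dir, "inputs", "truth_fnp.tsv"))
      list(outputs = unname(paths))
    } else {
      inp <- config$inputs
      for (f in c("vcf", "labels", "gff", "pheno", "ref")) {
        if (is.null(inp[[f]]) || !file.exists(inp[[f]])) {
          abort(sprintf("input '%s' missing: %s", f,
                        inp[[f]] %||% "<not given>"))
        }
      }
      state$gt <- read_genotypes(inp$vcf, inp$labels)
      state$genes <- read_gene_models(inp$gff)
      state$pheno <- read_phenotypes(inp$pheno)
      state$ref <- read_ref_fasta(inp$ref)
      state$sim_cfg <- NULL
      list(outputs = character())
    }
  })

  focal_gene <- state$genes[[1]]
  if ("gene_focal" %in% names(state$genes)) {
    focal_gene <- state$genes[["gene_focal"]]
  }
  focal_mid <- mean(focal_gene$span)

  # -- stage 2: amino-acid markers + association ----------------------
  assoc_res <- run_stage("assoc", function() {
    set.seed(.stage_seed(config$seed, "assoc"))
    aa <- build_aa_matrix(state$gt, state$genes, state$ref,
                          missing_max = config$assoc$missing_max)
    if (ncol(aa$markers) == 0) abort("no amino-acid markers")
    keep <- ld_prune(aa$markers, window = config$assoc$window,
                     step = config$assoc$step,
                     r2_max = config$assoc$r2_max,
                     maf_min = config$assoc$maf_min)
    if (length(keep) == 0) abort("no markers survive MAF/LD pruning")
    mds_gt <- state$gt
    if (config$assoc$mds_exclude_bp > 0) {
      half <- config$assoc$mds_exclude_bp / 2
      away <- mds_gt$sites$chrom != focal_gene$chrom |
        mds_gt$sites$pos < focal_mid - half |
        mds_gt$sites$pos >= focal_mid + half
      if (sum(away) >= 10) mds_gt <- gt_subset(mds_gt, sites = away)
    }
    mds <- mds_coords(mds_gt, dims = config$assoc$mds_dims)
    res <- associate_genes(aa$markers[, keep, drop = FALSE],
                           aa$variants, state$pheno,
                           covariates = mds, alpha = config$assoc$alpha)
    p1 <- file.path(out_dir, "aa_variants.tsv")
    p2 <- file.path(out_dir, "assoc_markers.tsv")
    p3 <- file.path(out_dir, "assoc_genes.tsv")
    p4 <- file.path(out_dir, "mds_coords.tsv")
    readr::write_tsv(aa$variants |> select(-dplyr::any_of("site_index")), p1)
    readr::write_tsv(res$markers, p2)
    readr::write_tsv(res$genes, p3)
    readr::write_tsv(mds, p4)
    list(outputs = c(p1, p2, p3, p4), res = res, aa = aa)
  })

  # -- stage 3: omega sweep scan (within-population signal) -----------
  sweep_res <- run_stage("omega", function() {
    chrom_len <- NULL
    if (!is.null(state$sim_cfg)) {
      chrom_len <- setNames(state$sim_cfg$chrom_length, state$sim_cfg$chrom)
    } else if (!is.null(state$ref)) {
      chrom_len <- setNames(nchar(state$ref), names(state$ref))
    }
    groups <- config$omega_groups
    if (is.null(groups)) {
      groups <- intersect(c("cultivar_A", "cultivar_B"),
                          unique(state$gt$samples$subpop))
    }
    split_ids <- if (length(groups) == 0) {
      list(all = state$gt$samples$sample)
    } else {
      setNames(lapply(groups, function(g) {
        state$gt$samples$sample[state$gt$samples$subpop == g]
      }), groups)
    }
    tracks <- list()
    regions <- list()
    gene_flags <- NULL
    for (g in names(split_ids)) {
      gt_g <- gt_subset(state$gt, samples = split_ids[[g]])
      track <- omega_scan(gt_g, config$omega, chrom_length = chrom_len)
      calls <- call_sweep_regions(track, state$genes)
      tracks[[g]] <- mutate(calls$track, group = g, .before = 1)
      if (nrow(calls$regions) > 0) {
        regions[[g]] <- mutate(calls$regions, group = g, .before = 1)
      }
      gf <- calls$genes
      gene_flags <- if (is.null(gene_flags)) gf else {
        mutate(gene_flags,
               sweep_overlap = .data$sweep_overlap | gf$sweep_overlap)
      }
    }
    regions <- bind_rows(regions)
    p1 <- file.path(out_dir, "omega_track.tsv")
    p2 <- file.path(out_dir, "sweep_regions.bed")
    p3 <- file.path(out_dir, "sweep_genes.tsv")
    readr::write_tsv(bind_rows(tracks), p1)
    if (nrow(regions) > 0) {
      write_bed(regions[, c("chrom", "start", "end")] |>
                  mutate(start = floor(.data$start),
                         end = pmax(floor(.data$end) - 1, floor(.data$start))),
                p2)
    } else {
      writeLines(character(), p2)
    }
    readr::write_tsv(gene_flags, p3)
    list(outputs = c(p1, p2, p3),
         calls = list(regions = regions, genes = gene_flags))
  })

  # -- stage 4: diversity contrast ------------------------------------
  run_stage("pi", function() {
    fb <- config$pi_opts$focal_bp
    sb <- config$pi_opts$set_bp
    regions <- tibble(
      region = c("upstream", "focal", "downstream"),
      start = c(focal_mid - sb / 2, focal_mid - fb / 2, focal_mid + fb / 2),
      end = c(focal_mid - fb / 2, focal_mid + fb / 2, focal_mid + sb / 2)
    )
    rows <- list()
    verdicts <- list()
    for (sp in unique(state$gt$samples$subpop)) {
      ids <- state$gt$samples$sample[state$gt$samples$subpop == sp]
      pw <- lapply(seq_len(nrow(regions)), function(i) {
        window_pi(state$gt, samples = ids,
                  region = c(regions$start[i], regions$end[i]),
                  window = config$pi_opts$window,
                  sample_missing_max = config$pi_opts$sample_missing_max) |>
          mutate(region = regions$region[i], subpop = sp)
      })
      rows[[sp]] <- bind_rows(pw)
      rc <- region_contrast(pw[[2]], pw[[1]], pw[[3]],
                            alpha = config$pi_opts$alpha,
                            log_transform = config$pi_opts$log_transform)
      verdicts[[sp]] <- glance(rc) |> mutate(subpop = sp, .before = 1)
    }
    p1 <- file.path(out_dir, "pi_windows.tsv")
    p2 <- file.path(out_dir, "pi_contrast.tsv")
    readr::write_tsv(bind_rows(rows), p1)
    readr::write_tsv(bind_rows(verdicts), p2)
    list(outputs = c(p1, p2))
  })

  # -- stage 5: haplotype network -------------------------------------
  hap_res <- run_stage("hapnet", function() {
    rb <- config$hapnet$region_bp
    aln <- genotypes_to_alignment(state$gt,
                                  c(focal_mid - rb / 2, focal_mid + rb / 2))
    hs <- prepare_haplotypes(aln, labels = state$gt$samples,
                             site_missing_max = config$hapnet$site_missing_max,
                             seq_missing_max = config$hapnet$seq_missing_max,
                             impute_k = config$hapnet$impute_k)
    net <- build_msn(hs)
    p1 <- file.path(out_dir, "haplotypes.tsv")
    p2 <- file.path(out_dir, "hapnet.graphml")
    readr::write_tsv(hs$haps |> select(-"members"), p1)
    write_hapnet_graphml(net, p2, hapset = hs)
    list(outputs = c(p1, p2), hs = hs, net = net)
  })

  # -- stage 6: haplotype scores + FNP summary ------------------------
  run_stage("hapscore", function() {
    rb <- config$hapscore$region_bp
    st <- haplotype_scores(state$gt,
                           c(focal_mid - rb / 2, focal_mid + rb / 2),
                           maf_min = config$hapscore$maf_min)
    # the pooled panel is the species under study; outgroup relatives
    # are summarised separately
    pooled <- st |>
      dplyr::filter(.data$subpop != "outgroup") |>
      mutate(subpop = "pooled")
    modal <- bind_rows(assess_modality(st), assess_modality(pooled))
    fnp_pos <- if (!is.null(state$truth)) {
      state$truth$fnp$pos
    } else {
      state$gt$sites$pos[attr(st, "markers")[1]]
    }
    fnp <- fnp_summary(state$gt, fnp_pos)
    p1 <- file.path(out_dir, "hap_scores.tsv")
    p2 <- file.path(out_dir, "modality.tsv")
    p3 <- file.path(out_dir, "fnp_summary.tsv")
    readr::write_tsv(tibble::as_tibble(st), p1)
    readr::write_tsv(modal, p2)
    readr::write_tsv(tidy(fnp), p3)
    list(outputs = c(p1, p2, p3))
  })

  # -- selection candidates: associated AND swept ---------------------
  candidates <- assoc_res$res$genes |>
    select("gene", "min_p_adj", "significant") |>
    left_join(sweep_res$calls$genes, by = "gene") |>
    mutate(selection_candidate = .data$significant & .data$sweep_overlap)
  pc <- file.path(out_dir, "selection_candidates.tsv")
  readr::write_tsv(candidates, pc)
  manifest$stages[["candidates"]] <- list(status = "ok", outputs = pc)

  manifest$checksums <- .output_checksums(manifest, out_dir)
  .write_manifest(manifest, out_dir)
  manifest$candidates <- candidates
  invisible(structure(manifest, class = "run_manifest"))
}

.config_echo <- function(config) {
  drop_tbl <- function(x) {
    if (inherits(x, "tbl_df")) return(as.list(x))
    if (is.list(x)) return(lapply(unclass(x), drop_tbl))
    x
  }
  drop_tbl(config)
}

.output_checksums <- function(manifest, out_dir) {
  outs <- unlist(lapply(manifest$stages, `[[`, "outputs"), use.names = FALSE)
  outs <- outs[file.exists(outs)]
  sums <- tools::md5sum(outs)
  setNames(unname(sums), sub(paste0("^", out_dir, "/?"), "", outs))
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(NULL)
}
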