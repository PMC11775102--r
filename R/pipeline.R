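## End-to-end orchestration: the default synthetic scenario with planted
## environment-dependent regulation, and a deterministic pipeline runner
## that writes all stage outputs as plain-text tables.

#' Build the default synthetic study scenario
#'
#' Generates a complete toy study with planted structure at every level:
#' a four-chromosome genome (two autosomes, chrX, chrY) with 2000 genes;
#' a 13-state chromatin segmentation with its binarized six-mark tracks;
#' three stage-resolved H3K79me2 peak sets with planted dynamics patterns
#' and a 10x RS-specific rate excess on chrX; planted deregulated genes
#' tied to promoter chromatin environment (upregulated genes drawn from
#' repressed/bivalent promoters and linked to H3K79me2-positive enhancers;
#' downregulated genes drawn from active promoters with H3K79me2-covered
#' gene bodies); a spike-in count matrix (ERCC rows, planted unwanted
#' factor); and spike-scaled CUT&Tag-like signal tracks where upregulated
#' promoters carry 3x H3K27me3 in CTL versus KO.
#'
#' @param seed integer master seed.
#' @param n_genes number of genes (default 2000).
#' @param n_up,n_down planted deregulated gene counts (default 100 each).
#' @param effect_log2fc planted effect size (default 2).
#' @param dispersion NB dispersion (default 0.1).
#' @param unwanted_strength planted unwanted-factor scale (default 1).
#' @param x_bias RS-specific chrX rate multiplier (default 10).
#' @param rate_per_mb base peak rate per Mb (default 20).
#' @return list with components `assembly`, `genes`, `model`, `tracks`,
#'   `segmentation` (truth), `peaks` (per stage), `peak_truth`,
#'   `h3k79_peaks`, `counts`, `group`, `control`, `cuttag`, `truth`.
#' @export
simulate_scenario <- function(seed = 1, n_genes = 2000, n_up = 100,
                              n_down = 100, effect_log2fc = 2,
                              dispersion = 0.1, unwanted_strength = 1,
                              x_bias = 10, rate_per_mb = 20) {
  assembly <- default_assembly()
  genes <- simulate_genome(assembly, n_genes, seed = seed)
  model <- default_state_model()
  sim <- simulate_state_tracks(model, assembly, seed = seed + 1)
  seg <- sim$truth

  mult <- matrix(1, length(assembly), 7,
                 dimnames = list(names(assembly),
                                 names(default_pattern_probs())))
  mult["chrX", "RS-spe"] <- x_bias
  pk <- simulate_peaks(assembly, rate_per_mb = rate_per_mb,
                       chrom_pattern_multiplier = mult, seed = seed + 2)

  ## promoter environments on the true segmentation decide the planted
  ## DE classes
  env <- gene_promoter_environment(genes, seg, assembly = assembly)
  repressed <- env$gene_id[env$predominant_state %in%
                             c("ReprPC", "TssBiv", "EnhBiv")]
  active <- env$gene_id[env$predominant_state %in%
                          c("TSSA", "Tx", "EnhG", "EnhA")]
  enh <- classify_enhancers(seg)
  links_all <- link_enhancer_genes(enh, genes, mode = "all")

  gsel <- with_seed(seed + 3, {
    up_pool <- intersect(repressed, links_all$gene_id)
    down_pool <- setdiff(active, up_pool)
    list(up = sample(up_pool, min(n_up, length(up_pool))),
         down = sample(down_pool, min(n_down, length(down_pool))))
  })
  up_genes <- gsel$up
  down_genes <- gsel$down

  ## H3K79me2 mark peaks: the RS-stage set as background, minus anything
  ## on an upregulated gene body, plus body-covering peaks on downregulated
  ## genes and peaks on one linked enhancer of each upregulated gene
  bg <- pk$peaks$RS
  up_idx <- genes$gene_id %in% up_genes
  up_bodies <- genes[up_idx, c("chrom", "start", "end")]
  if (nrow(up_bodies)) {
    hit <- interval_intersect(bg, up_bodies)$index_a
    if (length(hit)) bg <- bg[-unique(hit), , drop = FALSE]
  }
  down_rows <- genes[genes$gene_id %in% down_genes, , drop = FALSE]
  body_peaks <- data.frame(chrom = down_rows$chrom,
                           start = down_rows$start,
                           end = pmin(down_rows$start + 2000, down_rows$end),
                           stringsAsFactors = FALSE)
  enh_up <- links_all[links_all$gene_id %in% up_genes, , drop = FALSE]
  enh_up <- enh_up[!duplicated(enh_up$gene_id), , drop = FALSE]
  er <- enh[match(enh_up$enhancer_id, enh$enhancer_id), , drop = FALSE]
  enh_peaks <- data.frame(chrom = er$chrom, start = er$start, end = er$end,
                          stringsAsFactors = FALSE)
  ## enhancer peaks must not touch any up-gene body (keeps ENH-only planted)
  if (nrow(enh_peaks) && nrow(up_bodies)) {
    hit <- interval_intersect(enh_peaks, up_bodies)$index_a
    if (length(hit)) enh_peaks <- enh_peaks[-unique(hit), , drop = FALSE]
  }
  h3k79 <- rbind(bg, body_peaks, enh_peaks)
  h3k79 <- h3k79[interval_order(h3k79, assembly), , drop = FALSE]
  rownames(h3k79) <- NULL

  cm <- simulate_counts(genes, up_genes = up_genes, down_genes = down_genes,
                        effect_log2fc = effect_log2fc,
                        dispersion = dispersion,
                        unwanted_strength = unwanted_strength,
                        seed = seed + 4)

  cuttag <- simulate_cuttag(assembly, genes, up_genes, down_genes,
                            seed = seed + 5)

  list(assembly = assembly, genes = genes, model = model,
       tracks = sim$tracks, segmentation = seg,
       peaks = pk$peaks, peak_truth = pk$truth, h3k79_peaks = h3k79,
       counts = cm$counts, group = cm$group, control = cm$control,
       cuttag = cuttag,
       truth = list(up = up_genes, down = down_genes,
                    factor = cm$truth$factor,
                    loadings = cm$truth$loadings,
                    x_bias = x_bias, seed = seed))
}

## CUT&Tag-like per-sample signal tracks for two marks with a planted
## genotype-by-class H3K27me3 contrast at upregulated promoters, plus
## per-sample depth captured by the spike read counts
simulate_cuttag <- function(assembly, genes, up_genes, down_genes,
                            bin_size = 200, window = 3000, seed = 1) {
  with_seed(seed, {
    samples <- c(paste0("CTL", 1:3), paste0("KO", 1:3))
    genotype <- setNames(rep(c("CTL", "KO"), each = 3), samples)
    depth <- runif(length(samples), 0.6, 1.4)
    names(depth) <- samples
    up_rows <- genes[genes$gene_id %in% up_genes, , drop = FALSE]
    tracks <- list(H3K27me3 = list(), H3K27ac = list())
    for (s in samples) {
      vals27me3 <- list()
      vals27ac <- list()
      for (chr in names(assembly)) {
        nb <- ceiling(unname(assembly[chr]) / bin_size)
        base <- pmax(rnorm(nb, 1, 0.2), 0)
        v3 <- base
        v2 <- pmax(rnorm(nb, 1, 0.2), 0)
        sel <- which(up_rows$chrom == chr)
        for (i in sel) {
          tssb <- floor(up_rows$tss[i] / bin_size) + 1
          half <- floor(window / bin_size)
          idx <- max(tssb - half, 1):min(tssb + half, nb)
          amp <- if (genotype[s] == "CTL") 3 else 1
          v3[idx] <- v3[idx] + amp *
            exp(-((idx - tssb) * bin_size)^2 / (2 * 1000^2))
        }
        vals27me3[[chr]] <- v3 * depth[s]
        vals27ac[[chr]] <- v2 * depth[s]
      }
      tracks$H3K27me3[[s]] <- signal_track(vals27me3, bin_size)
      tracks$H3K27ac[[s]] <- signal_track(vals27ac, bin_size)
    }
    spike <- data.frame(sample = samples,
                        target_reads = round(2e6 * depth),
                        spike_reads = round(1e5 * depth),
                        stringsAsFactors = FALSE)
    list(tracks = tracks, spike = spike, genotype = genotype,
         depth = depth)
  })
}

#' Pipeline configuration with study defaults
#'
#' Defaults follow the study parameters: 200 bp bins, TSS window
#' +/- 3 kb, 100 kb enhancer-gene distance, cpm filter (1 cpm in >= 2
#' samples), fold-change threshold 1.5 at FDR 0.05, 10000 permutations,
#' one unwanted-variation factor.
#'
#' @param seed integer master seed.
#' @param output_dir output directory.
#' @param ... overrides for any default parameter.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, output_dir = tempfile("chromdyn_run"),
                            ...) {
  cfg <- list(bin_size = 200, tss_window = 3000, enhancer_dist = 100000,
              min_cpm = 1, min_samples = 2, fc = 1.5, alpha = 0.05,
              n_perm = 10000, k_ruv = 1, seed = seed,
              output_dir = output_dir,
              n_genes = 2000, n_up = 100, n_down = 100,
              effect_log2fc = 2, dispersion = 0.1, unwanted_strength = 1,
              x_bias = 10, rate_per_mb = 20)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$fc <= 1) stop("fc threshold must be > 1")
  if (cfg$n_perm < 100) stop("n_perm must be >= 100")
  structure(cfg, class = "pipeline_config")
}

## write a TSV with a provenance header comment
write_stage_tsv <- function(df, path, params = NULL) {
  hdr <- paste0("# chromdyn ", as.character(packageVersion("chromdyn")),
                if (!is.null(params)) paste0(" | ", params) else "")
  con <- file(path, "w")
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
}

#' Run the full analysis pipeline on the default synthetic scenario
#'
#' Executes every stage in dependency order on data generated from the
#' config seed: simulation, segmentation decoding, peak annotation and
#' dynamics, chromosome densities, promoter environments, enhancer
#' classification/linking/expression, spike-in differential expression
#' (unwanted-variation removal + threshold test), gene-level mark
#' categories, CUT&Tag class profiles, and the stage-peak association
#' matrix. All outputs are plain-text tables under `config$output_dir`,
#' together with the resolved config, a log, and a summary of
#' planted-structure recovery. Reruns with the same config are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the output directory path.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$fc <= 1) stop("fc threshold must be > 1")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  logf <- file(out("pipeline.log"), "w")
  on.exit(close(logf))
  logmsg <- function(...) writeLines(paste0("[", "stage", "] ", ...), logf)

  ## resolved config without the (run-specific) output path, so reruns with
  ## the same parameters produce byte-identical output trees
  cfg_dump <- unclass(config)
  cfg_dump$output_dir <- NULL
  jsonlite::write_json(cfg_dump, out("resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  with_seed(config$seed, run_pipeline_stages(config, out, logmsg))
}

## pipeline body; runs under a seeded RNG so every stochastic step
## (including simulated exact tests) is reproducible from the config seed
run_pipeline_stages <- function(config, out, logmsg) {
  logmsg("simulate: building scenario")
  sc <- simulate_scenario(seed = config$seed, n_genes = config$n_genes,
                          n_up = config$n_up, n_down = config$n_down,
                          effect_log2fc = config$effect_log2fc,
                          dispersion = config$dispersion,
                          unwanted_strength = config$unwanted_strength,
                          x_bias = config$x_bias,
                          rate_per_mb = config$rate_per_mb)
  write_chrom_sizes(sc$assembly, out("assembly.chrom.sizes"))
  write_genes_gtf(sc$genes, out("genes.gtf"))
  for (s in names(sc$peaks)) write_bed(sc$peaks[[s]], out(paste0("peaks_", s, ".bed")))
  write_bed(sc$h3k79_peaks, out("h3k79me2_peaks.bed"))

  logmsg("segment: decoding chromatin states")
  seg <- decode_segmentation(sc$model, sc$tracks, sc$assembly)
  write_segmentation(seg, out("segmentation.bed"))

  logmsg("annotate: peak genomic categories")
  annot <- do.call(rbind, lapply(names(sc$peaks), function(s) {
    cat <- annotate_peaks(sc$peaks[[s]], sc$genes,
                          tss_window = config$tss_window)
    data.frame(stage = s, category = levels(cat),
               n = as.integer(table(cat)),
               fraction = as.numeric(table(cat)) / length(cat))
  }))
  write_stage_tsv(annot, out("peak_annotation.tsv"),
                  paste0("tss_window=", config$tss_window))

  logmsg("dynamics: cross-stage presence classes")
  dyn <- classify_stage_dynamics(sc$peaks)
  write_stage_tsv(dyn, out("dynamics.tsv"))

  logmsg("density: per-chromosome peak densities")
  dens <- do.call(rbind, lapply(names(sc$peaks), function(s)
    cbind(stage = s, chromosome_peak_density(sc$peaks[[s]], sc$assembly))))
  write_stage_tsv(dens, out("peak_density.tsv"))

  logmsg("environment: promoter chromatin states")
  env <- gene_promoter_environment(sc$genes, seg,
                                   window = config$tss_window,
                                   assembly = sc$assembly)
  write_stage_tsv(env, out("gene_environment.tsv"))

  logmsg("enhancers: classification and gene links")
  enh <- classify_enhancers(seg, sc$h3k79_peaks)
  links <- link_enhancer_genes(enh, sc$genes, mode = "all",
                               max_dist = config$enhancer_dist)
  write_stage_tsv(enh, out("enhancers.tsv"))
  write_stage_tsv(links[, c("enhancer_id", "gene_id", "distance")],
                  out("enhancer_links.tsv"))

  logmsg("de: spike-in differential expression")
  filtered <- filter_expressed(sc$counts, sc$control,
                               min_cpm = config$min_cpm,
                               min_samples = config$min_samples)
  ctl_flags <- attr(filtered, "control")
  ruv <- ruv_control_normalize(filtered, ctl_flags, k = config$k_ruv)
  de <- de_threshold_test(filtered, sc$group, W = ruv$W,
                          control = ctl_flags,
                          fc_threshold = config$fc, alpha = config$alpha)
  write_stage_tsv(de, out("de_results.tsv"),
                  paste0("fc=", config$fc, " alpha=", config$alpha))
  fe <- feature_enrichment(de, sc$genes)
  write_stage_tsv(fe, out("feature_enrichment.tsv"))

  logmsg("categories: gene-level H3K79me2 classes")
  de_status <- setNames(de$status, de$gene_id)[!de$control]
  cat79 <- h3k79_gene_category(sc$genes, sc$h3k79_peaks, enh, links,
                               de_status = de_status)
  write_stage_tsv(data.frame(gene_id = names(cat79$category),
                             category = unname(cat79$category)),
                  out("h3k79_categories.tsv"))

  logmsg("expression: linked-gene expression by enhancer class")
  cp <- cpm_matrix(filtered, ctl_flags)
  mean_cpm <- rowMeans(cp[!ctl_flags, , drop = FALSE])
  ee <- enhancer_expression(enh, links, mean_cpm)
  write_stage_tsv(ee$tests, out("enhancer_expression_tests.tsv"))

  logmsg("cuttag: spike-scaled class profiles")
  factors <- spike_scale_factors(sc$cuttag$spike)
  profs <- lapply(names(sc$cuttag$tracks), function(mark)
    class_tss_profiles(sc$cuttag$tracks[[mark]], factors,
                       sc$cuttag$genotype, sc$genes, de_status,
                       window = config$tss_window))
  names(profs) <- names(sc$cuttag$tracks)
  for (mark in names(profs)) for (gt in names(profs[[mark]]))
    write_stage_tsv(as.data.frame(profs[[mark]][[gt]]),
                    out(paste0("cuttag_profile_", mark, "_", gt, ".tsv")))

  logmsg("assoc: stage-peak association matrix")
  am <- association_matrix(sc$peaks, sc$assembly,
                           n_perm = min(config$n_perm, 1000),
                           seed = config$seed)
  write_stage_tsv(as.data.frame(am$nz), out("assoc_nz.tsv"))
  write_stage_tsv(as.data.frame(am$p), out("assoc_p.tsv"))

  logmsg("summary: planted-structure recovery")
  up_called <- de$gene_id[de$status == "up"]
  down_called <- de$gene_id[de$status == "down"]
  f1 <- function(called, truth_set) {
    tp <- length(intersect(called, truth_set))
    if (tp == 0) return(0)
    prec <- tp / length(called)
    rec <- tp / length(truth_set)
    2 * prec * rec / (prec + rec)
  }
  dens_w <- split(dens, dens$stage)
  xr <- function(stage) {
    d <- dens_w[[stage]]
    d$density_per_mb[d$chrom == "chrX"] /
      mean(d$density_per_mb[d$chrom %in% c("chr1", "chr2")])
  }
  summary <- list(
    n_genes = nrow(sc$genes),
    de_up_called = length(up_called), de_down_called = length(down_called),
    f1_up = f1(up_called, sc$truth$up),
    f1_down = f1(down_called, sc$truth$down),
    env_contrast_p = cat79$contrast$p,
    x_density_ratio_rs_vs_gsc = xr("RS") / xr("GSC"))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  logmsg("done")
  invisible(config$output_dir)
}
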