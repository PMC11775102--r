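## Peak annotation, per-chromosome densities, cross-stage dynamics, and
## TSS-anchored meta-profiles.

#' Annotate peaks to genomic categories
#'
#' Each peak is assigned one of four categories with a fixed priority:
#' promoter (overlaps the strand-aware TSS window of any gene) >
#' intragenic (overlaps a gene body) > downstream (within
#' `downstream_window` bp past a gene's 3' end) > distal_intergenic.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`.
#' @param genes gene models from [read_gene_models()] (needs `chrom`,
#'   `start`, `end`, `strand`, `tss`).
#' @param tss_window half-width of the promoter window around the TSS in bp
#'   (default 3000; the window covers tss - w .. tss + w inclusive).
#' @param downstream_window bp past the 3' end counted as downstream
#'   (default 3000).
#' @return factor of categories (promoter, intragenic, downstream,
#'   distal_intergenic), one per peak; the fractions are available through
#'   `table()/length()`.
#' @export
annotate_peaks <- function(peaks, genes, tss_window = 3000,
                           downstream_window = 3000) {
  lvls <- c("promoter", "intragenic", "downstream", "distal_intergenic")
  if (nrow(peaks) == 0)
    return(factor(character(), levels = lvls))
  if (nrow(genes) == 0) stop("genes must be non-empty")
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(genes$tss - tss_window, 0),
                     end = genes$tss + tss_window + 1)
  body <- genes[, c("chrom", "start", "end")]
  dstart <- ifelse(genes$strand == "+", genes$end,
                   pmax(genes$start - downstream_window, 0))
  dend <- ifelse(genes$strand == "+", genes$end + downstream_window,
                 genes$start)
  down <- data.frame(chrom = genes$chrom, start = dstart, end = dend)
  down <- down[down$end > down$start, , drop = FALSE]
  hit <- function(regions) {
    if (nrow(regions) == 0) return(logical(nrow(peaks)))
    seq_len(nrow(peaks)) %in%
      interval_intersect(peaks, regions, min_overlap = 1)$index_a
  }
  cat <- rep("distal_intergenic", nrow(peaks))
  cat[hit(down)] <- "downstream"
  cat[hit(body)] <- "intragenic"
  cat[hit(prom)] <- "promoter"
  factor(cat, levels = lvls)
}

#' Per-chromosome peak density
#'
#' Peak counts normalized to chromosome length (peaks per Mb).
#'
#' @param peaks data.frame with `chrom`, `start`, `end`.
#' @param assembly a [genome_assembly()] covering all peak chromosomes.
#' @return data.frame with `chrom`, `n_peaks`, `length_bp`,
#'   `density_per_mb` (one row per assembly chromosome).
#' @export
chromosome_peak_density <- function(peaks, assembly) {
  check_intervals(peaks, assembly, "peak")
  n <- table(factor(peaks$chrom, levels = names(assembly)))
  data.frame(chrom = names(assembly),
             n_peaks = as.integer(n),
             length_bp = as.numeric(assembly),
             density_per_mb = as.integer(n) / (as.numeric(assembly) / 1e6),
             stringsAsFactors = FALSE)
}

#' Per-chromosome density fold change between two stages
#'
#' Ratio `density_b / density_a` per chromosome; `Inf` when stage a has no
#' peaks but stage b does, `NA` when both are empty.
#'
#' @param density_a,density_b outputs of [chromosome_peak_density()] on the
#'   same assembly.
#' @return data.frame with `chrom`, `ratio`.
#' @export
ratio_between_stages <- function(density_a, density_b) {
  stopifnot(identical(density_a$chrom, density_b$chrom))
  a <- density_a$density_per_mb
  b <- density_b$density_per_mb
  ratio <- ifelse(a == 0 & b == 0, NA_real_,
                  ifelse(a == 0, Inf, b / a))
  data.frame(chrom = density_a$chrom, ratio = ratio,
             stringsAsFactors = FALSE)
}

## presence pattern -> class label for an ordered stage vector
dynamics_class <- function(presence, stages) {
  on <- which(presence == 1)
  if (length(on) == length(stages)) return("common")
  if (length(on) == 1) return(paste0(stages[on], "-spe"))
  paste(stages[on], collapse = "-")
}

#' Classify cross-stage peak dynamics
#'
#' All stage peak sets are union-merged into maximal regions (book-ended
#' intervals merge, the BEDtools merge convention). Each merged
#' region is scored present in a stage when it overlaps any peak of that
#' stage by at least `min_overlap` bp, and the presence pattern names the
#' class: all stages -> `common`; one stage -> `<stage>-spe`; otherwise the
#' joined stage names (e.g. `GSC-SCI`, `GSC-RS`). Classes whose region count
#' is at most `min_group` are flagged minor.
#'
#' @param peaksets named list of peak data.frames, ordered by stage.
#' @param min_overlap minimum bp overlap for presence (default 1).
#' @param min_group groups with <= this many regions are flagged minor
#'   (default 100).
#' @return data.frame with `chrom`, `start`, `end`, one 0/1 presence column
#'   per stage, `class`, `minor`.
#' @export
classify_stage_dynamics <- function(peaksets, min_overlap = 1,
                                    min_group = 100) {
  stages <- names(peaksets)
  if (is.null(stages) || anyDuplicated(stages))
    stop("peaksets must be a named list with unique stage labels")
  if (length(stages) < 2) stop("need at least 2 stages")
  all_peaks <- do.call(rbind, lapply(peaksets, function(p)
    p[, c("chrom", "start", "end")]))
  if (nrow(all_peaks) == 0)
    stop("no peaks in any stage")
  merged_gr <- GenomicRanges::reduce(as_granges0(all_peaks))
  merged <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged_gr)),
    start = GenomicRanges::start(merged_gr) - 1L,
    end = GenomicRanges::end(merged_gr), stringsAsFactors = FALSE)
  presence <- sapply(stages, function(s) {
    hits <- interval_intersect(merged, peaksets[[s]], min_overlap)
    as.integer(seq_len(nrow(merged)) %in% hits$index_a)
  })
  presence <- matrix(presence, nrow = nrow(merged),
                     dimnames = list(NULL, stages))
  cls <- apply(presence, 1, dynamics_class, stages = stages)
  counts <- table(cls)
  out <- cbind(merged, as.data.frame(presence), class = cls,
               minor = as.integer(counts[cls]) <= min_group,
             stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Construct a per-bin signal track
#'
#' @param values named list (per chromosome) of numeric per-bin values.
#' @param bin_size bin width in bp.
#' @return a `signal_track` object.
#' @export
signal_track <- function(values, bin_size = 200) {
  if (is.null(names(values))) stop("values must be a named list")
  structure(list(values = values, bin_size = bin_size),
            class = "signal_track")
}

## mean signal of a track over [start,end) (0-based), clipped to track
track_window_bins <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) return(NULL)
  bs <- track$bin_size
  b0 <- max(floor(start / bs), 0) + 1
  b1 <- min(ceiling(end / bs), length(v))
  if (b1 < b0) return(NULL)
  v[b0:b1]
}

## rescale a numeric vector to m meta-bins by linear interpolation of means
rescale_bins <- function(v, m) {
  if (length(v) == m) return(v)
  idx <- findInterval(seq(0, 1, length.out = m + 1) * length(v) + 1e-9,
                      seq_len(length(v) + 1))
  out <- numeric(m)
  edges <- seq(0, length(v), length.out = m + 1)
  for (i in seq_len(m)) {
    lo <- floor(edges[i]) + 1
    hi <- max(ceiling(edges[i + 1]), lo)
    out[i] <- mean(v[lo:min(hi, length(v))])
  }
  out
}

#' TSS-anchored meta-gene signal profile by expression group
#'
#' Genes are split into expression-percentile groups (deciles by default)
#' within the sample; for each gene a profile is built from an upstream
#' flank at native bin resolution, the gene body rescaled to a fixed number
#' of meta-bins, and a downstream flank. Minus-strand genes are flipped so
#' positions run 5' to 3'. The group mean per position is returned.
#'
#' @param signal a [signal_track()].
#' @param genes gene models data.frame.
#' @param expression named numeric vector (gene_id -> expression, e.g. cpm).
#' @param n_groups number of percentile groups (default 10).
#' @param flank flank width in bp on each side (default 1500).
#' @param body_bins meta-bins for the rescaled gene body (default 100).
#' @return matrix groups x positions with attributes `positions` (labels)
#'   and `excluded` (genes shorter than 2 signal bins, dropped).
#' @export
tss_profile <- function(signal, genes, expression, n_groups = 10,
                        flank = 1500, body_bins = 100) {
  bs <- signal$bin_size
  flank_bins <- ceiling(flank / bs)
  genes <- genes[genes$gene_id %in% names(expression), , drop = FALSE]
  too_short <- (genes$end - genes$start) < 2 * bs
  excluded <- sum(too_short)
  genes <- genes[!too_short, , drop = FALSE]
  if (nrow(genes) == 0) stop("no usable genes")
  expr <- expression[genes$gene_id]
  grp <- cut(rank(expr, ties.method = "first"),
             breaks = n_groups, labels = FALSE)
  n_pos <- 2 * flank_bins + body_bins
  prof_sum <- matrix(0, n_groups, n_pos)
  prof_n <- matrix(0, n_groups, n_pos)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    up <- track_window_bins(signal, g$chrom, g$start - flank, g$start)
    body <- track_window_bins(signal, g$chrom, g$start, g$end)
    down <- track_window_bins(signal, g$chrom, g$end, g$end + flank)
    if (is.null(body)) next
    pad <- function(v, n, left) {
      if (is.null(v)) v <- numeric(0)
      if (length(v) >= n) return(v[seq_len(n)])
      if (left) c(rep(NA_real_, n - length(v)), v)
      else c(v, rep(NA_real_, n - length(v)))
    }
    row <- c(pad(up, flank_bins, left = TRUE),
             rescale_bins(body, body_bins),
             pad(down, flank_bins, left = FALSE))
    if (g$strand == "-") row <- rev(row)
    ok <- !is.na(row)
    prof_sum[grp[i], ok] <- prof_sum[grp[i], ok] + row[ok]
    prof_n[grp[i], ok] <- prof_n[grp[i], ok] + 1
  }
  prof <- prof_sum / pmax(prof_n, 1)
  prof[prof_n == 0] <- NA
  rownames(prof) <- paste0("decile", seq_len(n_groups))
  attr(prof, "positions") <- c(
    paste0("up", rev(seq_len(flank_bins))),
    paste0("body", seq_len(body_bins)),
    paste0("down", seq_len(flank_bins)))
  attr(prof, "excluded") <- excluded
  prof
}
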