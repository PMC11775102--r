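## Heterologous spike-in (Drosophila nuclei) scaling for CUT&Tag signal and
## DE-class-stratified TSS profiles.

#' Spike-in scale factors
#'
#' `factor_i = reference / spike_reads_i`, so multiplying each sample's
#' signal by its factor equalizes spike-derived signal across samples.
#' The default reference is the minimum spike count over samples, which
#' keeps all factors at or below 1. Factors are comparable only within one
#' reference constant.
#'
#' @param spike_table data.frame with columns `sample`, `target_reads`,
#'   `spike_reads`.
#' @param reference reference constant (default `min(spike_reads)`).
#' @return the input with an added `factor` column.
#' @export
spike_scale_factors <- function(spike_table, reference = NULL) {
  sr <- spike_table$spike_reads
  if (any(sr <= 0))
    stop("zero spike reads in sample(s): ",
         paste(spike_table$sample[sr <= 0], collapse = ", "))
  if (is.null(reference)) reference <- min(sr)
  spike_table$factor <- reference / sr
  attr(spike_table, "reference") <- reference
  spike_table
}

#' DE-class-stratified TSS profiles of spike-scaled signal
#'
#' Per-sample signal tracks are scaled by their spike factors, averaged
#' within genotype, and summarized as mean profiles over TSS +/- `window`
#' for each differential-expression class (up / down / not). Minus-strand
#' genes are flipped so positions run 5' to 3'. Classes without genes are
#' omitted with a warning.
#'
#' @param tracks named list of [signal_track()] objects, one per sample.
#' @param factors data.frame from [spike_scale_factors()] covering the
#'   samples in `tracks`.
#' @param genotype named character vector sample -> genotype (e.g. KO/CTL).
#' @param genes gene models data.frame.
#' @param de_status named vector gene_id -> {up, down, not}.
#' @param window half-width of the TSS window in bp (default 3000).
#' @return named list (one element per genotype) of matrices
#'   class x position (mean scaled signal), with bp offsets as the
#'   `"positions"` attribute.
#' @export
class_tss_profiles <- function(tracks, factors, genotype, genes, de_status,
                               window = 3000) {
  samples <- names(tracks)
  fac <- setNames(factors$factor, factors$sample)[samples]
  if (anyNA(fac)) stop("missing scale factor for some samples")
  bs <- tracks[[1]]$bin_size
  n_bins <- 2 * floor(window / bs) + 1
  classes <- c("up", "down", "not")
  genes <- genes[genes$gene_id %in% names(de_status), , drop = FALSE]
  gene_class <- de_status[genes$gene_id]
  out <- list()
  for (gt in unique(genotype[samples])) {
    gt_samples <- samples[genotype[samples] == gt]
    prof <- matrix(NA_real_, length(classes), n_bins,
                   dimnames = list(classes, NULL))
    for (cl in classes) {
      sel <- which(gene_class == cl)
      if (length(sel) == 0) {
        warning("no genes in class '", cl, "' for genotype ", gt)
        next
      }
      acc <- matrix(0, length(sel), n_bins)
      cnt <- matrix(0, length(sel), n_bins)
      for (s in gt_samples) {
        tr <- tracks[[s]]
        for (j in seq_along(sel)) {
          g <- genes[sel[j], ]
          v <- tr$values[[g$chrom]]
          if (is.null(v)) next
          tss_bin <- floor(g$tss / bs) + 1
          half <- floor(window / bs)
          idx <- (tss_bin - half):(tss_bin + half)
          ok <- idx >= 1 & idx <= length(v)
          row <- rep(NA_real_, n_bins)
          row[ok] <- v[idx[ok]] * fac[s]
          if (g$strand == "-") row <- rev(row)
          fin <- !is.na(row)
          acc[j, fin] <- acc[j, fin] + row[fin]
          cnt[j, fin] <- cnt[j, fin] + 1
        }
      }
      m <- acc / pmax(cnt, 1)
      m[cnt == 0] <- NA
      prof[cl, ] <- colMeans(m, na.rm = TRUE)
    }
    out[[gt]] <- prof
  }
  half <- floor(window / bs)
  for (gt in names(out)) attr(out[[gt]], "positions") <- (-half:half) * bs
  out
}
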