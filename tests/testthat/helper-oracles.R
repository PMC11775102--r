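# Brute-force per-base oracles and small random-instance generators.
# Oracles are written independently of the package internals: they expand
# intervals to per-base occupancy vectors and count.

random_intervals <- function(n, chrom_len, max_len = 500, chrom = "chr1") {
  start <- floor(runif(n) * (chrom_len - max_len))
  len <- pmax(1, floor(runif(n) * max_len))
  df <- data.frame(chrom = chrom, start = start,
                   end = pmin(start + len, chrom_len))
  df[order(df$start, df$end), , drop = FALSE]
}

# per-base intersection oracle: overlap of [s1,e1) and [s2,e2) by counting
# shared bases
oracle_intersect <- function(a, b, min_overlap = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    bases_a <- seq(a$start[i], a$end[i] - 1)
    bases_b <- seq(b$start[j], b$end[j] - 1)
    ov <- length(intersect(bases_a, bases_b))
    if (ov >= min_overlap)
      out[[length(out) + 1]] <- data.frame(index_a = i, index_b = j,
                                           overlap_bp = ov)
  }
  if (!length(out))
    return(data.frame(index_a = integer(), index_b = integer(),
                      overlap_bp = numeric()))
  do.call(rbind, out)
}

# per-base label vector for one chromosome of a segmentation
oracle_base_labels <- function(segmentation, chrom, chrom_len) {
  v <- rep("unannotated", chrom_len)
  seg <- segmentation[segmentation$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(seg)))
    v[(seg$start[i] + 1):seg$end[i]] <- seg$state[i]
  v
}

oracle_coverage <- function(window, segmentation, chrom_len) {
  v <- oracle_base_labels(segmentation, window$chrom, chrom_len)
  tab <- table(v[(window$start + 1):window$end])
  setNames(as.numeric(tab), names(tab))
}

# independent predominant-state oracle; tie-break rank written out by hand:
# category order active > bivalent > polycomb > weak > heterochromatin >
# quiescent, lexicographic within category
oracle_state_rank <- c(
  EnhA = 1, EnhG = 2, TSSA = 3, Tx = 4,            # active
  EnhBiv = 5, TssBiv = 6,                          # bivalent
  ReprPC = 7,                                      # polycomb
  EnhW = 8, TSSFlnk = 9, TxWk = 10,                # weak
  Het = 11, `ZNF/Rpts` = 12,                       # heterochromatin
  Quies = 13)

oracle_region_state <- function(region, segmentation, chrom_len) {
  v <- oracle_base_labels(segmentation, region$chrom, chrom_len)
  bases <- v[(region$start + 1):region$end]
  tab <- table(bases[bases != "unannotated"])
  if (length(tab) == 0) return(list(state = "unannotated", fraction = 1))
  cnt <- as.numeric(tab)
  lab <- names(tab)
  ord <- order(-cnt, oracle_state_rank[lab])
  list(state = lab[ord[1]],
       fraction = cnt[ord[1]] / (region$end - region$start))
}

# exhaustive per-peak annotation oracle applying the priority rules
oracle_annotate <- function(peak, genes, tss_window = 3000,
                            downstream_window = 3000) {
  overlaps <- function(s1, e1, s2, e2) min(e1, e2) - max(s1, s2) >= 1
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != peak$chrom) next
    if (overlaps(peak$start, peak$end,
                 max(g$tss - tss_window, 0), g$tss + tss_window + 1))
      return("promoter")
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != peak$chrom) next
    if (overlaps(peak$start, peak$end, g$start, g$end))
      return("intragenic")
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != peak$chrom) next
    ds <- if (g$strand == "+") c(g$end, g$end + downstream_window)
    else c(max(g$start - downstream_window, 0), g$start)
    if (ds[2] > ds[1] && overlaps(peak$start, peak$end, ds[1], ds[2]))
      return("downstream")
  }
  "distal_intergenic"
}

# per-base presence oracle for dynamics: merged regions are maximal runs of
# union coverage; presence = >= min_overlap covered bases per stage
oracle_dynamics_presence <- function(merged, peaksets, min_overlap = 1) {
  sapply(names(peaksets), function(s) {
    pk <- peaksets[[s]]
    vapply(seq_len(nrow(merged)), function(i) {
      m <- merged[i, ]
      pk_c <- pk[pk$chrom == m$chrom, , drop = FALSE]
      cov <- rep(FALSE, m$end - m$start)
      for (j in seq_len(nrow(pk_c))) {
        lo <- max(pk_c$start[j], m$start)
        hi <- min(pk_c$end[j], m$end)
        if (hi > lo) cov[(lo - m$start + 1):(hi - m$start)] <- TRUE
      }
      as.integer(sum(cov) >= min_overlap)
    }, 0L)
  })
}

# best-permutation matching of fitted states to true states (small K)
match_states <- function(emission_fit, emission_true) {
  K <- nrow(emission_true)
  perms <- gtools_permutations(K)
  best <- NULL
  best_err <- Inf
  for (r in seq_len(nrow(perms))) {
    pm <- perms[r, ]
    err <- max(abs(emission_fit[pm, , drop = FALSE] - emission_true))
    if (err < best_err) {
      best_err <- err
      best <- pm
    }
  }
  list(perm = best, max_abs_err = best_err)
}

gtools_permutations <- function(K) {
  if (K == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(K - 1)
  out <- NULL
  for (i in seq_len(K)) {
    rest <- seq_len(K)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

f1_score <- function(called, truth) {
  tp <- length(intersect(called, truth))
  if (tp == 0) return(0)
  prec <- tp / length(called)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}

random_segmentation <- function(chrom_len, labels = chrom_states_13(),
                                mean_run = 2000, chrom = "chr1") {
  pos <- 0
  runs <- list()
  while (pos < chrom_len) {
    len <- min(max(200, rgeom(1, 1 / mean_run)), chrom_len - pos)
    runs[[length(runs) + 1]] <- data.frame(
      chrom = chrom, start = pos, end = pos + len,
      state = sample(labels, 1))
    pos <- pos + len
  }
  seg <- do.call(rbind, runs)
  attr(seg, "label_vocabulary") <- labels
  seg
}
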