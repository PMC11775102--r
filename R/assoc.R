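## Region-overlap permutation association: observed overlap statistic,
## empirical p with the +1 permutation correction, z-score, and the
## normalized z-score nz = z / sqrt(|A|) that makes multi-set association
## matrices comparable.

## merged, sorted B boundaries per chromosome for fast overlap queries
prep_subject <- function(B) {
  out <- list()
  for (chr in unique(B$chrom)) {
    b <- B[B$chrom == chr, , drop = FALSE]
    gr <- GenomicRanges::reduce(as_granges0(b))
    bs <- GenomicRanges::start(gr) - 1L
    be <- GenomicRanges::end(gr)
    o <- order(bs)
    out[[chr]] <- list(bs = bs[o], be = be[o],
                       cumlen = cumsum((be - bs)[o]))
  }
  out
}

## does [s,e) overlap any merged subject interval? vectorized, integer-safe
overlaps_any <- function(s, e, sub) {
  if (is.null(sub)) return(rep(FALSE, length(s)))
  findInterval(e - 1, sub$bs) > findInterval(s, sub$be)
}

## total subject bp in [0, x)
cum_cov <- function(x, sub) {
  idx <- findInterval(x - 1, sub$bs)  # intervals starting before x
  ifelse(idx > 0,
         sub$cumlen[pmax(idx, 1)] - pmax(sub$be[pmax(idx, 1)] - x, 0),
         0)
}

## bp overlap of [s,e) with merged subject
bp_overlap <- function(s, e, sub) {
  if (is.null(sub)) return(rep(0, length(s)))
  cum_cov(e, sub) - cum_cov(s, sub)
}

## statistic over one layout: region count (>=1 bp) or total bp
assoc_stat <- function(s, e, chrom_index, subs, statistic) {
  tot <- 0
  for (ci in seq_along(subs)) {
    sel <- chrom_index == ci
    if (!any(sel)) next
    if (statistic == "count")
      tot <- tot + sum(overlaps_any(s[sel], e[sel], subs[[ci]]))
    else
      tot <- tot + sum(bp_overlap(s[sel], e[sel], subs[[ci]]))
  }
  tot
}

#' Permutation test of association between two region sets
#'
#' The observed statistic is the number of `A` regions overlapping at least
#' one `B` region (or the total overlap bp with `statistic = "bp"`). The
#' null is built by randomizing `A`: `"circular"` applies one random shift
#' per chromosome (wrapping around the chromosome end), preserving the
#' per-chromosome region count, length multiset and inter-region spacing;
#' `"random_regions"` re-places each region uniformly on its chromosome,
#' preserving lengths and avoiding `mask` when given. The empirical p-value
#' carries the +1 correction, `p = (1 + #\{perm >= obs\}) / (n_perm + 1)`,
#' so it cannot fall below `1/(n_perm+1)`. `z = (obs - mean)/sd` over
#' permutations and `nz = z / sqrt(|A|)`. Results are deterministic given
#' `seed`.
#'
#' @param A,B peak data.frames (`chrom`, `start`, `end`).
#' @param assembly a [genome_assembly()] covering both sets.
#' @param n_perm number of permutations (default 10000, minimum 100).
#' @param strategy `"circular"` (default) or `"random_regions"`.
#' @param mask optional data.frame of regions the randomization must avoid
#'   (`random_regions` only).
#' @param seed integer seed.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param statistic `"count"` (default) or `"bp"`.
#' @return object of class `assoc_result`: list with `observed`,
#'   `perm_mean`, `perm_sd`, `z`, `nz`, `p`, `n_perm`, `n_regions_a`,
#'   `strategy`, `alternative`, `seed`, `perm_stats`.
#' @export
permutation_association <- function(A, B, assembly, n_perm = 10000,
                                    strategy = c("circular",
                                                 "random_regions"),
                                    mask = NULL, seed = 1,
                                    alternative = c("greater", "less",
                                                    "two.sided"),
                                    statistic = c("count", "bp")) {
  strategy <- match.arg(strategy)
  alternative <- match.arg(alternative)
  statistic <- match.arg(statistic)
  if (n_perm < 100) stop("n_perm must be >= 100")
  check_intervals(A, assembly, "A region")
  check_intervals(B, assembly, "B region")
  chroms <- names(assembly)
  subs_all <- prep_subject(B)
  subs <- lapply(chroms, function(ch) subs_all[[ch]])
  mask_subs <- if (!is.null(mask)) {
    ms <- prep_subject(mask)
    lapply(chroms, function(ch) ms[[ch]])
  } else NULL
  ci <- match(A$chrom, chroms)
  s <- A$start
  e <- A$end
  len <- e - s
  L <- as.numeric(assembly)
  observed <- assoc_stat(s, e, ci, subs, statistic)
  nA <- nrow(A)
  perm_stats <- with_seed(seed, {
    ps <- numeric(n_perm)
    if (strategy == "circular") {
      for (p in seq_len(n_perm)) {
        d <- floor(runif(length(chroms)) * L)
        s2 <- (s + d[ci]) %% L[ci]
        e2 <- s2 + len
        wrap <- e2 > L[ci]
        tot <- assoc_stat(s2[!wrap], e2[!wrap], ci[!wrap], subs, statistic)
        if (any(wrap)) {
          wi <- which(wrap)
          if (statistic == "count") {
            ov1 <- logical(length(wi)); ov2 <- logical(length(wi))
            for (k in seq_along(wi)) {
              i <- wi[k]
              sub <- subs[[ci[i]]]
              ov1[k] <- overlaps_any(s2[i], L[ci[i]], sub)
              ov2[k] <- overlaps_any(0, e2[i] - L[ci[i]], sub)
            }
            tot <- tot + sum(ov1 | ov2)
          } else {
            for (k in seq_along(wi)) {
              i <- wi[k]
              sub <- subs[[ci[i]]]
              tot <- tot + bp_overlap(s2[i], L[ci[i]], sub) +
                bp_overlap(0, e2[i] - L[ci[i]], sub)
            }
          }
        }
        ps[p] <- tot
      }
    } else {
      maxs <- L[ci] - len
      for (p in seq_len(n_perm)) {
        s2 <- floor(runif(nA) * (maxs + 1))
        if (!is.null(mask_subs)) {
          for (tries in 1:50) {
            bad <- rep(FALSE, nA)
            for (cix in unique(ci)) {
              sel <- ci == cix
              bad[sel] <- overlaps_any(s2[sel], s2[sel] + len[sel],
                                       mask_subs[[cix]])
            }
            if (!any(bad)) break
            s2[bad] <- floor(runif(sum(bad)) * (maxs[bad] + 1))
          }
        }
        ps[p] <- assoc_stat(s2, s2 + len, ci, subs, statistic)
      }
    }
    ps
  })
  perm_mean <- mean(perm_stats)
  perm_sd <- sd(perm_stats)
  z <- if (perm_sd > 0) (observed - perm_mean) / perm_sd else NA_real_
  nz <- if (!is.na(z)) z / sqrt(nA) else NA_real_
  p_greater <- (1 + sum(perm_stats >= observed)) / (n_perm + 1)
  p_less <- (1 + sum(perm_stats <= observed)) / (n_perm + 1)
  p <- switch(alternative,
              greater = p_greater,
              less = p_less,
              two.sided = min(1, 2 * min(p_greater, p_less)))
  structure(list(observed = observed, perm_mean = perm_mean,
                 perm_sd = perm_sd, z = z, nz = nz, p = p,
                 n_perm = n_perm, n_regions_a = nA, strategy = strategy,
                 alternative = alternative, statistic = statistic,
                 seed = seed, perm_stats = perm_stats),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("Region-overlap permutation test (", x$strategy, ", ",
      x$n_perm, " permutations)\n", sep = "")
  cat("observed:", x$observed, " null:", round(x$perm_mean, 2), "+/-",
      round(x$perm_sd, 2), "\n")
  cat("z:", round(x$z, 3), " nz:", round(x$nz, 4), " p:",
      format(x$p, digits = 4), "(", x$alternative, ")\n")
  invisible(x)
}

#' Pairwise association matrix over multiple region sets
#'
#' Runs [permutation_association()] for every ordered pair (including the
#' diagonal self-association), with a seed stream derived from `seed`, and
#' BH-adjusts the p-values across the matrix for significance flags.
#'
#' @param sets named list of peak data.frames (unique labels).
#' @param assembly a [genome_assembly()].
#' @inheritParams permutation_association
#' @param p_cutoff significance cutoff on BH-adjusted p (default 0.05).
#' @return list with matrices `nz`, `z`, `p`, `fdr`, `significant`.
#' @export
association_matrix <- function(sets, assembly, n_perm = 1000,
                               strategy = "circular", seed = 1,
                               p_cutoff = 0.05) {
  labs <- names(sets)
  if (is.null(labs) || anyDuplicated(labs))
    stop("sets must carry unique labels")
  if (length(sets) < 2) stop("need >= 2 sets")
  n <- length(sets)
  nz <- z <- p <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- permutation_association(sets[[i]], sets[[j]], assembly,
                                 n_perm = n_perm, strategy = strategy,
                                 seed = seed + (i - 1) * n + (j - 1))
    nz[i, j] <- r$nz
    z[i, j] <- r$z
    p[i, j] <- r$p
  }
  fdr <- matrix(p.adjust(p, "BH"), n, n, dimnames = dimnames(p))
  list(nz = nz, z = z, p = p, fdr = fdr,
       significant = fdr < p_cutoff)
}
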