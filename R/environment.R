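## Chromatin-environment integration: predominant promoter states,
## mark-stratified regions, enhancer classification, gene linking within
## 100 kb, linked-gene expression, and gene-level mark categories.

ENHANCER_CLASSES <- c("EnhA", "EnhG", "EnhW", "EnhBiv")

#' Assign the predominant chromatin state of regions
#'
#' For each region, the state covering the most bp wins
#' (`coverage_fraction` = its bp / region length). Ties are broken by a
#' fixed state-priority list — category order active > bivalent > polycomb >
#' weak > heterochromatin > quiescent, then lexicographic — so results are
#' deterministic. Uncovered bp compete only when a region is entirely
#' unannotated, in which case the state is `"unannotated"`. The runner-up
#' state and its fraction are reported as an ambiguity check.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param segmentation data.frame with `chrom`, `start`, `end`, `state`.
#' @return data.frame with `state`, `coverage_fraction`, `second_state`,
#'   `second_fraction` (one row per region).
#' @export
assign_region_state <- function(regions, segmentation) {
  n <- nrow(regions)
  out <- data.frame(state = character(n), coverage_fraction = numeric(n),
                    second_state = NA_character_,
                    second_fraction = numeric(n), stringsAsFactors = FALSE)
  if (n == 0) return(out)
  hits <- interval_intersect(regions, segmentation, min_overlap = 1)
  if (nrow(hits)) {
    hits$state <- segmentation$state[hits$index_b]
    agg <- stats::aggregate(overlap_bp ~ index_a + state, data = hits, sum)
  } else {
    agg <- data.frame(index_a = integer(), state = character(),
                      overlap_bp = numeric())
  }
  len <- regions$end - regions$start
  for (i in seq_len(n)) {
    rows <- agg[agg$index_a == i, , drop = FALSE]
    if (nrow(rows) == 0) {
      out$state[i] <- "unannotated"
      out$coverage_fraction[i] <- 1
      next
    }
    pr <- state_priority_rank(rows$state)
    ord <- order(-rows$overlap_bp, pr)
    out$state[i] <- rows$state[ord[1]]
    out$coverage_fraction[i] <- rows$overlap_bp[ord[1]] / len[i]
    if (nrow(rows) > 1) {
      out$second_state[i] <- rows$state[ord[2]]
      out$second_fraction[i] <- rows$overlap_bp[ord[2]] / len[i]
    }
  }
  out
}

#' Promoter chromatin environment per gene
#'
#' Applies [assign_region_state()] to the TSS +/- `window` bp region of each
#' gene (clipped at chromosome ends when an assembly is given).
#'
#' @param genes gene models data.frame.
#' @param segmentation segmentation data.frame.
#' @param window half-width of the promoter window in bp (default 3000).
#' @param assembly optional [genome_assembly()] for clipping.
#' @return data.frame with `gene_id`, `predominant_state`,
#'   `coverage_fraction`, `second_state`, `second_fraction`.
#' @export
gene_promoter_environment <- function(genes, segmentation, window = 3000,
                                      assembly = NULL) {
  regions <- data.frame(chrom = genes$chrom,
                        start = pmax(genes$tss - window, 0),
                        end = genes$tss + window + 1,
                        stringsAsFactors = FALSE)
  if (!is.null(assembly))
    regions$end <- pmin(regions$end, unname(assembly[regions$chrom]))
  st <- assign_region_state(regions, segmentation)
  data.frame(gene_id = genes$gene_id, predominant_state = st$state,
             coverage_fraction = st$coverage_fraction,
             second_state = st$second_state,
             second_fraction = st$second_fraction,
             stringsAsFactors = FALSE)
}

#' Partition regions by presence of a histone mark
#'
#' A region is `"+"` when it overlaps any mark peak by at least
#' `min_overlap` bp, `"-"` otherwise. When the regions carry a `state`
#' column, the per-state proportions of the two groups are contrasted with
#' one chi-square test per state (state vs rest, + vs -), BH-adjusted.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally
#'   `state`.
#' @param mark_peaks data.frame of peaks; empty -> everything `"-"`.
#' @param min_overlap minimum bp overlap (default 1).
#' @return list with `status` (character vector "+"/"-") and `contrast`
#'   (data.frame per state with counts, proportions, `p`, `fdr`;
#'   `NULL` when regions carry no `state` column).
#' @export
split_regions_by_mark <- function(regions, mark_peaks, min_overlap = 1) {
  status <- rep("-", nrow(regions))
  if (!is.null(mark_peaks) && nrow(mark_peaks) > 0) {
    hits <- interval_intersect(regions, mark_peaks, min_overlap)
    status[unique(hits$index_a)] <- "+"
  }
  contrast <- NULL
  if (!is.null(regions$state)) {
    states <- sort(unique(regions$state))
    pos <- status == "+"
    contrast <- do.call(rbind, lapply(states, function(s) {
      tab <- table(factor(regions$state == s, c(FALSE, TRUE)),
                   factor(status, c("-", "+")))
      p <- if (any(tab == 0) || any(suppressWarnings(
        chisq.test(tab)$expected) < 5))
        fisher.test(tab)$p.value
      else suppressWarnings(chisq.test(tab)$p.value)
      data.frame(state = s,
                 n_pos = sum(regions$state == s & pos),
                 n_neg = sum(regions$state == s & !pos),
                 prop_pos = if (any(pos)) mean(regions$state[pos] == s)
                 else NA_real_,
                 prop_neg = if (any(!pos)) mean(regions$state[!pos] == s)
                 else NA_real_,
                 p = p, stringsAsFactors = FALSE)
    }))
    contrast$fdr <- p.adjust(contrast$p, "BH")
  }
  list(status = status, contrast = contrast)
}

#' Classify enhancer regions from a segmentation
#'
#' Maximal runs of the enhancer states (EnhA, EnhG, EnhW, EnhBiv) become
#' enhancer records. When mark peaks are given, each record is labelled
#' `"+"`/`"-"` for the mark via [split_regions_by_mark()].
#'
#' @param segmentation pooled (13-state vocabulary) segmentation.
#' @param mark_peaks optional peak data.frame (e.g. H3K79me2 peaks).
#' @param min_overlap minimum bp overlap for mark presence (default 1).
#' @return data.frame with `enhancer_id`, `chrom`, `start`, `end`, `class`
#'   and (when peaks were given) `h3k79me2`.
#' @export
classify_enhancers <- function(segmentation, mark_peaks = NULL,
                               min_overlap = 1) {
  vocab <- attr(segmentation, "label_vocabulary")
  if (is.null(vocab)) vocab <- unique(segmentation$state)
  if (!any(ENHANCER_CLASSES %in% vocab))
    stop("segmentation vocabulary has no enhancer states")
  enh <- segmentation[segmentation$state %in% ENHANCER_CLASSES, ,
                      drop = FALSE]
  enh <- data.frame(enhancer_id = if (nrow(enh)) paste0("enh", seq_len(nrow(enh)))
                    else character(),
                    chrom = enh$chrom, start = enh$start, end = enh$end,
                    class = enh$state, stringsAsFactors = FALSE)
  rownames(enh) <- NULL
  if (!is.null(mark_peaks))
    enh$h3k79me2 <- split_regions_by_mark(enh, mark_peaks,
                                          min_overlap)$status
  enh
}

#' Link enhancers to genes within a distance limit
#'
#' Distance is 0 when the gene body overlaps the enhancer, otherwise the bp
#' gap to the nearer enhancer boundary. `mode = "nearest"` keeps the single
#' closest gene per enhancer (exact ties keep all tied genes, flagged);
#' `mode = "all"` keeps every gene within `max_dist`.
#'
#' @param enhancers data.frame from [classify_enhancers()].
#' @param genes gene models data.frame.
#' @param mode `"nearest"` or `"all"`.
#' @param max_dist maximum boundary-to-boundary distance in bp
#'   (default 100000, inclusive).
#' @return data.frame with `enhancer_id`, `gene_id`, `distance`, `tie`.
#' @export
link_enhancer_genes <- function(enhancers, genes,
                                mode = c("nearest", "all"),
                                max_dist = 100000) {
  mode <- match.arg(mode)
  out <- list()
  for (i in seq_len(nrow(enhancers))) {
    e <- enhancers[i, ]
    g <- genes[genes$chrom == e$chrom, , drop = FALSE]
    if (nrow(g) == 0) next
    gap <- pmax(g$start - e$end, e$start - g$end, 0)
    keep <- gap <= max_dist
    if (!any(keep)) next
    g <- g[keep, , drop = FALSE]
    gap <- gap[keep]
    if (mode == "nearest") {
      best <- gap == min(gap)
      out[[length(out) + 1]] <- data.frame(
        enhancer_id = e$enhancer_id, gene_id = g$gene_id[best],
        distance = gap[best], tie = sum(best) > 1,
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1]] <- data.frame(
        enhancer_id = e$enhancer_id, gene_id = g$gene_id,
        distance = gap, tie = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      distance = numeric(), tie = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Linked-gene expression by enhancer class and mark status
#'
#' Computes, per enhancer, the mean expression (cpm) of its linked genes,
#' then contrasts `"+"` vs `"-"` enhancers within each class with a
#' two-sided Wilcoxon rank-sum test, BH-adjusted across classes. Groups
#' with fewer than 2 enhancers give a missing p.
#'
#' @param enhancers data.frame with `enhancer_id`, `class`, `h3k79me2`.
#' @param links data.frame from [link_enhancer_genes()].
#' @param expression named numeric vector gene_id -> cpm.
#' @return list with `per_enhancer` (enhancer_id, class, h3k79me2,
#'   mean_cpm, n_genes) and `tests` (class, mean_pos, mean_neg, p, fdr).
#' @export
enhancer_expression <- function(enhancers, links, expression) {
  miss <- setdiff(links$gene_id, names(expression))
  if (length(miss))
    stop("expression missing for ", length(miss), " linked gene(s)")
  links$cpm <- unname(expression[links$gene_id])
  agg <- stats::aggregate(cpm ~ enhancer_id, data = links, mean)
  ngen <- stats::aggregate(cpm ~ enhancer_id, data = links, length)
  per <- data.frame(enhancer_id = enhancers$enhancer_id,
                    class = enhancers$class,
                    h3k79me2 = enhancers$h3k79me2,
                    mean_cpm = agg$cpm[match(enhancers$enhancer_id,
                                             agg$enhancer_id)],
                    n_genes = ngen$cpm[match(enhancers$enhancer_id,
                                             ngen$enhancer_id)],
                    stringsAsFactors = FALSE)
  per$n_genes[is.na(per$n_genes)] <- 0
  tests <- do.call(rbind, lapply(sort(unique(per$class)), function(cl) {
    xp <- per$mean_cpm[per$class == cl & per$h3k79me2 == "+" &
                         !is.na(per$mean_cpm)]
    xn <- per$mean_cpm[per$class == cl & per$h3k79me2 == "-" &
                         !is.na(per$mean_cpm)]
    p <- if (length(xp) >= 2 && length(xn) >= 2)
      suppressWarnings(wilcox.test(xp, xn, correct = TRUE)$p.value)
    else NA_real_
    if (isTRUE(is.nan(p))) p <- 1  # fully tied groups: no shift evidence
    data.frame(class = cl,
               n_pos = length(xp), n_neg = length(xn),
               mean_pos = if (length(xp)) mean(xp) else NA_real_,
               mean_neg = if (length(xn)) mean(xn) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  }))
  tests$fdr <- p.adjust(tests$p, "BH")
  list(per_enhancer = per, tests = tests)
}

#' Gene-level mark category: gene body, enhancer, both, or neither
#'
#' A gene is `GB` when its body overlaps a mark peak by >= 1 bp, `ENH` when
#' any linked enhancer is mark-positive, `GB-ENH` when both hold and
#' `none` otherwise; the four labels partition the gene set. When DE
#' classes are given, the category-by-class contingency is tested
#' (chi-square, or Fisher when expected counts fall below 5).
#'
#' @param genes gene models data.frame.
#' @param mark_peaks data.frame of mark peaks.
#' @param enhancers data.frame with `enhancer_id`, `h3k79me2`.
#' @param links data.frame from [link_enhancer_genes()].
#' @param de_status optional named vector gene_id -> {up, down, not}.
#' @return list with `category` (named character vector per gene) and,
#'   when `de_status` is given, `contrast` (table + `p` + `method`).
#' @export
h3k79_gene_category <- function(genes, mark_peaks, enhancers, links,
                                de_status = NULL) {
  gb <- rep(FALSE, nrow(genes))
  if (!is.null(mark_peaks) && nrow(mark_peaks) > 0) {
    hits <- interval_intersect(genes[, c("chrom", "start", "end")],
                               mark_peaks, min_overlap = 1)
    gb[unique(hits$index_a)] <- TRUE
  }
  pos_enh <- enhancers$enhancer_id[enhancers$h3k79me2 == "+"]
  enh_genes <- unique(links$gene_id[links$enhancer_id %in% pos_enh])
  enh <- genes$gene_id %in% enh_genes
  category <- ifelse(gb & enh, "GB-ENH",
                     ifelse(gb, "GB", ifelse(enh, "ENH", "none")))
  names(category) <- genes$gene_id
  out <- list(category = category)
  if (!is.null(de_status)) {
    common <- intersect(names(de_status), names(category))
    tab <- table(category[common], de_status[common])
    method <- "chisq"
    exp_ok <- tryCatch(all(suppressWarnings(chisq.test(tab)$expected) >= 5),
                       error = function(e) FALSE)
    p <- if (exp_ok) suppressWarnings(chisq.test(tab)$p.value)
    else fisher.test(tab, simulate.p.value = TRUE, B = 1e4)$p.value
    if (!exp_ok) method <- "fisher_sim"
    out$contrast <- list(table = tab, p = p, method = method)
  }
  out
}
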