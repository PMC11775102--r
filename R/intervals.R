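## Interval I/O and algebra. Peaks and regions are plain data.frames with
## columns chrom, start, end (0-based half-open) plus optional name/score;
## GRanges is used internally for overlap machinery.

#' Read a BED file of peaks or regions
#'
#' Reads 3+ column tab-separated BED (no header). Intervals are validated
#' against the assembly and returned sorted by (chrom, start, end); a name
#' column (4th) and score column (5th) are kept when present. Overlapping
#' input lines are preserved as-is: the reader never merges.
#'
#' @param path BED file path.
#' @param assembly a [genome_assembly()].
#' @param label optional label stored as the `"label"` attribute
#'   (e.g. mark name + stage).
#' @param lenient if `TRUE`, lines on chromosomes absent from the assembly
#'   are skipped with a warning instead of raising an error.
#' @return data.frame with columns `chrom`, `start`, `end` and, if present in
#'   the file, `name` and `score`.
#' @export
read_bed <- function(path, assembly, label = NULL, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric())
    attr(df, "label") <- label
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-integer coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": requires 0 <= start < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (min(nf) >= 4) df$name <- vapply(fields, `[[`, "", 4L)
  if (min(nf) >= 5) {
    df$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    if (anyNA(df$score))
      stop("malformed BED line ", which(is.na(df$score))[1],
           ": non-numeric score")
  }
  missing_chrom <- !(df$chrom %in% names(assembly))
  if (any(missing_chrom)) {
    if (lenient) {
      warning("skipping ", sum(missing_chrom),
              " line(s) on chromosome(s) absent from assembly: ",
              paste(unique(df$chrom[missing_chrom]), collapse = ", "))
      df <- df[!missing_chrom, , drop = FALSE]
    } else {
      stop("BED line ", which(missing_chrom)[1], ": chromosome '",
           df$chrom[which(missing_chrom)[1]], "' not in assembly")
    }
  }
  check_intervals(df, assembly, "BED interval")
  df <- df[interval_order(df, assembly), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "label") <- label
  df
}

#' Write intervals as BED
#'
#' Canonical 3-column (chrom, start, end) or 5-column
#' (chrom, start, end, name, score) tab-separated output with no header.
#' `read_bed()` followed by `write_bed()` round-trips such files
#' byte-identically.
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  if (!is.null(df$name) && !is.null(df$score)) cols <- c(cols, "name", "score")
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  if (!is.null(out$score))
    out$score <- format(out$score, scientific = FALSE, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## biotype lookup: Gencode gene_type values -> the six-group scheme.
## Unmapped values become "other" (counted in the reader's report).
biotype_groups <- function() {
  list(
    `IG-TR` = c("IG_C_gene", "IG_D_gene", "IG_J_gene", "IG_V_gene",
                "IG_LV_gene", "IG_pseudogene", "IG_C_pseudogene",
                "IG_J_pseudogene", "IG_V_pseudogene", "IG_D_pseudogene",
                "TR_C_gene", "TR_D_gene", "TR_J_gene", "TR_V_gene",
                "TR_J_pseudogene", "TR_V_pseudogene"),
    protein_coding = c("protein_coding"),
    pseudogene = c("pseudogene", "processed_pseudogene",
                   "unprocessed_pseudogene",
                   "transcribed_processed_pseudogene",
                   "transcribed_unprocessed_pseudogene",
                   "transcribed_unitary_pseudogene", "unitary_pseudogene",
                   "translated_processed_pseudogene",
                   "translated_unprocessed_pseudogene",
                   "polymorphic_pseudogene"),
    lncRNA = c("lncRNA", "lincRNA", "antisense", "sense_intronic",
               "sense_overlapping", "processed_transcript", "TEC",
               "bidirectional_promoter_lncRNA", "3prime_overlapping_ncRNA",
               "macro_lncRNA"),
    mtRNA = c("Mt_rRNA", "Mt_tRNA"),
    snoRNA = c("snoRNA", "scaRNA")
  )
}

map_biotype <- function(gene_type) {
  groups <- biotype_groups()
  out <- rep("other", length(gene_type))
  for (g in names(groups)) out[gene_type %in% groups[[g]]] <- g
  out
}

#' Read gene models from a GTF file
#'
#' Imports gene-level records from a Gencode-dialect GTF, converts the
#' 1-based inclusive coordinates to 0-based half-open, computes the
#' strand-aware TSS, and maps `gene_type` to six annotation groups
#' (IG-TR, protein_coding, pseudogene, lncRNA, mtRNA, snoRNA); unmapped
#' biotypes are labelled `"other"` and counted in the `"biotype_report"`
#' attribute.
#'
#' @param path GTF path.
#' @param assembly a [genome_assembly()].
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `length`, `biotype`, `gene_type`.
#' @export
read_gene_models <- function(path, assembly) {
  gtf <- rtracklayer::import(path, format = "gtf")
  gtf <- gtf[gtf$type == "gene"]
  if (length(gtf) == 0) stop("no gene records in ", path)
  if (is.null(gtf$gene_id) || anyNA(gtf$gene_id))
    stop("gene record missing gene_id attribute")
  if (anyDuplicated(gtf$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(gtf$gene_id[duplicated(gtf$gene_id)]), collapse = ", "))
  gene_type <- if (!is.null(gtf$gene_type)) gtf$gene_type else
    rep(NA_character_, length(gtf))
  df <- data.frame(
    gene_id = gtf$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gtf)),
    start = GenomicRanges::start(gtf) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gtf),
    strand = as.character(GenomicRanges::strand(gtf)),
    stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-")))
    stop("gene records must be stranded (+/-)")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$length <- df$end - df$start
  df$biotype <- map_biotype(gene_type)
  df$gene_type <- gene_type
  check_intervals(df, assembly, "gene")
  df <- df[interval_order(df, assembly), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "biotype_report") <- table(df$biotype)
  df
}

#' Intersect two interval sets
#'
#' Reports every pair of intervals from `a` and `b` whose overlap is at
#' least `min_overlap` bp, with the overlap width
#' `min(end) - max(start)`. Half-open coordinates: `[0,10)` and `[10,20)`
#' do not overlap.
#'
#' @param a,b data.frames with `chrom`, `start`, `end` (0-based half-open).
#' @param min_overlap minimum overlap in bp (>= 1).
#' @return data.frame with columns `index_a`, `index_b`, `overlap_bp`.
#' @export
interval_intersect <- function(a, b, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(index_a = integer(), index_b = integer(),
                      overlap_bp = numeric()))
  hits <- GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b),
                                      minoverlap = min_overlap)
  ia <- S4Vectors::queryHits(hits)
  ib <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  data.frame(index_a = ia, index_b = ib, overlap_bp = ov)
}

#' Per-state coverage of a window by a segmentation
#'
#' Sums, for one window, the bp covered by each segmentation state.
#' Uncovered bp are reported under the reserved label `"unannotated"`.
#' The values always sum to the (clipped) window length. Windows extending
#' past the chromosome end are clipped with a warning.
#'
#' @param window list or one-row data.frame with `chrom`, `start`, `end`.
#' @param segmentation data.frame with `chrom`, `start`, `end`, `state`.
#' @param assembly optional [genome_assembly()] used for clipping.
#' @return named numeric vector of bp per state label.
#' @export
coverage_by_label <- function(window, segmentation, assembly = NULL) {
  chrom <- window$chrom[1]
  ws <- window$start[1]
  we <- window$end[1]
  if (!is.null(assembly)) {
    L <- unname(assembly[chrom])
    if (is.na(L)) stop("window chromosome '", chrom, "' not in assembly")
    if (ws < 0 || we > L) {
      warning("window clipped to chromosome bounds")
      ws <- max(ws, 0)
      we <- min(we, L)
    }
  }
  seg <- segmentation[segmentation$chrom == chrom &
                        segmentation$end > ws &
                        segmentation$start < we, , drop = FALSE]
  bp <- pmin(seg$end, we) - pmax(seg$start, ws)
  out <- tapply(bp, seg$state, sum)
  out <- setNames(as.numeric(out), names(out))
  covered <- sum(out)
  if (covered < we - ws) out <- c(out, unannotated = we - ws - covered)
  out
}
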