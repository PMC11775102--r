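## Genome assembly: the coordinate frame every region operation validates
## against. Internally a named integer vector of chromosome lengths.

#' Define a genome assembly
#'
#' An assembly is the ordered set of chromosome names and lengths against
#' which all intervals are validated.
#'
#' @param chromosomes character vector of unique chromosome names.
#' @param lengths integer vector of chromosome lengths in bp (>= 1).
#' @return A `genome_assembly` object (named integer vector of lengths).
#' @examples
#' genome_assembly(c("chr1", "chrX"), c(1e6, 5e5))
#' @export
genome_assembly <- function(chromosomes, lengths) {
  chromosomes <- as.character(chromosomes)
  if (anyDuplicated(chromosomes))
    stop("duplicate chromosome names: ",
         paste(unique(chromosomes[duplicated(chromosomes)]), collapse = ", "))
  lengths <- as.numeric(lengths)
  if (length(lengths) != length(chromosomes))
    stop("chromosomes and lengths differ in length")
  if (any(is.na(lengths)) || any(lengths < 1) || any(lengths != floor(lengths)))
    stop("chromosome lengths must be positive integers")
  structure(setNames(lengths, chromosomes), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("genome_assembly:", length(x), "chromosomes,",
      format(sum(x), big.mark = ","), "bp\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Read an assembly from a two-column chrom-sizes file
#'
#' @param path path to a tab-separated file with columns chromosome, length.
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  genome_assembly(df$chrom, df$length)
}

#' Write an assembly as a chrom-sizes file
#' @param assembly a [genome_assembly()].
#' @param path output path.
#' @export
write_chrom_sizes <- function(assembly, path) {
  write.table(data.frame(names(assembly), as.numeric(assembly)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## internal: validate a (chrom,start,end) frame against an assembly
check_intervals <- function(df, assembly, what = "interval") {
  bad <- !(df$chrom %in% names(assembly))
  if (any(bad))
    stop(what, " on chromosome(s) absent from assembly: ",
         paste(unique(df$chrom[bad]), collapse = ", "))
  if (any(df$start < 0) || any(df$start >= df$end))
    stop(what, "s must satisfy 0 <= start < end")
  lens <- unname(assembly[df$chrom])
  if (any(df$end > lens))
    stop(what, " end exceeds chromosome length")
  invisible(df)
}

## internal: 0-based half-open data.frame -> GRanges (1-based inclusive)
as_granges0 <- function(df, assembly = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
  gr
}

## internal: order (chrom in assembly order, start, end)
interval_order <- function(df, assembly) {
  chrom_rank <- match(df$chrom, names(assembly))
  order(chrom_rank, df$start, df$end)
}
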