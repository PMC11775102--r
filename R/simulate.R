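## Synthetic-data generators with planted ground truth for every pipeline
## stage. Every generator is deterministic given (arguments, seed).

#' Default toy genome: two autosomes plus sex chromosomes
#' @return a [genome_assembly()].
#' @export
default_assembly <- function() {
  genome_assembly(c("chr1", "chr2", "chrX", "chrY"),
                  c(5e6, 5e6, 3e6, 1e6))
}

## place n non-overlapping intervals of given lengths on [0, L); returns
## starts or NULL when capacity is exhausted
place_nonoverlapping <- function(lengths, L, existing_start = numeric(0),
                                 existing_end = numeric(0),
                                 max_attempts = 1000) {
  starts <- numeric(length(lengths))
  s_sorted <- existing_start
  e_sorted <- existing_end
  o <- order(s_sorted)
  s_sorted <- s_sorted[o]
  e_sorted <- e_sorted[o]
  ## longest first: large intervals need open space before gaps fragment
  for (i in order(lengths, decreasing = TRUE)) {
    len <- lengths[i]
    if (len >= L) return(NULL)
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      st <- floor(runif(1) * (L - len))
      en <- st + len
      ## overlap iff any existing with start < en and end > st
      if (findInterval(en - 1, s_sorted) == findInterval(st, e_sorted)) {
        ins <- findInterval(st, s_sorted)
        s_sorted <- append(s_sorted, st, after = ins)
        e_sorted <- append(e_sorted, en, after = ins)
        starts[i] <- st
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  starts
}

#' Simulate a genome annotation with non-overlapping genes
#'
#' Genes are assigned to chromosomes proportionally to length, placed
#' without overlap on random strands, with log-normal lengths and biotypes
#' drawn from a realistic mixture (protein_coding-dominated).
#'
#' @param assembly a [genome_assembly()] (chromosome lengths >= 50 kb).
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @param len_meanlog,len_sdlog log-normal gene-length parameters
#'   (default meanlog log(2000), sdlog 0.8).
#' @return gene models data.frame as from [read_gene_models()].
#' @export
simulate_genome <- function(assembly, n_genes, seed = 1,
                            len_meanlog = log(2000), len_sdlog = 0.8) {
  if (any(assembly < 5e4)) stop("chromosome lengths must be >= 50 kb")
  if (n_genes == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), tss = numeric(),
                      length = numeric(), biotype = character(),
                      gene_type = character()))
  with_seed(seed, {
    probs <- as.numeric(assembly) / sum(assembly)
    chrom <- sample(names(assembly), n_genes, replace = TRUE, prob = probs)
    lengths <- pmax(round(rlnorm(n_genes, len_meanlog, len_sdlog)), 200)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    bio_levels <- c("protein_coding", "lncRNA", "pseudogene", "snoRNA",
                    "IG-TR", "mtRNA")
    bio_raw <- c(protein_coding = "protein_coding", lncRNA = "lincRNA",
                 pseudogene = "processed_pseudogene", snoRNA = "snoRNA",
                 `IG-TR` = "IG_C_gene", mtRNA = "Mt_tRNA")
    biotype <- sample(bio_levels, n_genes, replace = TRUE,
                      prob = c(0.62, 0.2, 0.12, 0.03, 0.02, 0.01))
    start <- numeric(n_genes)
    for (chr in names(assembly)) {
      idx <- which(chrom == chr)
      if (!length(idx)) next
      st <- place_nonoverlapping(lengths[idx], unname(assembly[chr]))
      if (is.null(st))
        stop("gene demand exceeds genome capacity on ", chr)
      start[idx] <- st
    }
    df <- data.frame(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = chrom, start = start, end = start + lengths,
      strand = strand, stringsAsFactors = FALSE)
    df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
    df$length <- lengths
    df$biotype <- biotype
    df$gene_type <- unname(bio_raw[biotype])
    df <- df[interval_order(df, assembly), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Write gene models as a Gencode-dialect GTF
#' @param genes gene models data.frame.
#' @param path output path.
#' @export
write_genes_gtf <- function(genes, path) {
  lines <- sprintf(
    "%s\tchromdyn\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_type \"%s\";",
    genes$chrom, genes$start + 1, genes$end, genes$strand,
    genes$gene_id, genes$gene_type)
  writeLines(lines, path)
  invisible(path)
}

#' A plausible 13-state chromatin-state model over six histone marks
#'
#' Emission rows follow the conventional mark combinatorics (e.g. TSSA:
#' H3K4me3 + H3K27ac; Tx: H3K36me3; EnhA: H3K4me1 + H3K27ac; TssBiv:
#' H3K4me3 + H3K27me3; Quies: nothing), with sticky transitions and a
#' quiescent-heavy initial distribution.
#'
#' @param self_transition per-state self-transition probability
#'   (default 0.9).
#' @param bin_size bin width in bp.
#' @return a `state_hmm` from [state_model()].
#' @export
default_state_model <- function(self_transition = 0.9, bin_size = 200) {
  marks <- DEFAULT_MARKS
  states <- chrom_states_13()
  em <- matrix(0.03, length(states), length(marks),
               dimnames = list(states, marks))
  em["TSSA", c("H3K4me3", "H3K27ac", "H3K4me1")] <- c(0.9, 0.7, 0.3)
  em["TSSFlnk", c("H3K4me3", "H3K4me1")] <- c(0.5, 0.6)
  em["Tx", "H3K36me3"] <- 0.9
  em["TxWk", "H3K36me3"] <- 0.4
  em["EnhG", c("H3K4me1", "H3K36me3")] <- c(0.7, 0.6)
  em["EnhA", c("H3K4me1", "H3K27ac")] <- c(0.9, 0.8)
  em["EnhW", "H3K4me1"] <- 0.6
  em["ZNF/Rpts", c("H3K9me3", "H3K36me3")] <- c(0.6, 0.5)
  em["Het", "H3K9me3"] <- 0.9
  em["TssBiv", c("H3K4me3", "H3K27me3")] <- c(0.7, 0.7)
  em["EnhBiv", c("H3K4me1", "H3K27me3")] <- c(0.6, 0.6)
  em["ReprPC", "H3K27me3"] <- 0.8
  K <- length(states)
  rest <- 1 - self_transition
  trans <- matrix(0, K, K, dimnames = list(states, states))
  qi <- which(states == "Quies")
  for (i in seq_len(K)) {
    w <- rep(1, K)
    if (i != qi) w[qi] <- 4   # excursions usually return to quiescence
    w[i] <- 0
    trans[i, ] <- rest * w / sum(w)
    trans[i, i] <- self_transition
  }
  init <- rep(0.02, K)
  init[states == "Quies"] <- 1 - 0.02 * (K - 1)
  state_model(em, trans, init, bin_size = bin_size)
}

#' Simulate binarized tracks and their true segmentation
#'
#' Convenience wrapper around [simulate.state_hmm()].
#' @param model a `state_hmm`.
#' @param assembly a [genome_assembly()].
#' @param seed integer seed.
#' @return list with `tracks` and `truth` (segmentation data.frame).
#' @export
simulate_state_tracks <- function(model, assembly, seed = 1) {
  simulate(model, seed = seed, assembly = assembly)
}

## stage membership implied by a dynamics pattern label
pattern_stages <- function(pattern, stages) {
  if (pattern == "common") return(stages)
  if (endsWith(pattern, "-spe")) return(sub("-spe$", "", pattern))
  strsplit(pattern, "-", fixed = TRUE)[[1]]
}

#' Default presence-pattern probabilities for three stages
#' @param stages stage labels.
#' @return named numeric vector over the seven patterns, summing to 1.
#' @export
default_pattern_probs <- function(stages = c("GSC", "SCI", "RS")) {
  pats <- c("common",
            paste0(stages, "-spe"),
            paste(stages[1], stages[2], sep = "-"),
            paste(stages[2], stages[3], sep = "-"),
            paste(stages[1], stages[3], sep = "-"))
  p <- c(0.35, 0.15, 0.15, 0.15, 0.08, 0.08, 0.04)
  setNames(p, pats)
}

#' Simulate stage-resolved peak sets with planted dynamics patterns
#'
#' Base regions are placed by a Poisson process per chromosome (lengths
#' geometric, regions non-overlapping) and each region receives a presence
#' pattern with the configured probabilities; a stage's peak set contains
#' exactly the regions whose pattern includes that stage. Per-chromosome
#' multipliers allow planting rate biases (e.g. an X-chromosome excess of
#' one stage's specific regions).
#'
#' @param assembly a [genome_assembly()].
#' @param stages ordered stage labels (default GSC, SCI, RS).
#' @param rate_per_mb expected base regions per Mb (default 20).
#' @param pattern_probs named probabilities over presence patterns
#'   (default [default_pattern_probs()]).
#' @param mean_len mean region length in bp (default 1000, geometric).
#' @param chrom_pattern_multiplier optional matrix chromosomes x patterns of
#'   rate multipliers (default all 1).
#' @param seed integer seed.
#' @return list with `peaks` (named list of stage peak data.frames) and
#'   `truth` (regions with their pattern).
#' @export
simulate_peaks <- function(assembly, stages = c("GSC", "SCI", "RS"),
                           rate_per_mb = 20,
                           pattern_probs = default_pattern_probs(stages),
                           mean_len = 1000,
                           chrom_pattern_multiplier = NULL, seed = 1) {
  if (rate_per_mb <= 0) stop("rate_per_mb must be > 0")
  if (abs(sum(pattern_probs) - 1) > 1e-8)
    stop("pattern_probs must sum to 1")
  with_seed(seed, {
    regions <- list()
    for (chr in names(assembly)) {
      L <- unname(assembly[chr])
      ex_s <- numeric(0)
      ex_e <- numeric(0)
      for (pat in names(pattern_probs)) {
        mult <- 1
        if (!is.null(chrom_pattern_multiplier) &&
            chr %in% rownames(chrom_pattern_multiplier) &&
            pat %in% colnames(chrom_pattern_multiplier))
          mult <- chrom_pattern_multiplier[chr, pat]
        lambda <- rate_per_mb * (L / 1e6) * pattern_probs[[pat]] * mult
        n <- rpois(1, lambda)
        if (n == 0) next
        lens <- pmax(rgeom(n, 1 / mean_len) + 200, 200)
        st <- place_nonoverlapping(lens, L, ex_s, ex_e)
        if (is.null(st))
          stop("peak demand exceeds capacity on ", chr)
        o <- order(c(ex_s, st))
        ex_e <- c(ex_e, st + lens)[o]
        ex_s <- c(ex_s, st)[o]
        regions[[length(regions) + 1]] <- data.frame(
          chrom = chr, start = st, end = st + lens, pattern = pat,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, regions)
    truth <- truth[interval_order(truth, assembly), , drop = FALSE]
    rownames(truth) <- NULL
    peaks <- lapply(stages, function(s) {
      present <- vapply(truth$pattern, function(p)
        s %in% pattern_stages(p, stages), TRUE)
      df <- truth[present, c("chrom", "start", "end"), drop = FALSE]
      rownames(df) <- NULL
      df
    })
    names(peaks) <- stages
    list(peaks = peaks, truth = truth)
  })
}

#' Simulate a spike-in count matrix with planted effects
#'
#' Negative-binomial counts for a two-genotype design (CTL vs KO) with
#' genotype effects on the planted gene sets only, ERCC control rows that
#' carry no genotype effect by construction, and an optional planted
#' unwanted sample factor loading on every gene including the controls.
#'
#' @param genes gene models data.frame (ids become count rows).
#' @param n_per_group samples per genotype (default 3).
#' @param up_genes,down_genes character vectors of planted gene ids.
#' @param effect_log2fc planted |log2 fold change| (default 2).
#' @param base_meanlog,base_sdlog log-normal baseline mean parameters
#'   (default meanlog log(100), sdlog 1).
#' @param dispersion NB dispersion (default 0.1).
#' @param ercc_n number of ERCC control rows (default 92).
#' @param unwanted_strength scale of the planted unwanted factor in log2
#'   units (0 disables; default 0).
#' @param seed integer seed.
#' @return list with `counts` (matrix), `group` (factor), `control`
#'   (logical), `truth` (list: up, down, factor, loadings).
#' @export
simulate_counts <- function(genes, n_per_group = 3, up_genes = character(),
                            down_genes = character(), effect_log2fc = 2,
                            base_meanlog = log(100), base_sdlog = 1,
                            dispersion = 0.1, ercc_n = 92,
                            unwanted_strength = 0, seed = 1) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  with_seed(seed, {
    gene_ids <- genes$gene_id
    ercc_ids <- sprintf("ERCC-%04d", seq_len(ercc_n))
    ids <- c(gene_ids, ercc_ids)
    control <- c(rep(FALSE, length(gene_ids)), rep(TRUE, ercc_n))
    n <- 2 * n_per_group
    group <- factor(rep(c("CTL", "KO"), each = n_per_group),
                    levels = c("CTL", "KO"))
    samples <- paste0(group, rep(seq_len(n_per_group), 2))
    base <- rlnorm(length(ids), base_meanlog, base_sdlog)
    lfc <- setNames(rep(0, length(ids)), ids)
    lfc[up_genes] <- effect_log2fc
    lfc[down_genes] <- -effect_log2fc
    if (any(control & lfc != 0)) stop("control rows cannot carry effects")
    ## unwanted factor orthogonal to genotype: with 3 vs 3 samples a fully
    ## random factor can align with the genotype contrast by chance, in
    ## which case no normalization could separate the two; technical
    ## variation is modelled as genotype-independent
    raw <- rnorm(n)
    ko0 <- rep(c(0, 1), each = n_per_group)
    raw <- raw - mean(raw) - (ko0 - mean(ko0)) *
      sum(raw * (ko0 - mean(ko0))) / sum((ko0 - mean(ko0))^2)
    f <- as.numeric(scale(raw))
    loadings <- if (unwanted_strength > 0)
      rnorm(length(ids), unwanted_strength, unwanted_strength / 3)
    else rep(0, length(ids))
    ko <- as.numeric(group == "KO")
    log2mu <- log2(base) + outer(lfc, ko) + outer(loadings, f)
    mu <- 2^log2mu
    if (any(mu < 0)) stop("negative means")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow(mu), ncol(mu),
                     dimnames = list(ids, samples))
    list(counts = counts, group = group, control = control,
         truth = list(up = up_genes, down = down_genes, factor = f,
                      loadings = loadings, effect_log2fc = effect_log2fc,
                      dispersion = dispersion))
  })
}
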