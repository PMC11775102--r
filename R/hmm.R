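## Chromatin-state segmentation: product-Bernoulli hidden Markov model over
## fixed-width bins of binarized histone-mark presence calls, in the style of
## the widely used chromatin-state discovery tools. Chromosomes are treated
## as independent sequences sharing one initial distribution.

DEFAULT_MARKS <- c("H3K4me1", "H3K4me3", "H3K27ac",
                   "H3K27me3", "H3K36me3", "H3K9me3")

#' The 18-state and pooled 13-state chromatin-state vocabularies
#'
#' `chrom_states_18()` lists the full vocabulary; `chrom_states_13()` the
#' vocabulary after pooling (see [default_pooling_map()]).
#' @return character vector of state labels.
#' @export
chrom_states_18 <- function() {
  c("TSSA", "TSSFlnk", "TSSFlnkD", "Tx", "TxWk", "EnhG1", "EnhG2", "EnhA",
    "EnhW", "ZNF/Rpts", "Het", "TssBiv", "EnhBiv", "ReprPC", "ReprPCWk",
    "Quies1", "Quies2", "Quies3")
}

#' @rdname chrom_states_18
#' @export
chrom_states_13 <- function() {
  c("TSSA", "TSSFlnk", "Tx", "TxWk", "EnhG", "EnhA", "EnhW", "ZNF/Rpts",
    "Het", "TssBiv", "EnhBiv", "ReprPC", "Quies")
}

#' Default 18-to-13 state pooling map
#'
#' Pools the TSS-flanking states into TSSFlnk, the two genic-enhancer states
#' into EnhG, the two polycomb states into ReprPC, and the three quiescent
#' states into Quies; all other labels map to themselves.
#' @return named character vector: names are 18-state labels, values pooled.
#' @export
default_pooling_map <- function() {
  m <- setNames(chrom_states_18(), chrom_states_18())
  m[c("TSSFlnk", "TSSFlnkD")] <- "TSSFlnk"
  m[c("EnhG1", "EnhG2")] <- "EnhG"
  m[c("ReprPC", "ReprPCWk")] <- "ReprPC"
  m[c("Quies1", "Quies2", "Quies3")] <- "Quies"
  m
}

#' Categorize a pooled chromatin state
#'
#' Maps each 13-state label to one of six categories: active (TSSA, Tx,
#' EnhG, EnhA), weak (TSSFlnk, TxWk, EnhW), heterochromatin (ZNF/Rpts, Het),
#' bivalent (TssBiv, EnhBiv), polycomb (ReprPC) and quiescent (Quies).
#'
#' @param label character vector of 13-state labels.
#' @return character vector of categories.
#' @export
categorize_state <- function(label) {
  map <- c(TSSA = "active", Tx = "active", EnhG = "active", EnhA = "active",
           TSSFlnk = "weak", TxWk = "weak", EnhW = "weak",
           `ZNF/Rpts` = "heterochromatin", Het = "heterochromatin",
           TssBiv = "bivalent", EnhBiv = "bivalent",
           ReprPC = "polycomb", Quies = "quiescent")
  out <- map[label]
  if (anyNA(out))
    stop("unknown state label(s): ",
         paste(unique(label[is.na(out)]), collapse = ", "))
  unname(out)
}

## state-priority rank used for deterministic tie-breaks: category order
## active > bivalent > polycomb > weak > heterochromatin > quiescent,
## then lexicographic within category.
state_priority_rank <- function(labels) {
  cat_rank <- c(active = 1, bivalent = 2, polycomb = 3, weak = 4,
                heterochromatin = 5, quiescent = 6)
  r <- suppressWarnings(tryCatch(cat_rank[categorize_state(labels)],
                                 error = function(e) NULL))
  if (is.null(r)) r <- rep(7, length(labels))  # unknown vocab: lexicographic
  r[is.na(r)] <- 7
  order(order(r, labels))  # smaller = higher priority
}

#' Construct binarized mark tracks
#'
#' @param bins named list (one element per chromosome) of bins x marks
#'   0/1 matrices with identical column names.
#' @param bin_size bin width in bp (default 200).
#' @param assembly optional [genome_assembly()]; if given, bin counts are
#'   checked against `ceiling(length / bin_size)`.
#' @return a `binarized_tracks` object.
#' @export
binarized_tracks <- function(bins, bin_size = 200, assembly = NULL) {
  if (is.null(names(bins)) || anyDuplicated(names(bins)))
    stop("bins must be a named list with unique chromosome names")
  marks <- colnames(bins[[1]])
  if (is.null(marks)) stop("mark names required as matrix column names")
  for (chr in names(bins)) {
    m <- bins[[chr]]
    if (!identical(colnames(m), marks))
      stop("mark names differ between chromosomes")
    if (!all(m %in% c(0, 1))) stop("track values must be 0/1")
    if (!is.null(assembly)) {
      expected <- ceiling(unname(assembly[chr]) / bin_size)
      if (is.na(expected)) stop("chromosome '", chr, "' not in assembly")
      if (nrow(m) != expected)
        stop("chromosome '", chr, "': ", nrow(m), " bins, expected ",
             expected)
    }
  }
  structure(list(bins = bins, marks = marks, bin_size = bin_size),
            class = "binarized_tracks")
}

#' @export
print.binarized_tracks <- function(x, ...) {
  cat("binarized_tracks:", length(x$bins), "chromosomes,",
      sum(vapply(x$bins, nrow, 0L)), "bins of", x$bin_size, "bp,",
      length(x$marks), "marks\n")
  invisible(x)
}

#' Binarize a per-bin count track against a Poisson background
#'
#' A bin is called present (1) when the upper-tail Poisson probability
#' `P(X >= count | lambda = global_rate)` is at most `p_threshold`.
#'
#' @param bin_counts non-negative integer vector of reads per bin.
#' @param global_rate genome-wide mean reads per bin (> 0).
#' @param p_threshold upper-tail probability cutoff (default 1e-4).
#' @return integer 0/1 vector.
#' @export
binarize_track <- function(bin_counts, global_rate, p_threshold = 1e-4) {
  if (any(bin_counts < 0) || any(bin_counts != floor(bin_counts)))
    stop("bin_counts must be non-negative integers")
  if (global_rate <= 0) stop("global_rate must be > 0")
  p <- ppois(bin_counts - 1, global_rate, lower.tail = FALSE)
  as.integer(p <= p_threshold)
}

## log emission likelihoods for all bins of one chromosome:
## X (bins x marks, 0/1), em (states x marks) -> bins x states
log_emission <- function(X, em) {
  em <- pmin(pmax(em, 1e-12), 1 - 1e-12)
  X %*% t(log(em)) + (1 - X) %*% t(log(1 - em))
}

## one restart of Baum-Welch EM; X_list: per-chromosome 0/1 matrices
em_run <- function(X_list, em, trans, init, max_iter, tol) {
  ll_trace <- numeric(0)
  K <- nrow(em)
  for (iter in seq_len(max_iter)) {
    ll <- 0
    em_num <- matrix(0, K, ncol(em))
    em_den <- numeric(K)
    trans_num <- matrix(0, K, K)
    init_num <- numeric(K)
    for (X in X_list) {
      fb <- hmm_forward_backward_cpp(log_emission(X, em), trans, init)
      ll <- ll + fb$loglik
      em_num <- em_num + t(fb$gamma) %*% X
      em_den <- em_den + colSums(fb$gamma)
      trans_num <- trans_num + fb$xi
      init_num <- init_num + fb$gamma[1, ]
    }
    ll_trace <- c(ll_trace, ll)
    if (iter > 1) {
      rel <- (ll - ll_prev) / (abs(ll_prev) + 1)
      if (rel < tol) break
    }
    ll_prev <- ll
    em <- em_num / pmax(em_den, 1e-300)
    em <- pmin(pmax(em, 1e-6), 1 - 1e-6)
    tn <- trans_num + 1e-10
    trans <- tn / rowSums(tn)
    init <- (init_num + 1e-10) / sum(init_num + 1e-10)
  }
  list(emission = em, transition = trans, initial = init,
       logLik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       niter = length(ll_trace),
       converged = length(ll_trace) < max_iter)
}

## seeded initialization: perturbed centroids of observed mark patterns
init_params <- function(X_all, n_states) {
  n <- nrow(X_all)
  idx <- sample.int(n, min(n, 5000L))
  pat <- X_all[idx, , drop = FALSE]
  centers <- pat[sample.int(nrow(pat), n_states, replace = nrow(pat) < n_states),
                 , drop = FALSE]
  em <- centers * 0.7 + 0.15 +
    matrix(runif(length(centers), -0.1, 0.1), nrow(centers))
  em <- pmin(pmax(em, 0.05), 0.95)
  trans <- matrix(0.1 / max(n_states - 1, 1), n_states, n_states)
  diag(trans) <- if (n_states > 1) 0.9 else 1
  list(emission = em, transition = trans,
       initial = rep(1 / n_states, n_states))
}

## run expr with a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Fit a Bernoulli-emission chromatin-state HMM
#'
#' Baum-Welch expectation-maximization for a hidden Markov model with
#' independent Bernoulli emissions per histone mark given the state, over
#' fixed-width genomic bins. The log-likelihood is non-decreasing across
#' iterations; fitting stops when its relative change falls below `tol` or
#' after `max_iter` iterations. Several seeded restarts from perturbed
#' mark-pattern centroids guard against local optima; the best-likelihood
#' restart is returned. Results are deterministic given `seed`.
#'
#' @param tracks a [binarized_tracks()] object.
#' @param n_states number of hidden states (>= 1).
#' @param seed integer seed controlling initialization.
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-4).
#' @param n_restarts number of random restarts (default 5).
#' @return A `state_hmm` object with components `emission`
#'   (states x marks), `transition`, `initial`, `marks`, `logLik`,
#'   `ll_trace`, `fit_report`.
#' @seealso [decode_segmentation()], [simulate.state_hmm()]
#' @export
fit_state_model <- function(tracks, n_states, seed = 1, max_iter = 200,
                            tol = 1e-4, n_restarts = 5) {
  stopifnot(inherits(tracks, "binarized_tracks"))
  if (n_states < 1) stop("n_states must be >= 1")
  X_list <- tracks$bins
  total_bins <- sum(vapply(X_list, nrow, 0L))
  if (n_states >= 2 && total_bins < 10 * n_states)
    stop("need at least 10 bins per state")
  mark_freq <- colSums(do.call(rbind, lapply(X_list, colSums))) / total_bins
  degenerate <- mark_freq == 0
  if (n_states == 1) {
    em <- matrix(mark_freq, 1, dimnames = list(NULL, tracks$marks))
    ll <- sum(vapply(X_list, function(X)
      sum(log_emission(X, em)), 0))
    fit <- list(emission = em,
                transition = matrix(1, 1, 1), initial = 1,
                logLik = ll, ll_trace = ll, niter = 1L, converged = TRUE)
    restarts_ll <- ll
  } else {
    X_all <- do.call(rbind, X_list)
    runs <- with_seed(seed, lapply(seq_len(n_restarts), function(r) {
      p0 <- init_params(X_all, n_states)
      em_run(X_list, p0$emission, p0$transition, p0$initial, max_iter, tol)
    }))
    restarts_ll <- vapply(runs, `[[`, 0, "logLik")
    fit <- runs[[which.max(restarts_ll)]]
  }
  colnames(fit$emission) <- tracks$marks
  labels <- paste0("S", seq_len(n_states))
  rownames(fit$emission) <- labels
  dimnames(fit$transition) <- list(labels, labels)
  structure(list(
    n_states = n_states, marks = tracks$marks, bin_size = tracks$bin_size,
    emission = fit$emission, transition = fit$transition,
    initial = setNames(as.numeric(fit$initial), labels),
    state_labels = labels,
    logLik = fit$logLik, ll_trace = fit$ll_trace, niter = fit$niter,
    converged = fit$converged, restarts_logLik = restarts_ll,
    n_bins = total_bins, seed = seed,
    fit_report = list(mark_frequency = mark_freq,
                      degenerate_marks = tracks$marks[degenerate])),
    class = "state_hmm")
}

#' Construct a state model from known parameters
#'
#' Useful for simulation and for decoding with an externally specified model.
#'
#' @param emission states x marks matrix of Bernoulli emission probabilities;
#'   row names are used as state labels.
#' @param transition row-stochastic states x states matrix.
#' @param initial initial state distribution (default stationary-ish uniform).
#' @param bin_size bin width in bp.
#' @return A `state_hmm` object.
#' @export
state_model <- function(emission, transition,
                        initial = rep(1 / nrow(emission), nrow(emission)),
                        bin_size = 200) {
  K <- nrow(emission)
  stopifnot(nrow(transition) == K, ncol(transition) == K, length(initial) == K)
  if (any(emission < 0 | emission > 1)) stop("emission probabilities in [0,1]")
  if (any(abs(rowSums(transition) - 1) > 1e-8))
    stop("transition rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-8) stop("initial must sum to 1")
  labels <- rownames(emission)
  if (is.null(labels)) labels <- paste0("S", seq_len(K))
  marks <- colnames(emission)
  if (is.null(marks)) marks <- paste0("mark", seq_len(ncol(emission)))
  dimnames(emission) <- list(labels, marks)
  dimnames(transition) <- list(labels, labels)
  structure(list(n_states = K, marks = marks, bin_size = bin_size,
                 emission = emission, transition = transition,
                 initial = setNames(as.numeric(initial), labels),
                 state_labels = labels, logLik = NA_real_,
                 ll_trace = numeric(0), niter = 0L, converged = NA,
                 restarts_logLik = numeric(0), n_bins = NA_integer_,
                 seed = NA_integer_, fit_report = list()),
            class = "state_hmm")
}

#' @export
print.state_hmm <- function(x, ...) {
  cat("state_hmm:", x$n_states, "states,", length(x$marks), "marks (",
      paste(x$marks, collapse = ", "), ")\n")
  if (!is.na(x$logLik))
    cat("log-likelihood:", format(x$logLik), "after", x$niter,
        "EM iterations",
        if (isTRUE(x$converged)) "(converged)" else "(max_iter reached)",
        "\n")
  invisible(x)
}

#' @export
summary.state_hmm <- function(object, ...) {
  cat("Bernoulli-emission chromatin-state HMM\n")
  print(object)
  cat("\nEmission probabilities (state x mark):\n")
  print(round(object$emission, 3))
  cat("\nSelf-transition probabilities:\n")
  print(round(diag(object$transition), 3))
  if (length(object$fit_report$degenerate_marks))
    cat("\nDegenerate (all-zero) marks:",
        paste(object$fit_report$degenerate_marks, collapse = ", "), "\n")
  invisible(object)
}

#' @export
logLik.state_hmm <- function(object, ...) {
  ll <- object$logLik
  attr(ll, "df") <- with(object,
    n_states * length(marks) + n_states * (n_states - 1) + n_states - 1)
  class(ll) <- "logLik"
  ll
}

#' Decode a segmentation from binarized tracks
#'
#' Assigns each bin the state with maximal posterior probability
#' (forward-backward), then run-length encodes the per-bin labels into a
#' segmentation that tiles each chromosome. The last run of each chromosome
#' is clipped to the chromosome length when an assembly is given.
#'
#' @param model a `state_hmm`.
#' @param tracks a [binarized_tracks()] with the same marks.
#' @param assembly optional [genome_assembly()] for end clipping.
#' @return data.frame segmentation: `chrom`, `start`, `end`, `state`
#'   (0-based half-open), with attributes `bin_size` and `label_vocabulary`.
#' @export
decode_segmentation <- function(model, tracks, assembly = NULL) {
  stopifnot(inherits(model, "state_hmm"), inherits(tracks, "binarized_tracks"))
  if (!identical(model$marks, tracks$marks))
    stop("model and tracks disagree on marks")
  bs <- tracks$bin_size
  out <- lapply(names(tracks$bins), function(chr) {
    X <- tracks$bins[[chr]]
    fb <- hmm_forward_backward_cpp(log_emission(X, model$emission),
                                   model$transition,
                                   as.numeric(model$initial))
    states <- max.col(fb$gamma, ties.method = "first")
    r <- rle(states)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0, head(ends_bin, -1))
    end_bp <- ends_bin * bs
    if (!is.null(assembly))
      end_bp[length(end_bp)] <- min(end_bp[length(end_bp)],
                                    unname(assembly[chr]))
    data.frame(chrom = chr, start = starts_bin * bs, end = end_bp,
               state = model$state_labels[r$values],
               stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  attr(seg, "bin_size") <- bs
  attr(seg, "label_vocabulary") <- model$state_labels
  seg
}

#' @export
predict.state_hmm <- function(object, tracks, assembly = NULL, ...) {
  decode_segmentation(object, tracks, assembly)
}

#' Simulate binarized tracks from a state model
#'
#' Samples a state path per chromosome from the Markov chain and emits each
#' mark independently Bernoulli given the state. The true path is returned
#' as a segmentation alongside the tracks.
#'
#' @param object a `state_hmm`.
#' @param nsim unused (one genome per call).
#' @param seed integer seed.
#' @param assembly a [genome_assembly()] giving chromosome lengths.
#' @param ... unused.
#' @return list with `tracks` ([binarized_tracks()]) and `truth`
#'   (segmentation data.frame as in [decode_segmentation()]).
#' @export
simulate.state_hmm <- function(object, nsim = 1, seed = 1, assembly, ...) {
  bs <- object$bin_size
  K <- object$n_states
  with_seed(seed, {
    bins <- list()
    truths <- list()
    for (chr in names(assembly)) {
      n_bins <- ceiling(unname(assembly[chr]) / bs)
      path <- markov_path_cpp(object$transition,
                              as.numeric(object$initial), runif(n_bins))
      X <- matrix(rbinom(n_bins * length(object$marks), 1,
                         object$emission[path, ]),
                  n_bins, length(object$marks),
                  dimnames = list(NULL, object$marks))
      bins[[chr]] <- X
      r <- rle(path)
      ends_bin <- cumsum(r$lengths)
      end_bp <- pmin(ends_bin * bs, unname(assembly[chr]))
      truths[[chr]] <- data.frame(
        chrom = chr, start = c(0, head(ends_bin, -1)) * bs, end = end_bp,
        state = object$state_labels[r$values], stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truths)
    rownames(truth) <- NULL
    attr(truth, "bin_size") <- bs
    attr(truth, "label_vocabulary") <- object$state_labels
    list(tracks = binarized_tracks(bins, bs, assembly), truth = truth)
  })
}

#' Pool segmentation states
#'
#' Relabels states through a total pooling map and merges adjacent runs that
#' acquire the same pooled label. The default map pools 18 states to 13.
#'
#' @param seg segmentation data.frame (`chrom`, `start`, `end`, `state`).
#' @param pooling_map named character vector mapping every input label.
#' @return pooled segmentation data.frame.
#' @export
pool_states <- function(seg, pooling_map = default_pooling_map()) {
  labs <- unique(seg$state)
  unmapped <- setdiff(labs, names(pooling_map))
  if (length(unmapped))
    stop("pooling map lacks label(s): ", paste(unmapped, collapse = ", "))
  new_state <- unname(pooling_map[seg$state])
  ## merge adjacent equal-label runs within chromosome
  brk <- c(TRUE, new_state[-1] != new_state[-length(new_state)] |
             seg$chrom[-1] != seg$chrom[-nrow(seg)] |
             seg$start[-1] != seg$end[-nrow(seg)])
  grp <- cumsum(brk)
  out <- data.frame(
    chrom = tapply(seg$chrom, grp, `[`, 1),
    start = as.numeric(tapply(seg$start, grp, min)),
    end = as.numeric(tapply(seg$end, grp, max)),
    state = tapply(new_state, grp, `[`, 1),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "bin_size") <- attr(seg, "bin_size")
  attr(out, "label_vocabulary") <- unique(unname(pooling_map))
  out
}

#' Read/write a segmentation as BED4
#'
#' BED4: chrom, start, end, state_label; tab-separated, no header.
#' @param seg segmentation data.frame.
#' @param path file path.
#' @param assembly a [genome_assembly()].
#' @export
write_segmentation <- function(seg, path) {
  write.table(data.frame(seg$chrom,
                         format(seg$start, scientific = FALSE, trim = TRUE),
                         format(seg$end, scientific = FALSE, trim = TRUE),
                         seg$state),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path, assembly) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "state"))
  check_intervals(df, assembly, "segmentation run")
  df <- df[interval_order(df, assembly), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write/read binarized tracks as per-chromosome TSV
#'
#' One file per chromosome named `<prefix>_<chrom>.tsv`: header row of mark
#' names, one row per bin.
#' @param tracks a [binarized_tracks()].
#' @param prefix output path prefix.
#' @export
write_tracks <- function(tracks, prefix) {
  for (chr in names(tracks$bins)) {
    write.table(tracks$bins[[chr]], paste0(prefix, "_", chr, ".tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_tracks
#' @param chromosomes chromosome names to read (files must exist for each).
#' @param bin_size bin width in bp.
#' @param assembly optional [genome_assembly()] for validation.
#' @export
read_tracks <- function(prefix, chromosomes, bin_size = 200,
                        assembly = NULL) {
  bins <- lapply(chromosomes, function(chr) {
    m <- as.matrix(read.table(paste0(prefix, "_", chr, ".tsv"), sep = "\t",
                              header = TRUE, check.names = FALSE))
    storage.mode(m) <- "integer"
    m
  })
  names(bins) <- chromosomes
  binarized_tracks(bins, bin_size, assembly)
}
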