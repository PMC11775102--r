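## Spike-in-anchored differential expression: cpm filtering, control-gene
## (ERCC) unwanted-variation removal, and a negative-binomial
## fold-change-threshold test: NB generalized linear models fitted by IRLS,
## gene-wise dispersions from a Cox-Reid adjusted profile likelihood grid
## shrunk toward the common dispersion, and a TREAT-style likelihood-ratio
## test against the fold-change bound.

#' Counts per million
#'
#' Library sizes are computed over the non-control genes only, so spike-in
#' rows carry normalization information through the unwanted-variation
#' factors rather than through depth.
#'
#' @param counts genes x samples non-negative integer matrix with rownames.
#' @param control logical per-gene vector (spike-in rows), or `NULL` to
#'   detect rows whose name starts with `"ERCC-"`.
#' @return matrix of cpm values with the same dimensions.
#' @export
cpm_matrix <- function(counts, control = NULL) {
  control <- resolve_control(counts, control)
  lib <- colSums(counts[!control, , drop = FALSE])
  if (any(lib == 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  t(t(counts) / lib) * 1e6
}

resolve_control <- function(counts, control) {
  if (is.null(control)) control <- startsWith(rownames(counts), "ERCC-")
  if (length(control) != nrow(counts))
    stop("control flags must match the number of genes")
  control
}

#' Filter lowly expressed genes
#'
#' Keeps genes with cpm >= `min_cpm` in at least `min_samples` samples.
#' Control (spike-in) genes are always kept: they are needed downstream for
#' normalization.
#'
#' @inheritParams cpm_matrix
#' @param min_cpm cpm threshold (default 1).
#' @param min_samples minimum number of samples at or above the threshold
#'   (default 2).
#' @return the filtered count matrix (attribute `"control"` carries the
#'   filtered control flags).
#' @export
filter_expressed <- function(counts, control = NULL, min_cpm = 1,
                             min_samples = 2) {
  control <- resolve_control(counts, control)
  cp <- cpm_matrix(counts, control)
  keep <- rowSums(cp >= min_cpm) >= min_samples | control
  out <- counts[keep, , drop = FALSE]
  attr(out, "control") <- control[keep]
  out
}

#' Remove unwanted variation using control genes
#'
#' The construction follows the control-gene (RUVg) recipe: log counts
#' (pseudocount 0.5) of the control genes are row-centred, the first `k`
#' right singular vectors of that submatrix give the per-sample unwanted
#' factors W (orthonormal columns), and W is regressed out of every gene's
#' log expression.
#'
#' @inheritParams cpm_matrix
#' @param k number of unwanted factors (default 1); must be below the rank
#'   of the control submatrix.
#' @return list with `adjusted` (genes x samples log2 expression after
#'   factor removal), `W` (samples x k), `log_expression` (the unadjusted
#'   log2 matrix).
#' @export
ruv_control_normalize <- function(counts, control = NULL, k = 1) {
  control <- resolve_control(counts, control)
  if (sum(control) < 10)
    warning("fewer than 10 control genes; normalization may be unstable")
  Y <- log2(counts + 0.5)
  Zc <- Y[control, , drop = FALSE]
  Zc <- Zc - rowMeans(Zc)
  sv <- svd(Zc)
  r <- sum(sv$d > max(dim(Zc)) * .Machine$double.eps * sv$d[1])
  if (k >= r) stop("k must be below the rank of the control submatrix (",
                   r, ")")
  W <- sv$v[, seq_len(k), drop = FALSE]
  rownames(W) <- colnames(counts)
  ## regress W out of each gene's log expression (W orthonormal)
  Yc <- Y - rowMeans(Y)
  adjusted <- Y - (Yc %*% W) %*% t(W)
  list(adjusted = adjusted, W = W, log_expression = Y)
}

## NB log-likelihood per gene (rows), natural parameters; phi scalar or
## per-gene vector
nb_loglik <- function(Y, MU, phi) {
  r <- 1 / phi
  MU <- pmax(MU, 1e-10)
  if (length(r) > 1) r <- matrix(r, nrow(Y), ncol(Y))
  ll <- lgamma(Y + r) - lgamma(r) - lgamma(Y + 1) +
    r * log(r / (r + MU)) + Y * log(MU / (r + MU))
  ll[Y == 0 & MU <= 1e-10] <- 0
  rowSums(ll)
}

## Batched NB IRLS with log link: one shared design X (n x p), per-gene
## responses (rows of Y), shared offset (length n, natural log), dispersion
## phi (scalar or per-gene). Returns coefficients, fitted means, per-gene
## log-likelihood and the Cox-Reid log-determinant of X'WX.
nb_irls <- function(Y, X, offset, phi, max_iter = 25, tol = 1e-8) {
  G <- nrow(Y)
  n <- ncol(Y)
  p <- ncol(X)
  PH <- if (length(phi) > 1) matrix(phi, G, n) else phi
  MU <- pmax(Y + rowMeans(Y) / 2, 0.125)
  ETA <- log(MU)
  OFF <- matrix(offset, G, n, byrow = TRUE)
  beta_old <- NULL
  xx <- lapply(seq_len(p), function(a)
    lapply(seq_len(p), function(b) X[, a] * X[, b]))
  for (iter in seq_len(max_iter)) {
    W <- MU / (1 + PH * MU)
    Z <- ETA - OFF + (Y - MU) / MU
    M <- matrix(0, G, p * p)
    for (a in seq_len(p)) for (b in seq_len(p))
      M[, (a - 1) * p + b] <- W %*% xx[[a]][[b]]
    B <- (W * Z) %*% X
    sol <- batch_solve_cpp(M, B)
    beta <- sol$beta
    bad <- !is.finite(rowSums(beta))
    if (any(bad)) beta[bad, ] <- if (!is.null(beta_old))
      beta_old[bad, , drop = FALSE] else 0
    ETA <- pmin(pmax(beta %*% t(X) + OFF, -30), 30)
    MU <- exp(ETA)
    if (!is.null(beta_old) &&
        max(abs(beta - beta_old)) < tol) {
      beta_old <- beta
      break
    }
    beta_old <- beta
  }
  list(beta = beta_old, mu = MU, ll = nb_loglik(Y, MU, phi),
       logdet = sol$logdet)
}

## mean of pnorm over [a, b] (closed form); equals pnorm(a) when a == b
integrate_pnorm <- function(a, b) {
  ifelse(a == b, stats::pnorm(a),
         (b * stats::pnorm(b) + stats::dnorm(b) -
            a * stats::pnorm(a) - stats::dnorm(a)) / (b - a))
}

## TREAT p-value from the signed near-boundary z (zl) and far-boundary z
## (zr): either the worst-case boundary null (sum of two tails) or the
## interval null that averages the rejection probability over the null
## fold-change interval (integration segment length 1.470402, the TREAT
## interval calibration constant)
treat_pvalue <- function(zl, zr, null = "interval") {
  if (null == "worst.case") return(pmin(stats::pnorm(zl) +
                                          stats::pnorm(-zr), 1))
  cc <- 1.470402
  j <- (zr + zl) > cc
  p <- numeric(length(zl))
  p[j] <- integrate_pnorm(-zr[j], -zr[j] + cc) +
    integrate_pnorm(zl[j] - cc, zl[j])
  p[!j] <- 2 * integrate_pnorm(-zr[!j], zl[!j])
  pmin(pmax(p, 0), 1)
}

## parabolic refinement of a grid argmax in x given values y
refine_argmax <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(x[i])
  d1 <- y[i] - y[i - 1]
  d2 <- y[i] - y[i + 1]
  if (d1 + d2 <= 0) return(x[i])
  x[i] + 0.5 * (x[i + 1] - x[i]) * (d1 - d2) / (d1 + d2)
}

## gene-wise and common NB dispersions from a Cox-Reid adjusted profile
## likelihood evaluated on a log-spaced grid, with shrinkage of the
## gene-wise values toward the common value on the log scale
estimate_dispersion_apl <- function(Y, X, offset, gene_weight = 0.25,
                                    grid = exp(seq(log(1e-3), log(3),
                                                   length.out = 15))) {
  G <- nrow(Y)
  apl <- matrix(NA_real_, G, length(grid))
  for (j in seq_along(grid)) {
    fit <- nb_irls(Y, X, offset, grid[j], max_iter = 10)
    apl[, j] <- fit$ll - 0.5 * fit$logdet
  }
  lg <- log(grid)
  gene <- vapply(seq_len(G), function(g) {
    i <- which.max(apl[g, ])
    exp(refine_argmax(lg, apl[g, ], i))
  }, 0)
  tot <- colSums(apl)
  common <- exp(refine_argmax(lg, tot, which.max(tot)))
  shrunk <- exp(gene_weight * log(pmax(gene, 1e-6)) +
                  (1 - gene_weight) * log(common))
  list(gene = gene, common = common, shrunk = pmax(shrunk, 1e-6))
}

#' Negative-binomial fold-change-threshold differential expression test
#'
#' Tests, per gene, the null that the true fold change between genotypes
#' does not exceed `fc_threshold` (a TREAT-style threshold test), rather
#' than the point null of no change. Each gene is modelled as negative
#' binomial with a log link under the design (intercept, genotype, optional
#' unwanted-variation covariates `W`) and library-size offsets computed
#' over non-control genes. Gene-wise dispersions maximize a Cox-Reid
#' adjusted profile likelihood on a grid and are shrunk toward the common
#' (all-gene) dispersion on the log scale (default weight 0.25 gene / 0.75
#' common). The test refits each gene with the genotype coefficient pinned
#' at the two fold-change boundaries and converts the likelihood-ratio
#' statistics to boundary z-scores; the default `null = "interval"`
#' averages the rejection probability over the interval of null fold
#' changes (the TREAT interval formulation), while `null = "worst.case"`
#' sums the two boundary tails. Either way a gene whose estimated fold
#' change does not clear the threshold cannot reach a small p. BH
#' correction across genes; status `up`/`down` requires `fdr < alpha`.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @param group factor/character of length samples with exactly two levels
#'   (e.g. CTL, KO); the second level is the test condition.
#' @param W optional samples x k covariate matrix (e.g. from
#'   [ruv_control_normalize()]).
#' @param control logical control-gene flags (excluded from library size
#'   and from testing), or `NULL` to detect `"ERCC-"` prefixes.
#' @param fc_threshold fold-change null bound (> 1; default 1.5).
#' @param alpha FDR cutoff for status calls (default 0.05).
#' @param dispersion_weight weight of the gene-wise dispersion in the
#'   shrinkage (default 0.25).
#' @param null `"interval"` (default) or `"worst.case"` null composition.
#' @return data.frame with `gene_id`, `log2fc`, `p`, `fdr`, `status`
#'   (up/down/not), `dispersion`, `control`, `flag`.
#' @export
de_threshold_test <- function(counts, group, W = NULL, control = NULL,
                              fc_threshold = 1.5, alpha = 0.05,
                              dispersion_weight = 0.25,
                              null = c("interval", "worst.case")) {
  null <- match.arg(null)
  if (fc_threshold <= 1) stop("fc_threshold must be > 1")
  control <- resolve_control(counts, control)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) < 2)) stop("need >= 2 samples per group")
  lib <- colSums(counts[!control, , drop = FALSE])
  if (any(lib == 0)) stop("zero library size")
  X <- cbind(`(Intercept)` = 1,
             group = as.numeric(group == levels(group)[2]))
  if (!is.null(W)) X <- cbind(X, as.matrix(W))
  offset <- log(lib)
  Y <- counts
  storage.mode(Y) <- "double"
  zero <- rowSums(Y) == 0
  Ywork <- Y
  Ywork[zero, 1] <- 1  # placeholder so IRLS stays finite; results overridden
  disp <- estimate_dispersion_apl(Ywork, X, offset,
                                  gene_weight = dispersion_weight)
  phi <- disp$shrunk
  full <- nb_irls(Ywork, X, offset, phi)
  lfc_ln <- full$beta[, 2]
  tau <- log(fc_threshold)
  X0 <- X[, -2, drop = FALSE]
  ## constrained fits with the genotype effect pinned at +tau and -tau;
  ## the pinned term enters through the offset
  ll0 <- sapply(c(tau, -tau), function(b)
    nb_irls(Ywork, X0, offset + b * X[, 2], phi, max_iter = 25)$ll)
  zA <- sqrt(pmax(2 * (full$ll - ll0[, 1]), 0))
  zB <- sqrt(pmax(2 * (full$ll - ll0[, 2]), 0))
  zmin <- pmin(zA, zB)
  zmax <- pmax(zA, zB)
  within <- abs(lfc_ln) <= tau
  zl <- ifelse(within, zmin, -zmin)
  zr <- zmax
  p <- treat_pvalue(zl, zr, null)
  lfc <- lfc_ln / log(2)
  flag <- character(nrow(Y))
  p[zero] <- 1
  lfc[zero] <- 0
  flag[zero] <- "all_zero"
  p[control] <- NA
  fdr <- rep(NA_real_, length(p))
  fdr[!control] <- p.adjust(p[!control], "BH")
  status <- rep("not", length(p))
  status[!control & !is.na(fdr) & fdr < alpha & lfc > 0] <- "up"
  status[!control & !is.na(fdr) & fdr < alpha & lfc < 0] <- "down"
  data.frame(gene_id = rownames(counts), log2fc = lfc, p = p, fdr = fdr,
             status = status, dispersion = phi, control = control,
             flag = flag, stringsAsFactors = FALSE, row.names = NULL)
}

#' Feature enrichment of differential-expression classes
#'
#' For each feature — gene-length decile (computed over the tested genes),
#' biotype group, chromosome — compares the feature distribution of `up`
#' (and of `down`) genes against not-deregulated genes with a chi-square
#' test, switching to a simulated-p Fisher test when expected cell counts
#' fall below 5. BH correction across all contrasts.
#'
#' @param de data.frame from [de_threshold_test()].
#' @param genes gene models data.frame (`gene_id`, `length`, `biotype`,
#'   `chrom`).
#' @return data.frame with `feature`, `direction`, `p`, `fdr`, `method`;
#'   the contingency tables are attached as the `"tables"` attribute.
#' @export
feature_enrichment <- function(de, genes) {
  de <- de[!de$control, , drop = FALSE]
  g <- genes[match(de$gene_id, genes$gene_id), , drop = FALSE]
  keep <- !is.na(g$gene_id)
  de <- de[keep, , drop = FALSE]
  g <- g[keep, , drop = FALSE]
  decile <- cut(rank(g$length, ties.method = "first"), breaks = 10,
                labels = paste0("D", 1:10))
  feats <- list(length_decile = decile,
                biotype = factor(g$biotype),
                chromosome = factor(g$chrom))
  rows <- list()
  tabs <- list()
  for (fname in names(feats)) {
    for (dir in c("up", "down")) {
      sel <- de$status %in% c(dir, "not")
      if (sum(de$status == dir) == 0) {
        rows[[paste(fname, dir)]] <- data.frame(
          feature = fname, direction = dir, p = NA_real_, method = "none",
          stringsAsFactors = FALSE)
        next
      }
      tab <- table(feats[[fname]][sel],
                   factor(de$status[sel], c("not", dir)))
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      exp_ok <- tryCatch(
        all(suppressWarnings(chisq.test(tab)$expected) >= 5),
        error = function(e) FALSE)
      if (exp_ok) {
        p <- suppressWarnings(chisq.test(tab)$p.value)
        method <- "chisq"
      } else {
        p <- fisher.test(tab, simulate.p.value = TRUE, B = 1e4)$p.value
        method <- "fisher_sim"
      }
      rows[[paste(fname, dir)]] <- data.frame(
        feature = fname, direction = dir, p = p, method = method,
        stringsAsFactors = FALSE)
      tabs[[paste(fname, dir)]] <- tab
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- p.adjust(out$p, "BH")
  attr(out, "tables") <- tabs
  out
}
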