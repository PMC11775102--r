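toy_counts <- function(n_genes = 50, n_ercc = 12, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("g%03d", seq_len(n_genes)),
           sprintf("ERCC-%04d", seq_len(n_ercc)))
  m <- matrix(rnbinom(length(ids) * 6, mu = 100, size = 10),
              length(ids), 6,
              dimnames = list(ids, paste0("s", 1:6)))
  m
}

test_that("cpm uses non-control library sizes and sums to 1e6", {
  counts <- matrix(c(5, 10), 2, 1,
                   dimnames = list(c("gA", "ERCC-0001"), "s1"))
  counts["gA", 1] <- 1e6
  counts["ERCC-0001", 1] <- 500
  cp <- cpm_matrix(counts)
  expect_equal(cp["gA", 1], 1e6)  # library size excludes the ERCC row

  m <- toy_counts()
  ctl <- startsWith(rownames(m), "ERCC-")
  cp <- cpm_matrix(m)
  expect_equal(unname(colSums(cp[!ctl, ])), rep(1e6, 6))
  expect_error(cpm_matrix(m * 0), "zero library")
})

test_that("filter_expressed drops sub-threshold genes but keeps controls", {
  m <- toy_counts()
  # one gene expressed in exactly one sample
  m["g001", ] <- c(1000, 0, 0, 0, 0, 0)
  # one gene dead everywhere
  m["g002", ] <- 0
  out <- filter_expressed(m)
  expect_false("g001" %in% rownames(out))
  expect_false("g002" %in% rownames(out))
  expect_true(all(sprintf("ERCC-%04d", 1:12) %in% rownames(out)))
  # kept set equals direct rule evaluation
  cp <- cpm_matrix(m)
  want <- rowSums(cp >= 1) >= 2 | startsWith(rownames(m), "ERCC-")
  expect_setequal(rownames(out), rownames(m)[want])
})

test_that("ruv_control_normalize returns orthonormal W and is near-identity
           without a planted factor", {
  m <- toy_counts(n_genes = 200, n_ercc = 30, seed = 2)
  ruv <- ruv_control_normalize(m, k = 2)
  expect_equal(crossprod(ruv$W), diag(2), tolerance = 1e-10)
  # pure-noise controls: adjustment changes little
  delta <- mean(abs(ruv$adjusted - ruv$log_expression))
  expect_lt(delta, 0.2)
  expect_error(ruv_control_normalize(m, k = 6), "rank")
})

test_that("a planted unwanted factor is removed by one RUV factor", {
  genes <- data.frame(gene_id = sprintf("g%04d", 1:800))
  cm <- simulate_counts(genes, seed = 7, unwanted_strength = 1,
                        ercc_n = 60)
  ruv <- ruv_control_normalize(cm$counts, cm$control, k = 1)
  pc1 <- function(M) svd(M - rowMeans(M))$v[, 1]
  before <- abs(cor(pc1(log2(cm$counts + 0.5)), cm$truth$factor))
  after <- abs(cor(pc1(ruv$adjusted), cm$truth$factor))
  expect_gt(before, 0.9)
  expect_lt(after, 0.2)
})

test_that("identical groups give zero fold change and p near one", {
  m <- matrix(rep(c(10, 20, 30, 10, 20, 30), times = 40), 40, 6,
              byrow = TRUE,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
  de <- de_threshold_test(m, rep(c("CTL", "KO"), each = 3),
                          control = rep(FALSE, 40))
  expect_lt(max(abs(de$log2fc)), 1e-8)
  expect_true(all(de$p > 0.9))
  expect_true(all(de$status == "not"))
})

test_that("swapping group labels negates the fold change exactly", {
  genes <- data.frame(gene_id = paste0("g", 1:150))
  cm <- simulate_counts(genes, up_genes = paste0("g", 1:15), seed = 4,
                        ercc_n = 0)
  d1 <- de_threshold_test(cm$counts, cm$group,
                          control = rep(FALSE, 150))
  d2 <- de_threshold_test(cm$counts,
                          factor(cm$group, levels = c("KO", "CTL")),
                          control = rep(FALSE, 150))
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-10)
  expect_equal(d1$p, d2$p, tolerance = 1e-8)
})

test_that("degenerate and invalid inputs are rejected or flagged", {
  m <- toy_counts(20, 0, seed = 5)
  expect_error(de_threshold_test(m, rep(c("A", "B"), each = 3),
                                 control = rep(FALSE, 20),
                                 fc_threshold = 1), "fc_threshold")
  expect_error(de_threshold_test(m, rep("A", 6),
                                 control = rep(FALSE, 20)), "two levels")
  m["g001", ] <- 0
  de <- de_threshold_test(m, rep(c("A", "B"), each = 3),
                          control = rep(FALSE, 20))
  expect_equal(de$flag[de$gene_id == "g001"], "all_zero")
  expect_equal(de$p[de$gene_id == "g001"], 1)
  expect_equal(de$status[de$gene_id == "g001"], "not")
})

test_that("threshold-test calls agree with an independent reference
           implementation on status", {
  skip_if_not_installed("edgeR")
  genes <- data.frame(gene_id = sprintf("g%04d", 1:500))
  cm <- simulate_counts(genes, up_genes = sprintf("g%04d", 1:40),
                        down_genes = sprintf("g%04d", 41:80),
                        effect_log2fc = 3, seed = 6, ercc_n = 0,
                        base_sdlog = 0.3)
  de <- de_threshold_test(cm$counts, cm$group, control = rep(FALSE, 500))
  y <- edgeR::DGEList(cm$counts, group = cm$group)
  y <- edgeR::calcNormFactors(y, method = "none")
  design <- stats::model.matrix(~cm$group)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmFit(y, design)
  tt <- edgeR::topTags(edgeR::glmTreat(fit, coef = 2, lfc = log2(1.5)),
                       n = Inf, sort.by = "none")$table
  ref_called <- rownames(tt)[tt$FDR < 0.05]
  called <- de$gene_id[de$status != "not"]
  # same operating point: >= 90% agreement on the called set
  expect_gt(f1_score(called, ref_called), 0.9)
  expect_gt(cor(de$log2fc, tt$logFC), 0.99)
})

test_that("feature enrichment detects a planted decile excess and is null
           on uniform draws", {
  genes <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                      length = exp(rnorm(1000, 8, 1)),
                      biotype = "protein_coding",
                      chrom = "chr1")
  genes$length <- sort(genes$length)
  de <- data.frame(gene_id = genes$gene_id, log2fc = 0, p = 1, fdr = 1,
                   status = "not", control = FALSE)
  # all up genes planted in the top decile
  de$status[901:1000][1:60] <- "up"
  fe <- feature_enrichment(de, genes)
  expect_lt(fe$p[fe$feature == "length_decile" & fe$direction == "up"],
            1e-6)
  # uniformly drawn up genes: decile contrast null
  set.seed(44)
  de2 <- de
  de2$status <- "not"
  de2$status[sample(1000, 60)] <- "up"
  fe2 <- feature_enrichment(de2, genes)
  expect_gt(fe2$p[fe2$feature == "length_decile" & fe2$direction == "up"],
            0.001)
})
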