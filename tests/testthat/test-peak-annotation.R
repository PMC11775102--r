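toy_genes <- function() {
  data.frame(gene_id = c("g1", "g2"),
             chrom = "chr1",
             start = c(3000, 30000), end = c(10000, 36000),
             strand = c("+", "-"),
             tss = c(3000, 35999),
             length = c(7000, 6000),
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

test_that("annotate_peaks applies the promoter > intragenic > downstream
           priority", {
  genes <- toy_genes()
  peaks <- data.frame(
    chrom = "chr1",
    start = c(2900, 8000, 10500, 20000, 29000),
    end = c(3100, 8200, 11000, 20500, 29500))
  got <- as.character(annotate_peaks(peaks, genes))
  # peak 2: inside g1 body, ~5 kb from its TSS -> promoter window misses it
  expect_equal(got, c("promoter", "intragenic", "downstream",
                      "distal_intergenic", "downstream"))
  # empty peak set is fine
  expect_equal(length(annotate_peaks(peaks[0, ], genes)), 0)
  expect_error(annotate_peaks(peaks, genes[0, ]), "non-empty")
})

test_that("annotate_peaks matches the exhaustive oracle on random peaks", {
  set.seed(17)
  asm_len <- 50000
  genes <- simulate_genome(genome_assembly("chr1", asm_len), 8, seed = 3,
                           len_meanlog = log(3000))
  peaks <- random_intervals(200, asm_len, max_len = 1500)
  got <- as.character(annotate_peaks(peaks, genes))
  want <- vapply(seq_len(nrow(peaks)), function(i)
    oracle_annotate(peaks[i, ], genes), "")
  expect_equal(got, want)
  expect_equal(length(got), nrow(peaks))
})

test_that("peak densities and stage ratios follow the stated conventions", {
  asm <- genome_assembly(c("chrA", "chrB"), c(1e5, 2e5))
  peaks <- data.frame(chrom = rep("chrA", 10),
                      start = seq(0, 9000, 1000), end = seq(100, 9100, 1000))
  d <- chromosome_peak_density(peaks, asm)
  expect_equal(d$density_per_mb[d$chrom == "chrA"], 100)
  expect_equal(d$density_per_mb[d$chrom == "chrB"], 0)

  d2 <- d
  d2$density_per_mb <- c(400, 0)
  r <- ratio_between_stages(d, d2)
  expect_equal(r$ratio[1], 4)
  expect_true(is.na(r$ratio[2]))
  d3 <- d
  d3$density_per_mb <- c(0, 0)
  r2 <- ratio_between_stages(d3, d2)
  expect_equal(r2$ratio[1], Inf)
})

test_that("stage dynamics classes follow presence patterns and match the
           per-base oracle", {
  stages <- list(
    GSC = data.frame(chrom = "chr1", start = c(100, 5000),
                     end = c(400, 5400)),
    SCI = data.frame(chrom = "chr1", start = c(300, 9000),
                     end = c(600, 9100)),
    RS = data.frame(chrom = "chr1", start = c(350, 20000),
                    end = c(500, 20100)))
  dyn <- classify_stage_dynamics(stages, min_group = 0)
  expect_setequal(dyn$class, c("common", "GSC-spe", "SCI-spe", "RS-spe"))
  expect_equal(dyn$class[dyn$start == 100], "common")
  expect_equal(dyn$class[dyn$start == 20000], "RS-spe")

  # invariance to peak row ordering within each stage
  shuffled <- lapply(stages, function(p) p[rev(seq_len(nrow(p))), ])
  dyn2 <- classify_stage_dynamics(shuffled, min_group = 0)
  expect_equal(table(dyn$class), table(dyn2$class))

  # presence equals oracle on random sets
  set.seed(23)
  for (rep in 1:4) {
    ps <- list(GSC = random_intervals(40, 30000, 600),
               SCI = random_intervals(40, 30000, 600),
               RS = random_intervals(40, 30000, 600))
    dd <- classify_stage_dynamics(ps, min_group = 0)
    want <- oracle_dynamics_presence(dd[, c("chrom", "start", "end")], ps)
    expect_equal(unname(as.matrix(dd[, c("GSC", "SCI", "RS")])),
                 unname(want))
  }

  expect_error(classify_stage_dynamics(setNames(stages, c("a", "a", "b"))),
               "unique")
  expect_error(classify_stage_dynamics(stages[1]), "2 stages")
})

test_that("minor groups are flagged at the count threshold", {
  stages <- list(
    A = data.frame(chrom = "chr1", start = seq(0, 990, 10) * 100,
                   end = seq(0, 990, 10) * 100 + 500),
    B = data.frame(chrom = "chr1", start = 1, end = 2))
  dyn <- classify_stage_dynamics(stages, min_group = 100)
  counts <- table(dyn$class)
  expect_true(all(dyn$minor[dyn$class %in%
                              names(counts)[counts <= 100]]))
  expect_false(any(dyn$minor[dyn$class %in%
                               names(counts)[counts > 100]]))
})

test_that("tss_profile is flat for constant signal and respects strand", {
  asm <- genome_assembly("chr1", 2e5)
  genes <- simulate_genome(asm, 40, seed = 7)
  expression <- setNames(rlnorm(40, 3, 1), genes$gene_id)
  const <- signal_track(list(chr1 = rep(2.5, 1000)), 200)
  prof <- tss_profile(const, genes, expression, n_groups = 4)
  expect_true(all(abs(prof[!is.na(prof)] - 2.5) < 1e-12))

  # flipping every strand leaves a symmetric profile unchanged
  genes_f <- genes
  genes_f$strand <- ifelse(genes$strand == "+", "-", "+")
  genes_f$tss <- ifelse(genes_f$strand == "+", genes_f$start,
                        genes_f$end - 1)
  prof_f <- tss_profile(const, genes_f, expression, n_groups = 4)
  expect_equal(prof[!is.na(prof)], prof_f[!is.na(prof_f)])
})

test_that("tss_profile group means are ordered under a planted monotone
           signal-expression coupling", {
  asm <- genome_assembly("chr1", 2e6)
  genes <- simulate_genome(asm, 150, seed = 8)
  set.seed(8)
  expression <- setNames(rlnorm(150, 3, 1), genes$gene_id)
  vals <- rep(0.05, 1e4)
  for (i in seq_len(nrow(genes))) {
    b <- (floor(genes$start[i] / 200) + 1):ceiling(genes$end[i] / 200)
    vals[b] <- vals[b] + expression[genes$gene_id[i]] / 20
  }
  prof <- tss_profile(signal_track(list(chr1 = vals), 200), genes,
                      expression)
  body_means <- rowMeans(prof[, grep("^body", attr(prof, "positions"))],
                         na.rm = TRUE)
  expect_true(all(diff(body_means) > 0))
})
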