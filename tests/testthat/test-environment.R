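test_that("assign_region_state picks the max-coverage state with the
           documented tie-break", {
  seg <- data.frame(chrom = "chr1",
                    start = c(0, 6000), end = c(6000, 10000),
                    state = c("TxWk", "Quies"))
  r <- assign_region_state(data.frame(chrom = "chr1", start = 2000,
                                      end = 12000), seg)
  expect_equal(r$state, "TxWk")
  expect_equal(r$coverage_fraction, 0.4)

  # exact 50/50: EnhA wins over Quies by the priority list
  seg2 <- data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 1000),
                     state = c("Quies", "EnhA"))
  r2 <- assign_region_state(data.frame(chrom = "chr1", start = 0,
                                       end = 1000), seg2)
  expect_equal(r2$state, "EnhA")
  expect_equal(r2$second_state, "Quies")
  expect_equal(r2$second_fraction, 0.5)

  # fully unannotated region
  r3 <- assign_region_state(data.frame(chrom = "chr1", start = 20000,
                                       end = 21000), seg)
  expect_equal(r3$state, "unannotated")

  # runner-up never exceeds the winner
  set.seed(31)
  seg <- random_segmentation(40000, mean_run = 900)
  regions <- random_intervals(60, 38000, max_len = 6000)
  rr <- assign_region_state(regions, seg)
  ok <- !is.na(rr$second_state)
  expect_true(all(rr$second_fraction[ok] <= rr$coverage_fraction[ok]))
})

test_that("assign_region_state equals the per-base counting oracle", {
  set.seed(32)
  for (rep in 1:3) {
    seg <- random_segmentation(30000, mean_run = 700)
    regions <- random_intervals(80, 28000, max_len = 4000)
    got <- assign_region_state(regions, seg)
    for (i in seq_len(nrow(regions))) {
      want <- oracle_region_state(regions[i, ], seg, 30000)
      expect_equal(got$state[i], want$state)
      expect_equal(got$coverage_fraction[i], want$fraction)
    }
  }
})

test_that("gene_promoter_environment assigns the TSS window state", {
  seg <- data.frame(chrom = "chr1", start = 0, end = 20000,
                    state = "TssBiv")
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 9000,
                      end = 12000, strand = "+", tss = 9000)
  env <- gene_promoter_environment(genes, seg)
  expect_equal(env$predominant_state, "TssBiv")
  expect_equal(env$coverage_fraction, 1)

  # TSS near the chromosome start: window is clipped, fraction still of the
  # clipped window
  asm <- genome_assembly("chr1", 20000)
  genes2 <- data.frame(gene_id = "g2", chrom = "chr1", start = 500,
                       end = 2000, strand = "+", tss = 500)
  env2 <- gene_promoter_environment(genes2, seg, assembly = asm)
  expect_equal(env2$coverage_fraction, 1)
})

test_that("split_regions_by_mark partitions by >= 1 bp overlap", {
  regions <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                        end = c(500, 1500, 2500))
  peaks <- data.frame(chrom = "chr1", start = c(0, 1499), end = c(500, 1500))
  sp <- split_regions_by_mark(regions, peaks)
  expect_equal(sp$status, c("+", "+", "-"))
  sp0 <- split_regions_by_mark(regions, peaks[0, ])
  expect_equal(sp0$status, c("-", "-", "-"))
})

test_that("classify_enhancers emits one record per enhancer run", {
  seg <- data.frame(chrom = "chr1",
                    start = c(0, 1000, 3000, 4000),
                    end = c(1000, 3000, 4000, 8000),
                    state = c("Quies", "EnhA", "Tx", "EnhG"))
  attr(seg, "label_vocabulary") <- chrom_states_13()
  peaks <- data.frame(chrom = "chr1", start = 4100, end = 4200)
  enh <- classify_enhancers(seg, peaks)
  expect_equal(nrow(enh), 2)
  expect_equal(enh$class, c("EnhA", "EnhG"))
  expect_equal(enh$h3k79me2, c("-", "+"))

  seg_none <- data.frame(chrom = "chr1", start = 0, end = 100,
                         state = "Quies")
  attr(seg_none, "label_vocabulary") <- c("Quies", "Tx")
  expect_error(classify_enhancers(seg_none), "no enhancer states")

  # record count equals a per-bin run oracle on a random segmentation
  set.seed(33)
  rseg <- random_segmentation(30000, mean_run = 600)
  want <- sum(rseg$state %in% c("EnhA", "EnhG", "EnhW", "EnhBiv"))
  expect_equal(nrow(classify_enhancers(rseg)), want)
})

test_that("enhancer-gene links respect distance, mode and ties", {
  enh <- data.frame(enhancer_id = "e1", chrom = "chr1",
                    start = 200000, end = 201000, class = "EnhA")
  genes <- data.frame(
    gene_id = c("near", "far", "out", "inside"),
    chrom = "chr1",
    start = c(251000, 281000, 301001, 200500),
    end = c(252000, 282000, 302000, 200800),
    strand = "+", tss = c(251000, 281000, 301001, 200500))
  all_links <- link_enhancer_genes(enh, genes, mode = "all")
  expect_setequal(all_links$gene_id, c("near", "far", "inside"))
  expect_equal(all_links$distance[all_links$gene_id == "inside"], 0)
  expect_equal(all_links$distance[all_links$gene_id == "near"], 50000)
  # 100,001 bp away is excluded (boundary is inclusive at 100,000)
  expect_false("out" %in% all_links$gene_id)

  nearest <- link_enhancer_genes(enh, genes, mode = "nearest")
  expect_equal(nearest$gene_id, "inside")

  # exact tie: both genes reported and flagged
  genes_tie <- data.frame(gene_id = c("L", "R"), chrom = "chr1",
                          start = c(190000, 206000),
                          end = c(195000, 215000),
                          strand = "+", tss = c(190000, 206000))
  tie <- link_enhancer_genes(enh, genes_tie, mode = "nearest")
  expect_equal(nrow(tie), 2)
  expect_true(all(tie$tie))
})

test_that("enhancer-gene links match a brute-force distance scan", {
  set.seed(34)
  asm <- genome_assembly("chr1", 5e5)
  genes <- simulate_genome(asm, 30, seed = 10)
  enh <- random_intervals(25, 490000, max_len = 2000)
  enh$enhancer_id <- paste0("e", seq_len(nrow(enh)))
  enh$class <- "EnhA"
  links <- link_enhancer_genes(enh, genes, mode = "all")
  for (i in seq_len(nrow(enh))) {
    gap <- pmax(genes$start - enh$end[i], enh$start[i] - genes$end, 0)
    want <- genes$gene_id[gap <= 100000]
    got <- links$gene_id[links$enhancer_id == enh$enhancer_id[i]]
    expect_setequal(got, want)
  }
})

test_that("enhancer expression contrasts mark-positive vs negative classes", {
  enh <- data.frame(enhancer_id = paste0("e", 1:6),
                    class = "EnhA",
                    h3k79me2 = c("+", "+", "+", "-", "-", "-"))
  links <- data.frame(enhancer_id = paste0("e", 1:6),
                      gene_id = paste0("g", 1:6), distance = 0)
  expr <- setNames(rep(4, 6), paste0("g", 1:6))
  ee <- enhancer_expression(enh, links, expr)
  expect_equal(ee$tests$mean_pos, ee$tests$mean_neg)
  expect_equal(ee$tests$p, 1)
  # single-gene link: enhancer mean is that gene's cpm
  expect_equal(ee$per_enhancer$mean_cpm, unname(expr))

  # planted 2x mean near "+" enhancers is detected at n = 200 per group
  set.seed(35)
  n <- 200
  enh2 <- data.frame(enhancer_id = paste0("e", 1:(2 * n)), class = "EnhA",
                     h3k79me2 = rep(c("+", "-"), each = n))
  links2 <- data.frame(enhancer_id = enh2$enhancer_id,
                       gene_id = paste0("g", 1:(2 * n)), distance = 0)
  expr2 <- setNames(c(rlnorm(n, log(20), 0.8), rlnorm(n, log(10), 0.8)),
                    links2$gene_id)
  ee2 <- enhancer_expression(enh2, links2, expr2)
  expect_gt(ee2$tests$mean_pos, ee2$tests$mean_neg)
  expect_lt(ee2$tests$p, 0.05)
})

test_that("under a null mark placement the expression contrast p-values are
           uniform", {
  set.seed(36)
  ps <- replicate(200, {
    enh <- data.frame(enhancer_id = paste0("e", 1:60), class = "EnhA",
                      h3k79me2 = sample(rep(c("+", "-"), 30)))
    links <- data.frame(enhancer_id = enh$enhancer_id,
                        gene_id = paste0("g", 1:60), distance = 0)
    expr <- setNames(rlnorm(60, 3, 1), links$gene_id)
    enhancer_expression(enh, links, expr)$tests$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("gene-level mark categories partition genes and follow the rules", {
  genes <- data.frame(gene_id = c("gb", "enh", "both", "none"),
                      chrom = "chr1",
                      start = c(0, 10000, 20000, 30000),
                      end = c(5000, 15000, 25000, 35000),
                      strand = "+", tss = c(0, 10000, 20000, 30000))
  peaks <- data.frame(chrom = "chr1", start = c(100, 20100),
                      end = c(200, 20200))
  enh <- data.frame(enhancer_id = c("e1", "e2"), chrom = "chr1",
                    start = c(16000, 26000), end = c(16500, 26500),
                    class = "EnhA", h3k79me2 = c("+", "+"))
  links <- data.frame(enhancer_id = c("e1", "e1", "e2"),
                      gene_id = c("enh", "both", "both"), distance = 1000)
  cat <- h3k79_gene_category(genes, peaks, enh, links)$category
  expect_equal(unname(cat), c("GB", "ENH", "GB-ENH", "none"))
  expect_setequal(names(cat), genes$gene_id)
})
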