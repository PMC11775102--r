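test_that("binarize_track applies the exact Poisson tail rule", {
  expect_equal(binarize_track(0L, global_rate = 5), 0L)
  # smallest flagged count is the minimal k with P(X >= k) <= 1e-4
  lambda <- 1
  k_min <- min(which(ppois(0:50 - 1, lambda, lower.tail = FALSE) <= 1e-4)) - 1
  counts <- 0:20
  got <- binarize_track(counts, lambda)
  expect_equal(got, as.integer(counts >= k_min))
  # exact tail oracle on a grid of counts and rates
  for (lam in c(0.5, 2, 10)) {
    counts <- 0:40
    want <- as.integer(sapply(counts, function(k)
      sum(dpois(k:200, lam))) <= 1e-4)
    expect_equal(binarize_track(counts, lam), want)
  }
  expect_error(binarize_track(c(1.5, 2), 1), "integers")
  expect_error(binarize_track(1L, 0), "global_rate")
})

test_that("single-state fit equals empirical mark frequencies exactly", {
  set.seed(21)
  X <- matrix(rbinom(600, 1, c(0.3, 0.7, 0.1)), 200, 3, byrow = TRUE,
              dimnames = list(NULL, c("m1", "m2", "m3")))
  tr <- binarized_tracks(list(chr1 = X), 200)
  fit <- fit_state_model(tr, 1, seed = 1)
  expect_equal(unname(fit$emission[1, ]), unname(colMeans(X)))
})

test_that("EM log-likelihood is monotone and fits are seed-reproducible", {
  em <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2,
               dimnames = list(NULL, c("m1", "m2")))
  m0 <- state_model(em, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
  sim <- simulate(m0, seed = 5, assembly = genome_assembly("chr1", 6e5))
  fit1 <- fit_state_model(sim$tracks, 2, seed = 3, n_restarts = 2)
  expect_true(all(diff(fit1$ll_trace) > -1e-6))
  fit2 <- fit_state_model(sim$tracks, 2, seed = 3, n_restarts = 2)
  expect_identical(fit1$emission, fit2$emission)
  expect_identical(fit1$transition, fit2$transition)
  # recovery within 0.05 after best state matching
  mt <- match_states(fit1$emission, em)
  expect_lt(mt$max_abs_err, 0.05)
})

test_that("decoding recovers a deterministic-emission truth exactly", {
  em <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(NULL, c("m1", "m2")))
  m0 <- state_model(em, matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE))
  asm <- genome_assembly("chr1", 1e5)
  sim <- simulate(m0, seed = 9, assembly = asm)
  seg <- decode_segmentation(m0, sim$tracks, asm)
  expect_identical(seg, sim$truth)
})

test_that("decoding a single-bin chromosome yields one run", {
  em <- matrix(c(0.9, 0.1), 2, 1, dimnames = list(NULL, "m1"))
  m0 <- state_model(em, matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2))
  X <- matrix(1L, 1, 1, dimnames = list(NULL, "m1"))
  tr <- binarized_tracks(list(chr1 = X), 200)
  seg <- decode_segmentation(m0, tr)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$end - seg$start, 200)
})

test_that("decode rejects mark mismatches", {
  em <- matrix(0.5, 2, 2, dimnames = list(NULL, c("a", "b")))
  m0 <- state_model(em, diag(2) * 0.8 + 0.1)
  X <- matrix(0L, 5, 2, dimnames = list(NULL, c("a", "c")))
  tr <- binarized_tracks(list(chr1 = X), 200)
  expect_error(decode_segmentation(m0, tr), "marks")
})

test_that("posterior decoding still tiles the genome when states are
           indistinguishable", {
  em <- matrix(0.5, 2, 2, dimnames = list(NULL, c("a", "b")))
  m0 <- state_model(em, matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2))
  set.seed(4)
  X <- matrix(rbinom(60, 1, 0.5), 30, 2, dimnames = list(NULL, c("a", "b")))
  tr <- binarized_tracks(list(chr1 = X), 200)
  seg <- decode_segmentation(m0, tr)
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[nrow(seg)], 30 * 200)
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)]))
})

test_that("forward-backward posteriors sum to one at every bin", {
  set.seed(31)
  em <- matrix(runif(12, 0.1, 0.9), 3, 4)
  tpm <- matrix(runif(9), 3, 3)
  tpm <- tpm / rowSums(tpm)
  X <- matrix(rbinom(200, 1, 0.4), 50, 4)
  logE <- X %*% t(log(em)) + (1 - X) %*% t(log(1 - em))
  fb <- chromdyn:::hmm_forward_backward_cpp(logE, tpm, rep(1 / 3, 3))
  expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-8))
  # log-likelihood matches direct summation over paths on a tiny case
  logE2 <- logE[1:4, ]
  states <- expand.grid(1:3, 1:3, 1:3, 1:3)
  probs <- apply(states, 1, function(s) {
    p <- log(1 / 3) + logE2[1, s[1]]
    for (t in 2:4) p <- p + log(tpm[s[t - 1], s[t]]) + logE2[t, s[t]]
    exp(p)
  })
  fb2 <- chromdyn:::hmm_forward_backward_cpp(logE2, tpm, rep(1 / 3, 3))
  expect_equal(fb2$loglik, log(sum(probs)), tolerance = 1e-10)
})

test_that("pool_states merges adjacent runs and is monotone", {
  seg <- data.frame(chrom = "chr1",
                    start = c(0, 200, 400, 600),
                    end = c(200, 400, 600, 1000),
                    state = c("EnhG1", "EnhG2", "TSSA", "Quies1"))
  pooled <- pool_states(seg)
  expect_equal(pooled$state, c("EnhG", "TSSA", "Quies"))
  expect_equal(pooled$end[1], 400)
  expect_lte(nrow(pooled), nrow(seg))

  idmap <- setNames(unique(seg$state), unique(seg$state))
  expect_equal(pool_states(seg, idmap)$state, seg$state)

  expect_error(pool_states(seg, c(EnhG1 = "EnhG")), "lacks label")
})

test_that("state categories form a total partition of the 13 labels", {
  expect_equal(categorize_state("Tx"), "active")
  expect_equal(categorize_state("TssBiv"), "bivalent")
  cats <- categorize_state(chrom_states_13())
  expect_equal(length(cats), 13)
  expect_setequal(unique(cats),
                  c("active", "weak", "heterochromatin", "bivalent",
                    "polycomb", "quiescent"))
  expect_error(categorize_state("NotAState"), "unknown")
})

test_that("simulated paths reproduce the generating transition matrix", {
  em <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
               dimnames = list(c("A", "B"), c("m1", "m2")))
  tpm <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, 2, byrow = TRUE)
  m0 <- state_model(em, tpm)
  sim <- simulate(m0, seed = 13, assembly = genome_assembly("chr1", 4e6))
  seg <- sim$truth
  # reconstruct the per-bin path and count transitions
  path <- rep(seg$state, (seg$end - seg$start) / 200)
  trans <- table(head(path, -1), tail(path, -1))
  est <- trans / rowSums(trans)
  expect_lt(max(abs(est[c("A", "B"), c("A", "B")] - tpm)), 0.01)
  # mark frequencies match stationary-weighted emissions
  statn <- table(path) / length(path)
  want <- as.numeric(statn[c("A", "B")] %*% em)
  got <- colMeans(sim$tracks$bins$chr1)
  expect_lt(max(abs(got - want)), 0.01)
})

test_that("tracks survive a write/read round trip", {
  set.seed(41)
  X <- matrix(rbinom(40, 1, 0.5), 20, 2, dimnames = list(NULL, c("a", "b")))
  tr <- binarized_tracks(list(chr1 = X), 200)
  pre <- tempfile()
  write_tracks(tr, pre)
  tr2 <- read_tracks(pre, "chr1", 200)
  expect_equal(tr2$bins$chr1, X)

  seg <- data.frame(chrom = "chr1", start = c(0, 400), end = c(400, 4000),
                    state = c("TSSA", "Quies"))
  f <- tempfile()
  write_segmentation(seg, f)
  seg2 <- read_segmentation(f, genome_assembly("chr1", 4000))
  expect_equal(seg2, seg)
})
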