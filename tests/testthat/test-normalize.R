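test_that("TMM absorbs pure depth differences and ignores row order", {
  set.seed(1)
  a <- rpois(200, rlnorm(200, 4, 1)) + 1
  counts <- cbind(A = a, B = 2L * a)
  rownames(counts) <- paste0("t", seq_len(200))
  f <- tmm_factors(counts)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)

  perm <- sample(nrow(counts))
  f2 <- tmm_factors(counts[perm, ])
  expect_equal(f, f2, tolerance = 1e-12)
})

test_that("TMM with zero trims equals the hand-computed weighted M/A mean", {
  counts <- matrix(c(100, 100,
                     200, 200,
                     300, 300,
                     400, 400,
                     100, 400),
                   ncol = 2, byrow = TRUE,
                   dimnames = list(paste0("t", 1:5), c("A", "B")))
  nA <- sum(counts[, 1]); nB <- sum(counts[, 2])
  # oracle: untrimmed inverse-variance-weighted mean of M against library A
  M <- log2((counts[, 2] / nB) / (counts[, 1] / nA))
  v <- (nB - counts[, 2]) / nB / counts[, 2] +
       (nA - counts[, 1]) / nA / counts[, 1]
  fB <- 2^(sum(M / v) / sum(1 / v))
  expected <- c(1, fB) / exp(mean(log(c(1, fB))))
  f <- tmm_factors(counts, ref_library = "A",
                   logratio_trim = 0, abs_trim = 0)
  expect_equal(unname(f), unname(expected), tolerance = 1e-10)
})

test_that("TMM matches the reference edgeR implementation", {
  set.seed(7)
  counts <- matrix(rnbinom(300 * 6, mu = rlnorm(300, 4, 1.5), size = 2),
                   300, 6, dimnames = list(paste0("t", 1:300), paste0("L", 1:6)))
  counts <- counts[rowSums(counts) > 0, ]
  f <- tmm_factors(counts)
  fe <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(f), unname(fe), tolerance = 1e-10)
})

test_that("TMM rejects all-zero libraries", {
  counts <- matrix(c(1, 2, 0, 0), 2, 2,
                   dimnames = list(c("t1", "t2"), c("A", "B")))
  expect_error(tmm_factors(counts), "all-zero")
})

test_that("CPM follows its defining formula and scaling contract", {
  counts <- matrix(c(10, 0, 20, 5), 2, 2, byrow = TRUE,
                   dimnames = list(c("t1", "t2"), c("A", "B")))
  cpm <- compute_cpm(counts, c(A = 1, B = 1), library_size = c(A = 1e7, B = 1e7))
  expect_equal(cpm["t1", "A"], 1)
  expect_equal(cpm["t2", "A"], 2)
  expect_equal(cpm["t1", "B"], 0)
  cpm2 <- compute_cpm(counts, c(A = 2, B = 1), library_size = c(A = 1e7, B = 1e7))
  expect_equal(cpm2[, "A"], cpm[, "A"] / 2)
  expect_equal(cpm2[, "B"], cpm[, "B"])
})

test_that("low-expression filter keeps the >= 1 CPM boundary", {
  cpm <- rbind(t_low = c(0.9, 0.9, 0.9),
               t_edge = c(0.9, 0.9, 1.0),
               t_high = c(5, 5, 5))
  expect_setequal(low_expression_filter(cpm), c("t_edge", "t_high"))
  expect_identical(low_expression_filter(cpm[0, , drop = FALSE]), character(0))
})

test_that("FPKM follows its defining formula, multiplicatively normalized", {
  counts <- matrix(c(100, 1), 2, 1, dimnames = list(c("t1", "t2"), "A"))
  fpkm <- compute_fpkm(counts, c(A = 1),
                       effective_length = c(t1 = 2000, t2 = 1000),
                       library_size = c(A = 1e7))
  expect_equal(fpkm["t1", "A"], 5)
  counts2 <- matrix(1, 1, 1, dimnames = list("t1", "A"))
  expect_equal(compute_fpkm(counts2, c(A = 1), c(t1 = 1000), c(A = 1e6))[1, 1], 1)
  # multiply vs divide convention
  f2 <- compute_fpkm(counts, c(A = 2), c(t1 = 2000, t2 = 1000), c(A = 1e7))
  expect_equal(f2["t1", "A"], 10)
  f3 <- compute_fpkm(counts, c(A = 2), c(t1 = 2000, t2 = 1000), c(A = 1e7),
                     apply = "divide")
  expect_equal(f3["t1", "A"], 2.5)
  expect_error(compute_fpkm(counts, c(A = 1), c(t1 = 0, t2 = 1000), c(A = 1e7)),
               "> 0")
})

test_that("FPKM recovers simulated input in expectation (Poisson round trip)", {
  set.seed(42)
  n <- 10000
  profile <- matrix(5, n, 1, dimnames = list(paste0("t", 1:n), "MA"))
  len <- setNames(rep(2000, n), rownames(profile))
  cm <- simulate_counts(profile, c(MA = 1L), 1e7, len, nb_dispersion = 0)
  fpkm <- compute_fpkm(cm, setNames(1, colnames(cm$counts)),
                       library_size = setNames(1e7, colnames(cm$counts)))
  # mu = 100 per transcript; SE of mean FPKM = 5/sqrt(100 n)
  expect_lt(abs(mean(fpkm) - 5), 3 * 5 / sqrt(100 * n))
})

test_that("mean tissue FPKM averages replicates and stays within their range", {
  fpkm <- matrix(c(4, 6, 1, 3,
                   0, 0, 2, 2), 2, 4, byrow = TRUE,
                 dimnames = list(c("t1", "t2"), paste0("L", 1:4)))
  samples <- data.frame(library = paste0("L", 1:4), species = "Lg",
                        tissue = c("MA", "MA", "Ceph", "Ceph"),
                        replicate = c(1, 2, 1, 2))
  prof <- mean_tissue_fpkm(fpkm, samples)
  expect_equal(prof["t1", "MA"], 5)
  expect_equal(prof["t1", "Ceph"], 2)
  expect_equal(prof["t2", "MA"], 0)
  expect_true(all(prof >= apply(fpkm, 1, min) - 1e-12) &&
              all(prof <= apply(fpkm, 1, max) + 1e-12))
  # single-replicate tissue passes through
  s1 <- samples[c(1, 3, 4), ]
  prof1 <- mean_tissue_fpkm(fpkm[, c(1, 3, 4)], s1)
  expect_equal(prof1["t1", "MA"], 4)
})

test_that("CPM of unchanged transcripts is invariant to rescaling one library", {
  set.seed(3)
  counts <- matrix(rpois(400, rlnorm(400, 4, 1)) + 1, 100, 4,
                   dimnames = list(paste0("t", 1:100), paste0("L", 1:4)))
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 5L
  # exact with the unweighted trimmed mean (M-values are depth-invariant)
  f <- tmm_factors(counts, weighted = FALSE)
  f2 <- tmm_factors(counts2, weighted = FALSE)
  cpm <- compute_cpm(counts, f)
  cpm2 <- compute_cpm(counts2, f2)
  expect_equal(cpm, cpm2, tolerance = 1e-12)
  # with inverse-variance weighting the invariance is only approximate,
  # because the weights see the absolute counts
  fw <- tmm_factors(counts)
  fw2 <- tmm_factors(counts2)
  cw <- compute_cpm(counts, fw)
  cw2 <- compute_cpm(counts2, fw2)
  expect_equal(cw, cw2, tolerance = 0.05)
})
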