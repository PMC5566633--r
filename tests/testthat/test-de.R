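test_that("exact test reduces to the conditional binomial at dispersion 0", {
  # spot grid here; the exhaustive total <= 200 sweep is an acceptance criterion
  for (t in c(1, 7, 30)) {
    for (za in 0:t) {
      p <- silkshift:::.nb_exact_p(za, t - za, 2, 3, 0)
      expect_equal(p, binom.test(za, t, 2 / 5)$p.value, tolerance = 1e-12)
    }
  }
  expect_equal(silkshift:::.nb_exact_p(0, 10, 1, 1, 0), 2 * 0.5^10)
})

test_that("exact test is symmetric, null at equality, widened by dispersion", {
  expect_equal(silkshift:::.nb_exact_p(3, 9, 2, 2, 0.4),
               silkshift:::.nb_exact_p(9, 3, 2, 2, 0.4))
  # identical counts in both groups
  counts <- matrix(c(5, 5), 1, 2, dimnames = list("t1", c("A", "B")))
  p <- nb_exact_test(counts[, 1, drop = FALSE], counts[, 2, drop = FALSE],
                     c(A = 100), c(B = 100), dispersion = 0.4)
  expect_equal(unname(p), 1)
  # overdispersion makes the same outcome less surprising
  expect_gt(silkshift:::.nb_exact_p(2, 20, 1, 1, 0.4),
            silkshift:::.nb_exact_p(2, 20, 1, 1, 0))
  expect_error(nb_exact_test(counts[, 1, drop = FALSE], counts[, 2, drop = FALSE],
                             dispersion = -1), ">= 0")
})

test_that("BH adjustment matches the hand step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.02, 0.9, 0.04)
  expect_true(all(diff(sort(bh_fdr(p))) >= 0))
  expect_true(all(bh_fdr(p) >= p))
})

test_that("common dispersion is 0 for identical replicates and recovers truth", {
  counts <- matrix(rep(c(10, 50, 200, 7), 2), ncol = 2,
                   dimnames = list(paste0("t", 1:4), c("A", "B")))
  expect_equal(estimate_common_dispersion(counts, c("g", "g")), 0)
  expect_error(estimate_common_dispersion(counts, c("g1", "g2")),
               "replication")

  set.seed(5)
  mu <- rlnorm(1500, log(100), 1)
  y <- vapply(1:4, function(i) rnbinom(1500, mu = mu, size = 1 / 1.5),
              numeric(1500))
  dimnames(y) <- list(paste0("t", 1:1500), paste0("L", 1:4))
  est <- estimate_common_dispersion(y, c("a", "a", "b", "b"),
                                    rep(sum(mu), 4))
  expect_lt(abs(est - 1.5) / 1.5, 0.1)

  yp <- vapply(1:4, function(i) rpois(1500, mu), numeric(1500))
  dimnames(yp) <- dimnames(y)
  expect_lt(estimate_common_dispersion(yp, c("a", "a", "b", "b"),
                                       rep(sum(mu), 4)), 0.02)
})

test_that("tagwise dispersion shrinks toward common and tracks disagreement", {
  set.seed(8)
  y <- matrix(rnbinom(200 * 4, mu = 50, size = 2), 200, 4,
              dimnames = list(paste0("t", 1:200), paste0("L", 1:4)))
  groups <- c("a", "a", "b", "b")
  common <- estimate_common_dispersion(y, groups, rep(2e4, 4))
  tw_inf <- estimate_tagwise_dispersion(y, groups, common, Inf, rep(2e4, 4))
  expect_true(all(tw_inf == common))

  # prior weight 0, single transcript: matches an independent grid search of
  # the conditional (Dirichlet-multinomial) likelihood
  y1 <- y[7, , drop = FALSE]
  tw0 <- estimate_tagwise_dispersion(y1, groups, common, 0, rep(2e4, 4))
  grid <- exp(seq(log(1e-4), log(30), length.out = 301))
  ll <- vapply(grid, function(phi) {
    r <- 1 / phi
    sum(vapply(c("a", "b"), function(g) {
      yy <- y1[, groups == g]
      sum(lgamma(yy + r)) - 2 * lgamma(r) -
        lgamma(sum(yy) + 2 * r) + lgamma(2 * r)
    }, 0))
  }, 0)
  expect_equal(unname(tw0), grid[which.max(ll)])

  # a transcript with larger replicate disagreement gets >= tagwise dispersion
  y2 <- rbind(t_tight = c(100, 100, 100, 100),
              t_loose = c(20, 180, 30, 170))
  colnames(y2) <- paste0("L", 1:4)
  tw <- estimate_tagwise_dispersion(y2, groups, common = 0.2,
                                    prior_weight = 2, rep(400, 4))
  expect_gte(tw["t_loose"], tw["t_tight"])
})

test_that("twofold silk flag uses the strict-ratio and zero conventions", {
  prof <- rbind(
    boundary = c(14, 0, 0, 0, 0, 0, 0, 1, 1, 1), # silk mean 2, non-silk 1
    silent   = c(rep(0, 7), 1, 1, 1),
    zero_den = c(rep(2, 7), 0, 0, 0),
    zerozero = rep(0, 10),
    low      = c(rep(0.8, 7), 0.1, 0.1, 0.1))
  colnames(prof) <- c(silk_gland_types(), non_silk_tissues())
  fl <- twofold_silk_flag(prof)
  expect_equal(fl$twofold_silk,
               c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(fl$fpkm_gt1, c(TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("OEST calling filters first and flags planted silk genes", {
  set.seed(11)
  des <- study_design()
  base <- rlnorm(400, log(20), 1)
  prof <- matrix(base, 400, 10,
                 dimnames = list(paste0("t", 1:400), des$tissues))
  prof[1:20, des$silk] <- pmax(prof[1:20, des$silk], 10) * 10
  prof[400, ] <- 0.0001 # below the CPM filter everywhere
  len <- setNames(rep(1500, 400), rownames(prof))
  cm <- simulate_counts(prof, des$replicates, 1e7, len, 0.4, species = "Lg")
  res <- call_oests(cm)
  expect_false("t400" %in% res$transcript)
  expect_gte(mean(res$oest_flag[match(paste0("t", 1:20), res$transcript)]), 0.9)
  expect_true(all(res$FDR >= res$PValue))
  expect_true(all(res$FDR >= 0 & res$FDR <= 1))
  # every OEST is silk-overrepresented and below the FDR threshold
  expect_true(all(res$logFC[res$oest_flag] > 0))
  expect_true(all(res$FDR[res$oest_flag] < 0.05))
})

test_that("per-gland contrasts fix dispersion at 0.4 when unreplicated", {
  set.seed(12)
  des <- study_design()
  prof <- matrix(rlnorm(200, log(20), 1), 200, 10,
                 dimnames = list(paste0("t", 1:200), des$tissues))
  len <- setNames(rep(1500, 200), rownames(prof))
  cm <- simulate_counts(prof, des$replicates, 1e7, len, 0.4, species = "Lg")
  unrep <- per_gland_contrast(cm, "Py") # 1 replicate by design
  expect_true(all(unrep$dispersion == 0.4))
  expect_true(all(unrep$dispersion_source == "fixed"))
  rep2 <- per_gland_contrast(cm, "MA") # 2 replicates
  expect_true(all(rep2$dispersion_source == "tagwise"))
  expect_error(per_gland_contrast(cm, "NotAGland"), "unknown gland")
})
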