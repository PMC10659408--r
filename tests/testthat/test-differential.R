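test_that("min-count filtering applies the stated strictness", {
  m <- matrix(c(45, 46, 45, 45), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  expect_equal(filter_min_counts(m, 90, strict = TRUE), "g1")   # 91 > 90, 90 fails
  expect_setequal(filter_min_counts(m, 90, strict = FALSE), c("g1", "g2"))
  expect_setequal(filter_min_counts(m, 0, strict = FALSE), c("g1", "g2"))
  # brute-force oracle over random matrices
  set.seed(1)
  for (i in 1:10) {
    mm <- matrix(rpois(60, 5), nrow = 10,
                 dimnames = list(paste0("g", 1:10), NULL))
    thr <- sample(10:40, 1)
    expect_setequal(filter_min_counts(mm, thr),
                    rownames(mm)[sapply(1:10, function(r) sum(mm[r, ]) > thr)])
  }
})

test_that("BH adjustment matches the step-up definition and the reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(3:60, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
  expect_error(bh_adjust(c(0.1, 1.5)), "\\[0, 1\\]")
})

test_that("dispersion estimation recovers the Poisson and NB regimes", {
  cond <- rep(c("A", "B"), each = 3)
  sf <- rep(1, 6)
  pois <- sim_nb_counts(2000, 3, mu = 100, disp = 1e-8, seed = 2)
  dp <- estimate_dispersions(pois, sf, cond)
  expect_lte(median(dp$shrunken), 0.01)

  nb <- sim_nb_counts(2000, 3, mu = 100, disp = 0.1, seed = 3)
  dn <- estimate_dispersions(nb, sf, cond)
  expect_gte(median(dn$shrunken), 0.05)
  expect_lte(median(dn$shrunken), 0.2)

  const <- matrix(7, nrow = 3, ncol = 6,
                  dimnames = list(c("a", "b", "c"), NULL))
  dc <- estimate_dispersions(const, sf, cond)
  expect_equal(unname(dc$raw), rep(dc$floor, 3))
  expect_error(estimate_dispersions(const, sf, letters[1:6]),
               ">= 2 replicates")
})

test_that("the Wald test is symmetric, label-consistent and size-factor invariant", {
  counts <- sim_nb_counts(200, 3, mu = 50, disp = 0.05, seed = 4)
  cond <- rep(c("A", "B"), each = 3)
  sf <- rep(1, 6)
  # identical groups: mirror the A replicates into B
  mirror <- cbind(counts[, 1:3], counts[, 1:3])
  res <- nb_wald_test(mirror, sf, cond, rep(0.05, 200))
  expect_equal(res$log2FC, rep(0, 200))
  expect_equal(res$pvalue, rep(1, 200))

  disp <- estimate_dispersions(counts, sf, cond)
  ab <- nb_wald_test(counts, sf, factor(cond, levels = c("A", "B")), disp)
  ba <- nb_wald_test(counts, sf, factor(cond, levels = c("B", "A")), disp)
  expect_equal(ab$log2FC, -ba$log2FC, tolerance = 1e-8)
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-8)

  # multiplying one sample's counts and its size factor by the same
  # constant leaves normalized quantities identical; the NB Wald test is
  # exactly invariant only in the equal-information limit (the rescaled
  # sample genuinely carries more counts), so the test statistics agree
  # closely but not bit-for-bit
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 5
  sf2 <- sf
  sf2[2] <- 5
  r1 <- nb_wald_test(counts, sf, cond, disp)
  r2 <- nb_wald_test(counts2, sf2, cond, disp)
  expect_equal(rowMeans(sweep(counts2, 2, sf2, "/")),
               rowMeans(sweep(counts, 2, sf, "/")))
  expect_equal(r2$baseMean, r1$baseMean)
  # the estimates track each other and the thresholded calls agree
  expect_gt(cor(r1$log2FC, r2$log2FC), 0.99)
  expect_identical(r1$class, r2$class)

  zero <- matrix(0, 2, 6, dimnames = list(c("z1", "z2"), NULL))
  rz <- nb_wald_test(zero, sf, cond, rep(0.05, 2))
  expect_equal(rz$pvalue, c(1, 1))
  expect_equal(rz$log2FC, c(0, 0))
  expect_true(all(rz$zero_flag))
})

test_that("planted fold changes are detected with high sensitivity", {
  set.seed(10)
  n <- 2000
  planted <- sample(n, 200)
  fc <- rep(1, n)
  fc[planted] <- 4
  counts <- sim_nb_counts(n, 3, mu = 100, disp = 0.05, fc = fc, seed = 11)
  cond <- rep(c("A", "B"), each = 3)
  sf <- rep(1, 6)
  disp <- estimate_dispersions(counts, sf, cond)
  res <- nb_wald_test(counts, sf, cond, disp)
  called <- classify_significant(res)$up
  sens <- length(intersect(called, rownames(counts)[planted])) / length(planted)
  expect_gte(sens, 0.9)
})

test_that("significance classification applies both gates", {
  res <- data.table::data.table(
    transcript_id = c("a", "b", "c", "d"),
    padj = c(0.04, 0.04, 0.06, 0.01),
    log2FC = c(log2(2.5), log2(1.5), log2(3), log2(0.3)))
  cls <- classify_significant(res)
  expect_equal(cls$up, "a")    # b fails FC gate, c fails FDR gate
  expect_equal(cls$down, "d")
  expect_equal(cls$n_up, 1)
})

test_that("hypergeometric overlap equals exact enumeration", {
  # disjoint sets covering the universe: p = 1 for overlap >= 0
  expect_equal(overlap_test(letters[1:5], letters[6:10], 10)$p, 1)
  u <- letters[1:6]
  expect_equal(overlap_test(u, u, 6)$p, 1)
  expect_error(overlap_test(letters[1:10], letters[1:2], 5), "universe")
  set.seed(20)
  for (i in 1:20) {
    N <- sample(8:20, 1)
    ids <- paste0("x", seq_len(N))
    A <- sample(ids, sample(2:(N - 1), 1))
    B <- sample(ids, sample(2:(N - 1), 1))
    k <- length(intersect(A, B))
    got <- overlap_test(A, B, N)
    expect_equal(got$overlap, k)
    expect_equal(got$p, oracle_hyper_p(k, length(A), length(B), N),
                 tolerance = 1e-12)
  }
})

test_that("Spearman correlation handles monotonicity and ties", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(spearman_corr(x, sqrt(x)), 1)
  expect_equal(spearman_corr(x, -x^3), -1)
  # tied example against the direct average-rank formula
  a <- c(1, 2, 2, 3)
  b <- c(10, 30, 20, 20)
  ra <- c(1, 2.5, 2.5, 4)
  rb <- c(1, 4, 2.5, 2.5)
  want <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spearman_corr(a, b), want)
  expect_warning(r <- spearman_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.nan(r))
  expect_error(spearman_corr(1:2, 2:1), ">= 3")
})
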