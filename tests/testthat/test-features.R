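test_that("PARS summaries match window arithmetic", {
  ann <- mk_ann("T1", 40, 300)
  prof <- data.table::data.table(transcript_id = "T1",
                                 position = 1:370, score = 0)
  s <- compute_pars_summaries(prof, ann)
  expect_equal(unlist(s[, .(total_pars, max30_pars, start30_pars,
                            plus15_pars, plus30_pars, plus45_pars)]),
               c(total_pars = 0, max30_pars = 0, start30_pars = 0,
                 plus15_pars = 0, plus30_pars = 0, plus45_pars = 0))
  prof1 <- data.table::copy(prof)[, score := 1]
  s1 <- compute_pars_summaries(prof1, ann)
  expect_equal(s1$total_pars, 40)
  expect_equal(s1$max30_pars, 30)
  expect_equal(s1$start30_pars, 30)
  expect_equal(s1$plus15_pars, 30)

  # 5'UTR shorter than 15 nt: Start30 undefined; shorter than 30: Max30
  # is the full 5'UTR sum (truncated window)
  ann2 <- mk_ann("T2", 10, 300)
  prof2 <- data.table::data.table(transcript_id = "T2",
                                  position = 1:340, score = 2)
  s2 <- compute_pars_summaries(prof2, ann2)
  expect_true(is.na(s2$start30_pars))
  expect_equal(s2$max30_pars, 20)
  expect_equal(s2$total_pars, 20)

  # windows not covered by the profile are flagged NA
  ann3 <- mk_ann("T3", 20, 300, utr3 = 0L)
  prof3 <- data.table::data.table(transcript_id = "T3",
                                  position = 1:60, score = 1)
  s3 <- compute_pars_summaries(prof3, ann3)
  expect_true(is.na(s3$plus45_pars))
})

test_that("Max30 equals the brute-force window maximum on random profiles", {
  set.seed(33)
  for (i in 1:15) {
    u <- sample(31:120, 1)
    ann <- mk_ann("X", u, 120)
    sc <- rnorm(u + 150)
    prof <- data.table::data.table(transcript_id = "X",
                                   position = seq_along(sc), score = sc)
    s <- compute_pars_summaries(prof, ann)
    want <- max(sapply(1:(u - 29), function(j) sum(sc[j:(j + 29)])))
    expect_equal(s$max30_pars, want)
    expect_equal(s$total_pars, sum(sc[1:u]))
    expect_equal(s$start30_pars, sum(sc[(u - 14):(u + 15)]))
  }
})

test_that("context scores follow the weight model", {
  model <- default_context_model()
  # consensus sequence scores exactly 1
  cons <- rownames(model)[apply(model, 2, which.max)]
  seq <- paste0("CCCC", paste(cons[1:6], collapse = ""), "ATG",
                paste(cons[7:9], collapse = ""), "CCCCC")
  expect_equal(compute_context_score(seq, 11L, model), 1)
  # uniform weights: identical scores for any sequence
  unif <- model
  unif[] <- 0.3
  expect_equal(compute_context_score(seq, 11L, unif), 0.3)
  expect_equal(compute_context_score("CCCCCCCCCCATGCCCCCC", 11L, unif), 0.3)
  # direct evaluation on a hand-picked sequence
  seq2 <- "AAAAAACAAGTATGACTAAA"
  w <- c(model["A", "-6"], model["C", "-5"], model["A", "-4"],
         model["A", "-3"], model["G", "-2"], model["T", "-1"],
         model["A", "4"], model["C", "5"], model["T", "6"])
  expect_equal(compute_context_score(seq2, 12L, model),
               exp(mean(log(w))))
  # 5'UTR < 6 nt: undefined
  expect_true(is.na(compute_context_score("AAATGAAAAAAAAA", 3L, model)))
})

test_that("equal-size binning partitions ranked values deterministically", {
  a <- bin_equal_size(rev(1:12), k = 6)
  expect_equal(as.integer(table(a)), rep(2L, 6))
  expect_equal(a[12], 1L)  # smallest value in bin 1
  b <- bin_equal_size(1:13, k = 6)
  expect_equal(as.integer(table(b)), c(3L, 2L, 2L, 2L, 2L, 2L))
  v <- c(5, 1, 5, 2, 5, 9)
  expect_identical(bin_equal_size(v, 3, ids = letters[1:6]),
                   bin_equal_size(v, 3, ids = letters[1:6]))
  expect_error(bin_equal_size(1:3, 6), "at least k")
  expect_error(bin_equal_size(c(1, NA, 3, 4), 2), "finite")
})

test_that("bin summaries match brute-force statistics", {
  set.seed(44)
  feat <- rnorm(60)
  met <- rnorm(60)
  a <- bin_equal_size(feat, 6)
  s <- summarize_bins(feat, met, a)
  expect_equal(s$n, rep(10L, 6))
  for (b in 1:6) {
    expect_equal(s$median[b], median(met[a == b]))
    expect_equal(s$mean[b], mean(met[a == b]))
  }
  s2 <- summarize_bins(feat, rep(3, 60), a)
  expect_equal(s2$mean, rep(3, 6))
})

test_that("leaky-scanning classification applies the reciprocity criterion", {
  mk_diff <- function(ids, cls) {
    up <- cls == "up"; down <- cls == "down"
    data.table::data.table(transcript_id = ids,
                           padj = ifelse(cls == "ns", 0.5, 0.01),
                           log2FC = ifelse(up, 2, ifelse(down, -2, 0)))
  }
  ids <- c("lk", "part", "nsd")
  # lk: mRPF 100->40, iRPF 5->40  (35 >= 0.5*60: leaky)
  # part: mRPF 100->40, iRPF 5->15 (10 < 30: reciprocity fails)
  # nsd: no significant mRPF decrease
  dm <- mk_diff(ids, c("down", "down", "ns"))
  di <- mk_diff(ids, c("up", "up", "up"))
  cm <- data.table::data.table(
    transcript_id = ids, mRPF_A = c(100, 100, 50), mRPF_B = c(40, 40, 60),
    iRPF_A = c(5, 5, 5), iRPF_B = c(40, 15, 20))
  out <- classify_leaky_scanning(dm, di, cm)
  expect_setequal(out$m_down, c("lk", "part"))
  expect_setequal(out$m_down_i_up, c("lk", "part"))
  expect_equal(out$leaky, "lk")
  # no significant decreases anywhere: all empty
  out2 <- classify_leaky_scanning(mk_diff(ids, rep("ns", 3)), di, cm)
  expect_length(out2$leaky, 0)
  expect_error(classify_leaky_scanning(dm, di[1:2], cm), "universe")
})

test_that("upstream reciprocity classification mirrors the criterion", {
  ids <- c("q", "weak")
  du <- data.table::data.table(transcript_id = ids, padj = 0.01,
                               log2FC = c(-3, -0.1))
  du$padj[2] <- 0.01
  du$log2FC[2] <- log2(38 / 40)  # not < 0.5-fold: ns by FC gate
  dm <- data.table::data.table(transcript_id = ids, padj = 0.01,
                               log2FC = log2(60 / 20))
  cm <- data.table::data.table(
    transcript_id = ids, uRPF_A = c(40, 40), uRPF_B = c(5, 38),
    mRPF_A = c(20, 20), mRPF_B = c(60, 60))
  out <- classify_uaug_reciprocity(du, dm, cm)
  expect_equal(out$reciprocal, "q")   # 35 >= 0.5*40; weak fails both
})

test_that("context-binned RRO detects uniform readthrough multipliers", {
  set.seed(55)
  n <- 120
  ids <- sprintf("T%03d", 1:n)
  ctx <- runif(n, 0.16, 0.97)
  rro0 <- 0.06 * exp(-2 * ctx)
  eff <- data.table::rbindlist(list(
    data.table::data.table(condition = "A", transcript_id = ids, RRO = rro0),
    data.table::data.table(condition = "B", transcript_id = ids,
                           RRO = rro0 * 1.7)))
  ctx_dt <- data.table::data.table(transcript_id = ids, context_score = ctx)
  rb <- rro_by_context(eff, ctx_dt, "A", "B", k = 6)
  expect_equal(rb$log2_delta_rro, rep(log2(1.7), 6), tolerance = 1e-9)
  # context-dependent baseline: RRO decreases across context bins
  expect_true(all(diff(rb$rro_A) < 0))
  # single bin: global means
  rb1 <- rro_by_context(eff, ctx_dt, "A", "B", k = 1)
  expect_equal(rb1$rro_A, mean(rro0))
})

test_that("rank heat-map ordering is a deterministic sort", {
  d1 <- data.table::data.table(transcript_id = c("a", "b", "c"),
                               log2_delta = c(1, 3, -2))
  d2 <- data.table::data.table(transcript_id = c("c", "a", "b"),
                               log2_delta = c(0.5, 0.1, 0.2))
  m <- rank_heatmap_table(list(x = d1, y = d2), order_by = "x")
  expect_equal(rownames(m), c("b", "a", "c"))
  expect_equal(m[, "y"], c(b = 0.2, a = 0.1, c = 0.5))
  # ordering invariant under a monotone transform of the ordering metric
  d1b <- data.table::copy(d1)[, log2_delta := log2_delta * 10 + 2]
  m2 <- rank_heatmap_table(list(x = d1b, y = d2), order_by = "x")
  expect_equal(rownames(m2), rownames(m))
  expect_error(rank_heatmap_table(list(x = d1, y = d2[1:2])), "universe")
})
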