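test_that("degenerate configurations produce the forced geometry", {
  empty <- generate_transcriptome(tiny_config(n_transcripts = 0L), seed = 1)
  expect_equal(nrow(empty$annotation), 0L)
  expect_length(empty$sequences, 0L)

  no_utr <- generate_transcriptome(
    tiny_config(utr5_len_dist = list(fixed = 0)), seed = 1)
  expect_true(all(no_utr$annotation$cds_start == 1L))
  expect_true(all(no_utr$annotation$n_uaug == 0L))
  expect_equal(nrow(no_utr$upstream_aug), 0L)
})

test_that("transcriptome generation is reproducible and annotation is consistent", {
  cfg <- tiny_config()
  a <- generate_transcriptome(cfg, seed = 42)
  b <- generate_transcriptome(cfg, seed = 42)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$pars, b$pars)
  c <- generate_transcriptome(cfg, seed = 43)
  expect_false(identical(a$sequences, c$sequences))

  ann <- a$annotation
  expect_true(all(ann$utr5_len == ann$cds_start - 1L))
  expect_true(all(ann$cds_end > ann$cds_start))
  # every CDS starts with AUG and ends with a stop codon
  starts <- substring(a$sequences, ann$cds_start, ann$cds_start + 2L)
  stops <- substring(a$sequences, ann$cds_end - 2L, ann$cds_end)
  expect_true(all(starts == "ATG"))
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
  # annotated AUGs really are AUGs in the sequence, in the stated ranges
  ia <- a$internal_aug
  seqs <- a$sequences[ia$transcript_id]
  expect_true(all(substring(seqs, ia$pos, ia$pos + 2L) == "ATG"))
  cs <- ann$cds_start[match(ia$transcript_id, ann$transcript_id)]
  expect_true(all(ia$pos >= cs + 9L))
  ua <- a$upstream_aug
  u5 <- ann$utr5_len[match(ua$transcript_id, ann$transcript_id)]
  expect_true(all(ua$pos + 2L <= u5))
})

test_that("recruitment weights follow the saturating stimulation model", {
  cfg <- tiny_config(penalty_alpha = 0, penalty_beta = 0,
                     stim_mode = "structure")
  tx <- generate_transcriptome(cfg, seed = 5)
  tr <- planted_truth(tx, cfg, seed = 5)
  # zero penalties: no stimulation, weights independent of concentration
  w0 <- compute_recruitment_weights(tr, 0, cfg)
  w500 <- compute_recruitment_weights(tr, 500, cfg)
  expect_equal(w0, w500)
  expect_equal(unname(w0), tr$per_transcript$abundance)

  cfg2 <- tiny_config(stim_mode = "planted", stim_frac = 0.5, stim_S = 4)
  tx2 <- generate_transcriptome(cfg2, seed = 5)
  tr2 <- planted_truth(tx2, cfg2, seed = 5)
  # half-saturation identity at ded1 = K: stimulation is exactly 1 + S/2
  wK <- compute_recruitment_weights(tr2, cfg2$ded1_K, cfg2)
  w0 <- compute_recruitment_weights(tr2, 0, cfg2)
  expect_equal(unname(wK / w0), 1 + tr2$per_transcript$S / 2)
  expect_error(compute_recruitment_weights(tr2, -1, cfg2), "non-negative")
})

test_that("base weight penalises structure and stimulation grows with it", {
  cfg <- tiny_config(stim_mode = "structure")
  tx <- generate_transcriptome(cfg, seed = 11)
  tr <- planted_truth(tx, cfg, seed = 11)
  pt <- tr$per_transcript
  ann <- tx$annotation
  # direct evaluation of the stated formula
  pen <- cfg$penalty_alpha * pmax(pt$max30_pars, 0) +
    cfg$penalty_beta * ann$utr5_len
  expect_equal(pt$base_weight, exp(-pen))
  # larger penalty: lower base weight, higher amplitude
  o <- order(pen)
  expect_true(all(diff(pt$base_weight[o]) <= 0))
  expect_true(all(diff(pt$S[o]) >= 0))
})

test_that("jitter-free, leak-free footprints sit exactly 12 nt upstream of the mAUG", {
  cfg <- jitter_off(tiny_config(leak_base = 0, uaug_init_prob = 0,
                                utr5_len_dist = list(meanlog = log(60), sdlog = 0.2),
                                gcn4_like = FALSE))
  tx <- generate_transcriptome(cfg, seed = 3)
  tr <- planted_truth(tx, cfg, seed = 3)
  fp <- simulate_footprints(tx, tr, cfg, 0, "s1", seed = 3)
  cs <- tx$annotation$cds_start[match(fp$transcript_id,
                                      tx$annotation$transcript_id)]
  expect_true(all(fp$five_prime_pos == cs - 12L))
  expect_true(all(fp$length >= 25L & fp$length <= 34L))
  # multinomial allocation conserves the PIC pool exactly
  expect_equal(attr(fp, "n_allocated"), cfg$pic_pool)

  empty <- simulate_footprints(tx, tr, tiny_config(pic_pool = 0), 0, "s1",
                               seed = 3)
  expect_equal(nrow(empty), 0L)
})

test_that("forced readthrough lands every footprint on an internal AUG", {
  cfg <- jitter_off(tiny_config(uaug_init_prob = 0, gcn4_like = FALSE,
                                utr5_len_dist = list(meanlog = log(60), sdlog = 0.2)))
  tx <- generate_transcriptome(cfg, seed = 9)
  tr <- planted_truth(tx, cfg, seed = 9)
  tr$per_condition[, leak_prob := 1]
  fp <- simulate_footprints(tx, tr, cfg, 0, "s1", seed = 9)
  ia_key <- paste(tx$internal_aug$transcript_id, tx$internal_aug$pos - 12L)
  expect_true(all(paste(fp$transcript_id, fp$five_prime_pos) %in% ia_key))
})

test_that("footprint simulation is reproducible under a fixed seed", {
  cfg <- tiny_config()
  tx <- generate_transcriptome(cfg, seed = 2)
  tr <- planted_truth(tx, cfg, seed = 2)
  a <- suppressWarnings(simulate_footprints(tx, tr, cfg, 100, "sA", seed = 8))
  b <- suppressWarnings(simulate_footprints(tx, tr, cfg, 100, "sA", seed = 8))
  expect_identical(as.data.frame(a), as.data.frame(b))
  # a different sample id uses an independent stream
  d <- suppressWarnings(simulate_footprints(tx, tr, cfg, 100, "sB", seed = 8))
  expect_false(identical(a$count, d$count))
})

test_that("spike-in simulation matches configured counts and scales with loss", {
  cfg <- tiny_config(noise = "none")
  sp1 <- simulate_spikeins(cfg, "s1", seed = 1, sample_loss = 1)
  cc <- count_spike_categories(sp1, cfg$spike_reference)
  got <- unlist(cc[1, -1])
  expect_equal(got[names(cfg$spike_counts)], cfg$spike_counts)
  sp_half <- simulate_spikeins(cfg, "s1", seed = 1, sample_loss = 0.5)
  cc2 <- count_spike_categories(sp_half, cfg$spike_reference)
  expect_equal(unlist(cc2[1, -1])[names(cfg$spike_counts)],
               cfg$spike_counts / 2)
  expect_true(all(sp1$transcript_id %in% c("FLUC", "RLUC")))
})

test_that("RNA-seq simulation follows the uniform-fragment model", {
  cfg <- tiny_config()
  tx <- generate_transcriptome(cfg, seed = 6)
  ab <- tx$abundance
  ab[] <- 0
  expect_equal(nrow(simulate_rnaseq(tx, cfg, seed = 1, abundance = ab)[count > 0]),
               0L)
  r1 <- simulate_rnaseq(tx, cfg, seed = 4)
  r2 <- simulate_rnaseq(tx, cfg, seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # equal abundance, CDS twice as long: ~2x CDS reads, equal per-nt density;
  # exact under expectation mode
  ann2 <- rbind(mk_ann("SHORT", 50, 300), mk_ann("LONG", 50, 600))
  tx2 <- list(annotation = ann2,
              abundance = c(SHORT = 2, LONG = 2),
              sequences = NULL, pars = NULL)
  cfg_none <- tiny_config(noise = "none")
  rs <- simulate_rnaseq(tx2, cfg_none, seed = 1, abundance = tx2$abundance)
  dens <- compute_mrna_density(rs, ann2)
  expect_equal(dens$mrna_density[1], dens$mrna_density[2])
  expect_equal(dens$cds_reads[dens$transcript_id == "LONG"],
               2 * dens$cds_reads[dens$transcript_id == "SHORT"])
})

test_that("planted truth expectations are internally consistent", {
  cfg <- tiny_config(stim_mode = "planted")
  tx <- generate_transcriptome(cfg, seed = 21)
  tr <- planted_truth(tx, cfg, seed = 21)
  pc <- tr$per_condition
  expect_true(all(pc$stim_factor >= 1))
  expect_true(all(pc$expected_re >= 0, na.rm = TRUE))
  expect_true(all(pc$leak_prob >= 0 & pc$leak_prob <= 0.95))
  # expected mRPF sums to pool x mean(p_mAUG share) <= pool
  expect_lte(sum(pc[ded1_conc == 0]$expected_mrpf), cfg$pic_pool)
})
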