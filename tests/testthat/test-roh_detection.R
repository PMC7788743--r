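p_def <- roh_params()

test_that("a clean homozygous stretch yields one run with the right fields", {
  calls <- rep(0L, 40)
  pos <- seq(1e6, by = 5e4, length.out = 40)   # spans 1.95 Mb + 1
  runs <- detect_runs_animal_chrom(calls, pos, p_def)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start_bp, 1e6)
  expect_equal(runs$end_bp, pos[40])
  expect_equal(runs$n_snps, 40L)
  expect_equal(runs$length_bp, pos[40] - 1e6 + 1)
  expect_equal(as.character(classify_length(runs$length_bp)), "1-6Mb")
})

test_that("29 homozygous markers never form a run (marker-count rule)", {
  calls <- rep(0L, 29)
  pos <- seq(1e6, by = 1e5, length.out = 29)   # 2.8 Mb span, only 29 SNPs
  expect_equal(nrow(detect_runs_animal_chrom(calls, pos, p_def)), 0L)
})

test_that("a >250 kb gap splits a candidate into separately tested fragments", {
  calls <- rep(0L, 70)
  pos <- c(seq(1e6, by = 5e4, length.out = 35),
           seq(1e6 + 34 * 5e4 + 3e5, by = 5e4, length.out = 35))
  runs <- detect_runs_animal_chrom(calls, pos, p_def)
  # each fragment: 35 SNPs over 1.7 Mb -> both pass on their own
  expect_equal(nrow(runs), 2L)
  expect_true(all(runs$n_snps == 35L))
  # gap never spanned
  expect_true(all(runs$end_bp - runs$start_bp + 1 < 2e6))

  # shrink the fragments below min_snps: nothing may bridge the gap
  calls2 <- rep(0L, 40)
  pos2 <- c(seq(1e6, by = 5e4, length.out = 20),
            seq(1e6 + 19 * 5e4 + 3e5, by = 5e4, length.out = 20))
  expect_equal(nrow(detect_runs_animal_chrom(calls2, pos2, p_def)), 0L)
})

test_that("het and missing budgets are enforced and never terminal", {
  base <- rep(0L, 45)
  pos <- seq(1e6, by = 5e4, length.out = 45)
  one_het <- base; one_het[20] <- 1L
  r1 <- detect_runs_animal_chrom(one_het, pos, p_def)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_het, 1L)

  # two hets, but a 30-SNP window containing only the second one exists:
  # the maximal compliant sub-window [16..45] is emitted
  two_het <- base; two_het[c(15, 30)] <- 1L
  r2 <- detect_runs_animal_chrom(two_het, pos, p_def)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$start_bp, pos[16])
  expect_equal(r2$end_bp, pos[45])
  expect_equal(r2$n_het, 1L)

  # three spread hets leave no 30-SNP window with <= 1 het: nothing emitted
  three_het <- base; three_het[c(8, 23, 38)] <- 1L
  expect_equal(nrow(detect_runs_animal_chrom(three_het, pos, p_def)), 0L)

  # het at the edge of the compliant window is not absorbed as terminal
  edge <- base; edge[1] <- 1L
  r3 <- detect_runs_animal_chrom(edge, pos, p_def)
  expect_equal(r3$start_bp, pos[2])

  one_mis <- base; one_mis[22] <- NA_integer_
  expect_equal(detect_runs_animal_chrom(one_mis, pos, p_def)$n_missing, 1L)
  three_mis <- base; three_mis[c(8, 23, 38)] <- NA_integer_
  expect_equal(nrow(detect_runs_animal_chrom(three_mis, pos, p_def)), 0L)
})

test_that("density rule: sparse runs are rejected", {
  calls <- rep(0L, 30)
  pos <- seq(1e6, by = 1.2e5, length.out = 30)  # 120 kb per SNP > 100 kb
  expect_equal(nrow(detect_runs_animal_chrom(calls, pos, p_def)), 0L)
})

test_that("precondition violations raise errors", {
  expect_error(detect_runs_animal_chrom(rep(0L, 5), c(1, 2, 2, 3, 4) * 1e5),
               "strictly increasing")
  expect_error(detect_runs_animal_chrom(rep(0L, 5), c(1e5, 2e5)),
               "differ in length")
})

test_that("length classes are half-open, lower-inclusive", {
  expect_equal(as.character(classify_length(c(5880000, 6e6, 12e6, 24e6, 48e6, 5e7))),
               c("1-6Mb", "6-12Mb", "12-24Mb", "24-48Mb", ">48Mb", ">48Mb"))
  expect_error(classify_length(999999), "1 Mb minimum")
})

test_that("detector equals the brute-force window oracle on random chromosomes", {
  set.seed(20240917)
  for (rep in 1:25) {
    rc <- random_chrom(sample(80:220, 1))
    mine <- detect_runs_animal_chrom(rc$calls, rc$pos, p_def)
    oracle <- brute_force_runs(rc$calls, rc$pos, p_def)
    expect_equal(mine$start_idx, oracle$start_idx)
    expect_equal(mine$end_idx, oracle$end_idx)
  }
})

test_that("relaxing an admissibility threshold never decreases the run count", {
  # min_snps / min_length / density only admit more windows; the scan-break
  # structure is untouched, so the greedy count is monotone. (The budget and
  # gap thresholds are different: relaxing them can merge two runs into one,
  # so for those only window-level monotonicity holds — next test.)
  set.seed(42)
  for (rep in 1:10) {
    rc <- random_chrom(150)
    n0 <- nrow(detect_runs_animal_chrom(rc$calls, rc$pos, p_def))
    relaxed <- list(
      roh_params(min_snps = 20),
      roh_params(min_length_bp = 5e5),
      roh_params(min_density_bp_per_snp = 2e5))
    for (p in relaxed) {
      expect_gte(nrow(detect_runs_animal_chrom(rc$calls, rc$pos, p)), n0)
    }
  }
})

test_that("every emitted run stays compliant under any single-threshold relaxation", {
  set.seed(4242)
  relaxations <- list(
    roh_params(min_snps = 20), roh_params(min_length_bp = 5e5),
    roh_params(max_het = 2), roh_params(max_missing = 2),
    roh_params(min_density_bp_per_snp = 2e5), roh_params(max_gap_bp = 5e5))
  for (rep in 1:10) {
    rc <- random_chrom(150)
    runs <- detect_runs_animal_chrom(rc$calls, rc$pos, p_def)
    for (k in seq_len(nrow(runs))) {
      for (p in relaxations) {
        expect_true(window_ok(rc$calls, rc$pos,
                              runs$start_idx[k], runs$end_idx[k], p))
      }
    }
  }
})

test_that("every emitted segment passes the post-hoc validator", {
  set.seed(99)
  cfg <- sim_config(breeds = list(list(name = "A", n_animals = 6, f_target = 0.25)),
                    n_chroms = 3, chrom_length_bp = 4e7,
                    error_rate = 0.002, missing_rate = 0.01, seed = 99)
  sim <- simulate_panel(cfg)
  runs <- detect_roh(sim$panel, sim$meta)
  expect_gt(nrow(runs), 0)
  expect_true(validate_roh(runs, sim$panel))
})

test_that("the validator rejects corrupted segments", {
  calls <- matrix(0L, 1, 45)
  panel <- toy_panel(calls, pos = seq(1e6, by = 5e4, length.out = 45))
  runs <- detect_roh(panel)
  bad <- runs; bad$end_bp <- bad$end_bp + 12345L
  expect_error(validate_roh(bad, panel), "validation failed")
  bad2 <- rbind(runs, runs)  # overlapping duplicate
  bad2$length_bp <- bad2$end_bp - bad2$start_bp + 1
  expect_error(validate_roh(bad2, panel), "overlap")
})

test_that("breed summaries average per animal and recount per class", {
  runs <- data.frame(
    animal_id = c("x1", "x1", "x1", "x2", "x2", "x2", "x2", "x2"),
    population = "B1", chrom = 1L,
    start_bp = 1L, end_bp = 2L, n_snps = 30L, n_het = 0L, n_missing = 0L,
    length_bp = c(2e6, 4e6, 7e6, 1.5e6, 13e6, 2e6, 3e6, 25e6))
  runs$length_class <- classify_length(runs$length_bp)
  meta <- sample_metadata(c("x1", "x2"), c("B1", "B1"))
  s <- summarize_by_breed(runs, meta)
  expect_equal(s$mn_roh, 4)                       # (3 + 5) / 2
  expect_equal(s$al_roh_mb, mean(runs$length_bp) / 1e6)
  # class counts equal an independent filtering of the run table
  expect_equal(unname(unlist(s[, c("1-6Mb", "6-12Mb", "12-24Mb", "24-48Mb", ">48Mb")])),
               c(sum(runs$length_bp < 6e6), sum(runs$length_bp >= 6e6 & runs$length_bp < 12e6),
                 sum(runs$length_bp >= 12e6 & runs$length_bp < 24e6),
                 sum(runs$length_bp >= 24e6 & runs$length_bp < 48e6),
                 sum(runs$length_bp >= 48e6)))
  # zero-run animals stay in the denominator
  meta3 <- sample_metadata(c("x1", "x2", "x3"), "B1")
  expect_equal(summarize_by_breed(runs, meta3)$mn_roh, 8 / 3)

  m <- runs_per_chromosome(runs, meta)
  expect_equal(unname(m["B1", "1"]), 8L)
  expect_error(summarize_by_breed(runs, sample_metadata("x1", "B1")),
               "no metadata")
})
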