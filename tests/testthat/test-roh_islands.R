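mk_map <- function(n, chrom = 1L, spacing = 50000L) {
  snp_map(rep(chrom, n), seq_len(n) * spacing, sprintf("c%d_s%d", chrom, 1:n))
}

mk_run <- function(id, pop, chrom, start, end) {
  data.frame(animal_id = id, population = pop, chrom = chrom,
             start_bp = start, end_bp = end, stringsAsFactors = FALSE)
}

test_that("incidence counts distinct animals whose runs cover each marker", {
  map <- mk_map(60)
  runs <- mk_run("a1", "P", 1L, map$pos_bp[5], map$pos_bp[40])
  meta <- sample_metadata(c("a1", "a2"), "P")
  inc <- incidence_per_snp(runs, map, meta)
  expect_equal(inc$incidence, c(rep(0L, 4), rep(1L, 36), rep(0L, 20)))

  # two overlapping runs in the SAME animal still count once
  runs2 <- rbind(runs, mk_run("a1", "P", 1L, map$pos_bp[30], map$pos_bp[50]))
  inc2 <- incidence_per_snp(runs2, map, meta)
  expect_equal(max(inc2$incidence), 1L)
  expect_equal(sum(inc2$incidence), 46L)  # union 5..50

  expect_error(incidence_per_snp(mk_run("a1", "P", 9L, 1L, 2L), map),
               "absent from the map")
})

test_that("incidence equals the brute-force (animal, marker) double loop", {
  set.seed(5)
  map <- rbind(mk_map(40, 1L), mk_map(30, 2L))
  class(map) <- c("snp_map", "data.frame")
  runs <- do.call(rbind, lapply(1:8, function(a) {
    ch <- sample(1:2, 1)
    n <- sum(map$chrom == ch)
    i <- sort(sample(n, 2))
    pos <- map$pos_bp[map$chrom == ch]
    mk_run(sprintf("a%d", a), "P", ch, pos[i[1]], pos[i[2]])
  }))
  inc <- incidence_per_snp(runs, map)
  expect_equal(inc$incidence, brute_force_incidence(runs, map))
})

test_that("incidence conservation: total equals summed member-marker counts", {
  set.seed(6)
  map <- mk_map(80)
  runs <- do.call(rbind, lapply(1:10, function(a) {
    i <- sort(sample(80, 2))
    mk_run(sprintf("a%d", a), "P", 1L, map$pos_bp[i[1]], map$pos_bp[i[2]])
  }))
  inc <- incidence_per_snp(runs, map)
  member_counts <- vapply(seq_len(nrow(runs)), function(k)
    sum(map$pos_bp >= runs$start_bp[k] & map$pos_bp <= runs$end_bp[k]),
    numeric(1))
  expect_equal(sum(inc$incidence), sum(member_counts))
})

test_that("island calling enforces the span, count and incidence rules", {
  map <- mk_map(120, spacing = 40000L)  # 35 SNPs span 1.36 Mb
  inc <- data.frame(chrom = 1L, pos_bp = map$pos_bp, snp_id = map$snp_id,
                    incidence = 0L)
  inc$incidence[30:64] <- 25L  # 35 markers, span 34*40k+1 = 1.36 Mb
  isl <- call_islands(inc)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$n_snps, 35L)
  expect_equal(isl$start_bp, map$pos_bp[30])
  expect_equal(isl$end_bp, map$pos_bp[64])
  expect_equal(isl$min_incidence, 25L)

  # same 35 markers squeezed under 1 Mb: the span rule rejects
  map2 <- mk_map(120, spacing = 25000L)
  inc2 <- transform(inc, pos_bp = map2$pos_bp)
  expect_equal(nrow(call_islands(inc2)), 0L)

  # 29 markers above threshold: the marker-count rule rejects
  inc3 <- inc; inc3$incidence[] <- 0L; inc3$incidence[30:58] <- 25L
  expect_equal(nrow(call_islands(inc3)), 0L)

  # incidence exactly 20 is not "more than 20 samples"
  inc4 <- inc; inc4$incidence[30:64] <- 20L
  expect_equal(nrow(call_islands(inc4)), 0L)
})

test_that("islands are maximal and their members all exceed the threshold", {
  set.seed(7)
  map <- mk_map(400)
  # blocky incidence profile: plateaus above the threshold with noisy edges
  base <- rep(5L, 400)
  for (start in c(30, 120, 260)) {
    len <- sample(30:60, 1)
    base[start:(start + len)] <- sample(21:40, len + 1, replace = TRUE)
  }
  inc <- data.frame(chrom = 1L, pos_bp = map$pos_bp, snp_id = map$snp_id,
                    incidence = base)
  isl <- call_islands(inc)
  members <- attr(isl, "member_snps")
  for (k in seq_len(nrow(isl))) {
    ii <- match(members[[k]], inc$snp_id)
    expect_true(all(inc$incidence[ii] > 20))
    lo <- min(ii); hi <- max(ii)
    if (lo > 1) expect_lte(inc$incidence[lo - 1], 20)
    if (hi < nrow(inc)) expect_lte(inc$incidence[hi + 1], 20)
  }
})

test_that("sub-threshold gaps merge only when max_gap_bp allows", {
  map <- mk_map(200)
  inc <- data.frame(chrom = 1L, pos_bp = map$pos_bp, snp_id = map$snp_id,
                    incidence = 0L)
  inc$incidence[c(30:54, 56:80)] <- 30L  # one sub-threshold marker inside
  strict <- call_islands(inc)           # two stretches, each 25 SNPs < 30
  expect_equal(nrow(strict), 0L)
  merged <- call_islands(inc, max_gap_bp = 2e5)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_snps, 50L)      # the sub-threshold marker is no member
})

test_that("sharing classes partition islands by contributing populations", {
  map <- mk_map(120)
  inc_runs <- rbind(
    do.call(rbind, lapply(sprintf("u%d", 1:25),
      function(id) mk_run(id, "A", 1L, map$pos_bp[10], map$pos_bp[50]))),
    mk_run("v1", "B", 1L, map$pos_bp[48], map$pos_bp[60]),
    mk_run("w1", "C", 1L, map$pos_bp[100], map$pos_bp[110]))
  meta <- sample_metadata(c(sprintf("u%d", 1:25), "v1", "w1"),
                          c(rep("A", 25), "B", "C"))
  inc <- incidence_per_snp(inc_runs, map, meta)
  isl <- call_islands(inc)
  expect_equal(nrow(isl), 1L)
  cls <- classify_island_sharing(isl, inc_runs, meta, map)
  # B overlaps member markers 48..50, C does not reach the island
  expect_equal(cls$n_populations, 2L)
  expect_equal(as.character(cls$sharing_class), "shared")
  expect_equal(cls$populations, "A,B")

  # class boundaries: 1 -> unique, 3 -> shared, 4 -> common
  expect_equal(as.character(cut(c(1, 2, 3, 4, 7), c(0, 1, 3, Inf),
                                labels = c("unique", "shared", "common"))),
               c("unique", "shared", "shared", "common", "common"))
})

test_that("island SNP proportions count covered member markers per sample", {
  map <- mk_map(120)
  runs <- rbind(
    do.call(rbind, lapply(sprintf("u%d", 1:25),
      function(id) mk_run(id, "A", 1L, map$pos_bp[10], map$pos_bp[50]))),
    mk_run("h1", "B", 1L, map$pos_bp[10], map$pos_bp[30]))
  meta <- sample_metadata(c(sprintf("u%d", 1:25), "h1", "h2"),
                          c(rep("A", 25), "B", "B"))
  inc <- incidence_per_snp(runs, map, meta)
  isl <- call_islands(inc)
  expect_equal(isl$n_snps, 41L)  # markers 10..50
  props <- island_snp_proportions(isl, runs, meta, map)
  expect_equal(props$proportion[props$animal_id == "u1"], 1.0)
  expect_equal(props$proportion[props$animal_id == "h1"], 21 / 41)
  expect_equal(props$proportion[props$animal_id == "h2"], 0.0)
  expect_true(all(props$proportion >= 0 & props$proportion <= 1))

  bp <- island_breed_proportions(props)
  expect_equal(bp$mean_proportion[bp$population == "B"], mean(c(21 / 41, 0)))
})

test_that("breed model recovers hand-computed effects and flags thin designs", {
  d <- data.frame(population = c("A", "A", "B", "B"),
                  proportion = c(0.2, 0.2, 0.8, 0.8))
  m <- suppressWarnings(fit_breed_model(d))  # zero-residual toy fit
  expect_equal(m$mu, 0.5)
  expect_equal(unname(m$effects), c(-0.3, 0.3))
  expect_equal(sum(m$effects), 0)

  expect_message(out <- fit_breed_model(
    data.frame(population = "A", proportion = c(0.1, 0.2))), "skipped")
  expect_null(out)
})

test_that("breed-model F test is calibrated under the null and finds real effects", {
  set.seed(12)
  pvals <- replicate(300, {
    d <- data.frame(population = rep(c("A", "B", "C"), each = 10),
                    proportion = rnorm(30, 0.3, 0.1))
    fit_breed_model(d)$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)

  set.seed(13)
  est <- replicate(25, {
    d <- data.frame(population = rep(c("A", "B"), each = 20),
                    proportion = c(rnorm(20, 0.2, 0.1), rnorm(20, 0.5, 0.1)))
    m <- fit_breed_model(d)
    m$effects["B"] - m$effects["A"]
  })
  expect_lt(abs(mean(est) - 0.3), 0.05)
})
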