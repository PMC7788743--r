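#' Simulation configuration for a multi-breed SNP panel
#'
#' Describes a synthetic SNP-array panel emulating an OvineSNP50-style chip:
#' by default 26 autosomes of 94 Mb each (total 2444 Mb), markers at a mean
#' spacing of 50 kb with +/- 25 kb jitter, and one oversized inter-marker
#' gap per chromosome to exercise the detector's gap rule. Each breed has
#' its own allele-frequency profile (Balding-Nichols drift around shared
#' base frequencies) and a target autozygosity `f_target` realised by
#' planting identical-by-descent segments.
#'
#' Planted segment lengths are drawn from a mixture over the five standard
#' ROH length bins; bin-1 lengths start at `segment_min_bp` (default 2 Mb)
#' so every planted segment carries enough markers to be individually
#' detectable at the default spacing.
#'
#' @param breeds list of per-breed lists with fields `name`, `n_animals`,
#'   `f_target` and optionally `production_system`.
#' @param n_chroms number of autosomes (default 26).
#' @param chrom_length_bp chromosome length in bp (default 9.4e7).
#' @param mean_spacing_bp mean inter-marker spacing (default 5e4).
#' @param spacing_jitter_bp half-width of the uniform spacing jitter
#'   (default 2.5e4).
#' @param big_gaps_per_chrom count of oversized gaps per chromosome
#'   (default 1).
#' @param big_gap_bp size of an oversized gap (default 4e5, above the 250 kb
#'   gap rule).
#' @param base_freq_range range the shared base B-allele frequencies are
#'   rescaled into (default c(0.05, 0.95)).
#' @param base_freq_shape shape parameters of the Beta distribution the base
#'   frequencies are drawn from before rescaling (default c(2, 2), the
#'   common-variant profile of an ascertained array panel; c(1, 1) gives
#'   uniform frequencies).
#' @param fst breed drift parameter for the Balding-Nichols profile
#'   (default 0.05; 0 disables drift).
#' @param segment_bin_weights mixture weights over the length bins
#'   1-6 / 6-12 / 12-24 / 24-48 / >48 Mb (default c(.882, .08, .025, .01,
#'   .003), the empirical shape of sheep-panel ROH).
#' @param segment_min_bp lower bound of bin-1 segment lengths (default 2e6).
#' @param min_separation_bp minimum distance between planted segments within
#'   an animal (default 1e6) so truth segments stay distinct.
#' @param error_rate per-genotype status-flip probability (default 0).
#' @param missing_rate per-genotype missing probability (default 0).
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(breeds, n_chroms = 26, chrom_length_bp = 9.4e7,
                       mean_spacing_bp = 5e4, spacing_jitter_bp = 2.5e4,
                       big_gaps_per_chrom = 1, big_gap_bp = 4e5,
                       base_freq_range = c(0.05, 0.95),
                       base_freq_shape = c(2, 2), fst = 0.05,
                       segment_bin_weights = c(0.882, 0.08, 0.025, 0.01, 0.003),
                       segment_min_bp = 2e6, min_separation_bp = 1e6,
                       error_rate = 0, missing_rate = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory")
  stopifnot(is.list(breeds), length(breeds) >= 1)
  for (b in breeds) {
    stopifnot(!is.null(b$name), !is.null(b$n_animals), !is.null(b$f_target))
    if (b$f_target < 0 || b$f_target > 0.9) {
      stop("f_target must be in [0, 0.9]: ", b$name)
    }
  }
  stopifnot(error_rate >= 0, error_rate <= 1, missing_rate >= 0,
            missing_rate <= 1, length(segment_bin_weights) == 5,
            all(segment_bin_weights >= 0), sum(segment_bin_weights) > 0)
  structure(list(breeds = breeds, n_chroms = as.integer(n_chroms),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 mean_spacing_bp = as.numeric(mean_spacing_bp),
                 spacing_jitter_bp = as.numeric(spacing_jitter_bp),
                 big_gaps_per_chrom = as.integer(big_gaps_per_chrom),
                 big_gap_bp = as.numeric(big_gap_bp),
                 base_freq_range = base_freq_range,
                 base_freq_shape = base_freq_shape, fst = fst,
                 segment_bin_weights = segment_bin_weights /
                   sum(segment_bin_weights),
                 segment_min_bp = as.numeric(segment_min_bp),
                 min_separation_bp = as.numeric(min_separation_bp),
                 error_rate = error_rate, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw one segment length from the bin mixture (bp)
draw_segment_length <- function(cfg) {
  lo <- c(cfg$segment_min_bp, 6e6, 12e6, 24e6, 48e6)
  hi <- c(6e6, 12e6, 24e6, 48e6, 6e7)
  b <- sample.int(5L, 1L, prob = cfg$segment_bin_weights)
  len <- floor(stats::runif(1, lo[b], hi[b]))
  cap <- cfg$chrom_length_bp - 2 * cfg$mean_spacing_bp
  min(len, cap)
}

# plant non-overlapping IBD intervals for one animal until the target
# autozygous fraction is hit (final segment truncated to land exactly)
plant_intervals <- function(cfg, f_target) {
  genome <- cfg$n_chroms * cfg$chrom_length_bp
  target <- f_target * genome
  if (target == 0) {
    return(data.frame(chrom = integer(), start_bp = integer(),
                      end_bp = integer()))
  }
  if (f_target > 0.6) {
    stop("f_target not attainable with the required segment separation")
  }
  iv <- list(); total <- 0
  guard <- 0L
  while (total < target) {
    len <- draw_segment_length(cfg)
    if (total + len > target) len <- target - total
    if (len < 1e5) break
    placed <- FALSE
    for (try in 1:200) {
      ch <- sample.int(cfg$n_chroms, 1L)
      start <- floor(stats::runif(1, 1, cfg$chrom_length_bp - len))
      end <- start + len - 1
      ok <- TRUE
      for (v in iv) {
        if (v[1] == ch &&
            start <= v[3] + cfg$min_separation_bp &&
            end >= v[2] - cfg$min_separation_bp) { ok <- FALSE; break }
      }
      if (ok) {
        iv[[length(iv) + 1L]] <- c(ch, start, end)
        total <- total + len
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      guard <- guard + 1L
      if (guard > 50L) stop("could not place planted segments; lower f_target")
    }
  }
  if (!length(iv)) {
    return(data.frame(chrom = integer(), start_bp = integer(),
                      end_bp = integer()))
  }
  m <- do.call(rbind, iv)
  d <- data.frame(chrom = m[, 1], start_bp = m[, 2], end_bp = m[, 3])
  d[order(d$chrom, d$start_bp), , drop = FALSE]
}

#' Simulate a multi-breed SNP panel with planted autozygosity
#'
#' Markers are laid down per chromosome by cumulative jittered spacings with
#' occasional oversized gaps; shared base allele frequencies are drawn
#' uniformly and per-breed frequencies from the Balding-Nichols Beta model.
#' Each animal is built from two independent haplotypes sampled at its breed
#' frequencies; autozygosity is planted by copying haplotype 1 over
#' haplotype 2 inside non-overlapping intervals whose summed length hits the
#' breed's `f_target` exactly (the last interval is truncated). Genotype
#' status errors (hom <-> het flips) and missingness are then applied.
#' Markers are exchangeable: no linkage disequilibrium is simulated.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `panel` ([geno_panel()]), `meta`
#'   ([sample_metadata()]), `truth` (list: `intervals` data.frame with
#'   animal_id/chrom/start_bp/end_bp, `f_true` named per animal,
#'   `freqs` matrix breeds x markers, `genome_bp`).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed, kind = "Mersenne-Twister")

  # marker map
  maps <- vector("list", cfg$n_chroms)
  for (ch in seq_len(cfg$n_chroms)) {
    sp_lo <- cfg$mean_spacing_bp - cfg$spacing_jitter_bp
    sp_hi <- cfg$mean_spacing_bp + cfg$spacing_jitter_bp
    n_est <- ceiling(cfg$chrom_length_bp / sp_lo) + 10L
    gaps <- floor(stats::runif(n_est, sp_lo, sp_hi + 1))
    if (cfg$big_gaps_per_chrom > 0) {
      at <- sample.int(max(1L, floor(cfg$chrom_length_bp / cfg$mean_spacing_bp * 0.9)),
                       cfg$big_gaps_per_chrom)
      gaps[at] <- cfg$big_gap_bp
    }
    pos <- cumsum(c(floor(stats::runif(1, 1, cfg$mean_spacing_bp)), gaps))
    pos <- pos[pos <= cfg$chrom_length_bp]
    maps[[ch]] <- data.frame(chrom = ch, pos_bp = as.integer(pos))
  }
  mapdf <- do.call(rbind, maps)
  mapdf$snp_id <- sprintf("snp%d_%d", mapdf$chrom, mapdf$pos_bp)
  map <- snp_map(mapdf$chrom, mapdf$pos_bp, mapdf$snp_id)
  n_snps <- nrow(map)

  # allele-frequency profiles
  p_base <- cfg$base_freq_range[1] + diff(cfg$base_freq_range) *
    stats::rbeta(n_snps, cfg$base_freq_shape[1], cfg$base_freq_shape[2])
  n_breeds <- length(cfg$breeds)
  freqs <- matrix(0, n_breeds, n_snps,
                  dimnames = list(vapply(cfg$breeds, `[[`, "", "name"), NULL))
  for (b in seq_len(n_breeds)) {
    if (cfg$fst > 0) {
      shape <- (1 - cfg$fst) / cfg$fst
      freqs[b, ] <- stats::rbeta(n_snps, p_base * shape, (1 - p_base) * shape)
    } else {
      freqs[b, ] <- p_base
    }
  }

  default_systems <- c("mutton", "wool", "pelt", "dual")
  n_animals <- sum(vapply(cfg$breeds, `[[`, numeric(1), "n_animals"))
  calls <- matrix(NA_integer_, n_animals, n_snps)
  ids <- character(n_animals); pops <- character(n_animals)
  systems <- character(n_animals)
  truth_iv <- list(); f_true <- numeric(n_animals)
  genome <- cfg$n_chroms * cfg$chrom_length_bp

  a <- 0L
  for (b in seq_len(n_breeds)) {
    br <- cfg$breeds[[b]]
    sys <- if (!is.null(br$production_system)) br$production_system
           else default_systems[(b - 1L) %% length(default_systems) + 1L]
    for (k in seq_len(br$n_animals)) {
      a <- a + 1L
      ids[a] <- sprintf("%s_%03d", br$name, k)
      pops[a] <- br$name
      systems[a] <- sys
      h1 <- stats::rbinom(n_snps, 1L, freqs[b, ])
      h2 <- stats::rbinom(n_snps, 1L, freqs[b, ])
      iv <- plant_intervals(cfg, br$f_target)
      if (nrow(iv)) {
        for (v in seq_len(nrow(iv))) {
          sel <- map$chrom == iv$chrom[v] &
                 map$pos_bp >= iv$start_bp[v] & map$pos_bp <= iv$end_bp[v]
          h2[sel] <- h1[sel]
        }
        iv$animal_id <- ids[a]
        truth_iv[[length(truth_iv) + 1L]] <- iv
      }
      f_true[a] <- sum(as.numeric(iv$end_bp) - iv$start_bp + 1) / genome
      calls[a, ] <- h1 + h2
    }
  }
  rownames(calls) <- ids

  # genotype-status errors: het -> random hom, hom -> het
  if (cfg$error_rate > 0) {
    flip <- which(stats::runif(length(calls)) < cfg$error_rate)
    if (length(flip)) {
      old <- calls[flip]
      new <- ifelse(old == 1L,
                    ifelse(stats::runif(length(flip)) < 0.5, 0L, 2L), 1L)
      calls[flip] <- new
    }
  }
  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  }

  panel <- geno_panel(map, calls)
  meta <- sample_metadata(ids, pops, systems)
  intervals <- if (length(truth_iv)) {
    d <- do.call(rbind, truth_iv)[, c("animal_id", "chrom", "start_bp", "end_bp")]
    rownames(d) <- NULL
    d
  } else {
    data.frame(animal_id = character(), chrom = integer(),
               start_bp = integer(), end_bp = integer())
  }
  truth <- list(intervals = intervals,
                f_true = stats::setNames(f_true, ids),
                freqs = freqs, genome_bp = genome)
  list(panel = panel, meta = meta, truth = truth)
}

#' Write the planted-segment ground truth as TSV
#'
#' First line is a versioned schema comment (`#rohscan_truth_v1`); then a
#' header and one row per planted interval with the owning animal's
#' population and f_true.
#'
#' @param truth the `truth` element of [simulate_panel()] output.
#' @param meta the matching [sample_metadata()].
#' @param path output path.
#' @export
write_truth <- function(truth, meta, path) {
  iv <- truth$intervals
  d <- data.frame(animal_id = iv$animal_id,
                  population = meta$population[match(iv$animal_id, meta$animal_id)],
                  chrom = iv$chrom, start_bp = iv$start_bp, end_bp = iv$end_bp,
                  f_true = unname(truth$f_true[iv$animal_id]),
                  stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#rohscan_truth_v1", con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth TSV written by [write_truth()]
#' @param path TSV path.
#' @return data.frame of planted intervals with f_true.
#' @export
read_truth <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, "#rohscan_truth_v1")) {
    stop("unrecognised truth schema: ", first)
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                         stringsAsFactors = FALSE)
  for (col in c("chrom", "start_bp", "end_bp")) d[[col]] <- as.integer(d[[col]])
  d
}
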