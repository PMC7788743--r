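#' ROH detection parameters (consecutive-runs criteria)
#'
#' Defaults are the standard OvineSNP50-scale settings: minimum run length
#' 1 Mb (to exclude short runs generated by linkage disequilibrium), at least
#' 30 markers per run, at most one heterozygous and one missing call inside a
#' run, a minimum marker density of one SNP per 100 kb over the run, and a
#' maximum gap of 250 kb between consecutive genotyped markers in the run.
#'
#' @param min_length_bp minimum run length in bp (default 1e6).
#' @param min_snps minimum number of member markers (default 30).
#' @param max_het maximum heterozygous calls allowed inside a run (default 1).
#' @param max_missing maximum missing calls allowed inside a run (default 1).
#' @param min_density_bp_per_snp maximum bp per marker, i.e. length/n_snps
#'   must not exceed this (default 1e5).
#' @param max_gap_bp maximum gap between consecutive genotyped member
#'   markers (default 2.5e5).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(min_length_bp = 1e6, min_snps = 30, max_het = 1,
                       max_missing = 1, min_density_bp_per_snp = 1e5,
                       max_gap_bp = 2.5e5) {
  stopifnot(min_length_bp > 0, min_snps > 0, min_density_bp_per_snp > 0,
            max_gap_bp > 0, max_het >= 0, max_missing >= 0)
  structure(list(min_length_bp = as.numeric(min_length_bp),
                 min_snps = as.integer(min_snps),
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing),
                 min_density_bp_per_snp = as.numeric(min_density_bp_per_snp),
                 max_gap_bp = as.numeric(max_gap_bp)),
            class = "roh_params")
}

# Window compliance, shared by detector and validator:
#   * terminal markers homozygous and non-missing
#   * het count <= max_het, missing count <= max_missing
#   * every gap between consecutive GENOTYPED member markers <= max_gap_bp
#     (a missing member marker does not reset the gap distance)
#   * span = pos[j] - pos[i] + 1 >= min_length_bp
#   * n_snps = j - i + 1 >= min_snps
#   * span / n_snps <= min_density_bp_per_snp

#' Detect ROH on one animal x chromosome
#'
#' Greedy left-to-right scan emitting maximal, non-overlapping runs that
#' satisfy every criterion in `p`: among compliant windows the one with the
#' smallest start (ties: largest end) is emitted first, then the scan resumes
#' after its end. Heterozygous or missing markers are allowed only strictly
#' inside a run, never at its ends.
#'
#' @param calls integer status vector (see [genotype-codes]) for one animal
#'   on one chromosome, aligned with `positions`.
#' @param positions strictly increasing integer bp positions.
#' @param p a [roh_params()].
#' @return data.frame with columns `start_idx`, `end_idx`, `start_bp`,
#'   `end_bp`, `n_snps`, `n_het`, `n_missing`, `length_bp` (possibly 0 rows).
#' @export
detect_runs_animal_chrom <- function(calls, positions, p = roh_params()) {
  n <- length(calls)
  if (length(positions) != n) stop("calls and positions differ in length")
  if (n > 1 && any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  positions <- as.numeric(positions)
  is_hom <- !is.na(calls) & calls != 1L

  res <- list()
  i <- 1L
  while (i <= n) {
    if (!is_hom[i]) { i <- i + 1L; next }
    # extend from i, tracking budgets; remember the best compliant end
    n_het <- 0L; n_miss <- 0L
    last_nm <- positions[i]
    best <- NA_integer_; best_het <- 0L; best_miss <- 0L
    j <- i
    while (j <= n) {
      cj <- calls[j]
      if (j > i) {
        if (is.na(cj)) {
          n_miss <- n_miss + 1L
          if (n_miss > p$max_missing) break
        } else {
          if (positions[j] - last_nm > p$max_gap_bp) break
          if (cj == 1L) {
            n_het <- n_het + 1L
            if (n_het > p$max_het) break
          }
          last_nm <- positions[j]
        }
      }
      if (is_hom[j]) {
        span <- positions[j] - positions[i] + 1
        nsnp <- j - i + 1L
        if (span >= p$min_length_bp && nsnp >= p$min_snps &&
            span / nsnp <= p$min_density_bp_per_snp) {
          best <- j; best_het <- n_het; best_miss <- n_miss
        }
      }
      j <- j + 1L
    }
    if (!is.na(best)) {
      res[[length(res) + 1L]] <- c(i, best, best_het, best_miss)
      i <- best + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(res)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = numeric()))
  }
  m <- do.call(rbind, res)
  data.frame(start_idx = m[, 1], end_idx = m[, 2],
             start_bp = as.integer(positions[m[, 1]]),
             end_bp = as.integer(positions[m[, 2]]),
             n_snps = m[, 2] - m[, 1] + 1L,
             n_het = m[, 3], n_missing = m[, 4],
             length_bp = positions[m[, 2]] - positions[m[, 1]] + 1)
}

#' Assign a run length to its length class
#'
#' Bins are half-open, lower-inclusive: \[1,6), \[6,12), \[12,24), \[24,48)
#' and \[48, Inf) Mb.
#'
#' @param length_bp numeric vector of run lengths (each >= 1e6).
#' @return factor with levels `1-6Mb`, `6-12Mb`, `12-24Mb`, `24-48Mb`, `>48Mb`.
#' @export
classify_length <- function(length_bp) {
  if (any(length_bp < 1e6)) stop("length below the 1 Mb minimum")
  cut(length_bp / 1e6, breaks = c(1, 6, 12, 24, 48, Inf), right = FALSE,
      labels = c("1-6Mb", "6-12Mb", "12-24Mb", "24-48Mb", ">48Mb"))
}

#' Detect ROH across a whole panel
#'
#' Runs [detect_runs_animal_chrom()] for every animal x chromosome and
#' assembles the segment table.
#'
#' @param panel a (post-QC) [geno_panel()].
#' @param meta optional [sample_metadata()]; populates the `population`
#'   column.
#' @param p a [roh_params()].
#' @return data.frame of runs: `animal_id`, `population`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `n_het`, `n_missing`, `length_bp`,
#'   `length_class`, sorted by (animal_id, chrom, start_bp).
#' @export
detect_roh <- function(panel, meta = NULL, p = roh_params()) {
  if (!is.null(meta)) check_meta(panel$animal_ids, meta)
  chroms <- unique(panel$map$chrom)
  out <- vector("list", length(chroms) * nrow(panel$calls))
  k <- 0L
  for (ch in chroms) {
    idx <- which(panel$map$chrom == ch)
    pos <- panel$map$pos_bp[idx]
    sub <- panel$calls[, idx, drop = FALSE]
    for (a in seq_len(nrow(sub))) {
      r <- detect_runs_animal_chrom(sub[a, ], pos, p)
      if (nrow(r)) {
        r$animal_id <- panel$animal_ids[a]
        r$chrom <- ch
        k <- k + 1L
        out[[k]] <- r
      }
    }
  }
  if (k == 0L) {
    runs <- data.frame(animal_id = character(), population = character(),
                       chrom = integer(), start_bp = integer(),
                       end_bp = integer(), n_snps = integer(),
                       n_het = integer(), n_missing = integer(),
                       length_bp = numeric(),
                       length_class = classify_length(numeric()))
    return(runs)
  }
  runs <- do.call(rbind, out[seq_len(k)])
  runs$population <- if (is.null(meta)) NA_character_ else
    meta$population[match(runs$animal_id, meta$animal_id)]
  runs$length_class <- classify_length(runs$length_bp)
  runs <- runs[order(runs$animal_id, runs$chrom, runs$start_bp),
               c("animal_id", "population", "chrom", "start_bp", "end_bp",
                 "n_snps", "n_het", "n_missing", "length_bp", "length_class")]
  rownames(runs) <- NULL
  runs
}

#' Validate ROH segments against the run criteria
#'
#' Post-hoc validator: re-derives every emitted segment's member markers from
#' the panel and checks every run criterion (terminal homozygosity, het and
#' missing budgets, gap rule, length, marker count, density) plus per-animal
#' non-overlap. Intended for tests and defensive pipelines; any violation is
#' an error (zero tolerance).
#'
#' @param runs ROH segment data.frame.
#' @param panel the [geno_panel()] the runs were detected on.
#' @param p the [roh_params()] used.
#' @return `TRUE` invisibly if all segments pass; otherwise an error listing
#'   the first violations.
#' @export
validate_roh <- function(runs, panel, p = roh_params()) {
  problems <- character()
  note <- function(i, what) {
    problems <<- c(problems, sprintf("run %d (%s chr%s %d-%d): %s", i,
                                     runs$animal_id[i], runs$chrom[i],
                                     runs$start_bp[i], runs$end_bp[i], what))
  }
  for (i in seq_len(nrow(runs))) {
    a <- match(runs$animal_id[i], panel$animal_ids)
    if (is.na(a)) { note(i, "animal not in panel"); next }
    idx <- which(panel$map$chrom == runs$chrom[i] &
                 panel$map$pos_bp >= runs$start_bp[i] &
                 panel$map$pos_bp <= runs$end_bp[i])
    pos <- panel$map$pos_bp[idx]
    g <- panel$calls[a, idx]
    len <- runs$end_bp[i] - runs$start_bp[i] + 1
    if (len != runs$length_bp[i]) note(i, "length_bp != end - start + 1")
    if (len < p$min_length_bp) note(i, "below minimum length")
    if (length(idx) != runs$n_snps[i]) note(i, "n_snps mismatch with map")
    if (runs$n_snps[i] < p$min_snps) note(i, "too few markers")
    if (sum(g == 1L, na.rm = TRUE) > p$max_het) note(i, "het budget exceeded")
    if (sum(is.na(g)) > p$max_missing) note(i, "missing budget exceeded")
    if (len / runs$n_snps[i] > p$min_density_bp_per_snp) note(i, "density violated")
    nm <- pos[!is.na(g)]
    if (length(nm) > 1 && any(diff(nm) > p$max_gap_bp)) note(i, "gap rule violated")
    if (length(g)) {
      if (is.na(g[1]) || g[1] == 1L) note(i, "first marker not homozygous")
      gl <- g[length(g)]
      if (is.na(gl) || gl == 1L) note(i, "last marker not homozygous")
    }
  }
  # per-animal, per-chromosome non-overlap
  if (nrow(runs) > 1) {
    sp <- split(seq_len(nrow(runs)),
                paste(runs$animal_id, runs$chrom, sep = "\r"))
    for (ii in sp) {
      if (length(ii) < 2) next
      o <- ii[order(runs$start_bp[ii])]
      if (any(runs$start_bp[o][-1] <= runs$end_bp[o][-length(o)])) {
        problems <- c(problems,
                      sprintf("overlapping runs for %s chr%s",
                              runs$animal_id[o[1]], runs$chrom[o[1]]))
      }
    }
  }
  if (length(problems)) {
    stop("ROH validation failed:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "))
  }
  invisible(TRUE)
}

#' Per-breed ROH summary
#'
#' Computes, per population: number of animals, total run count, MN_ROH
#' (mean number of runs per animal, over all animals of the breed including
#' those with no run), AL_ROH (mean run length in Mb), the average per-animal
#' total ROH length in Mb, and run counts per length class.
#'
#' @param runs ROH segment data.frame.
#' @param meta [sample_metadata()] covering every animal (zero-run animals
#'   included in denominators).
#' @return data.frame, one row per population.
#' @export
summarize_by_breed <- function(runs, meta) {
  check_meta(runs$animal_id, meta)
  pops <- sort(unique(meta$population))
  lv <- levels(classify_length(1e6))
  rows <- lapply(pops, function(bp) {
    ids <- meta$animal_id[meta$population == bp]
    r <- runs[runs$animal_id %in% ids, , drop = FALSE]
    per_animal_sum <- vapply(ids, function(id)
      sum(r$length_bp[r$animal_id == id]) / 1e6, numeric(1))
    cls <- table(factor(r$length_class, levels = lv))
    cls_df <- as.data.frame(t(as.matrix(cls)))
    names(cls_df) <- lv
    cbind(data.frame(population = bp, n_animals = length(ids),
                     n_roh = nrow(r),
                     mn_roh = nrow(r) / length(ids),
                     al_roh_mb = if (nrow(r)) mean(r$length_bp) / 1e6 else NA_real_,
                     sum_roh_mb = mean(per_animal_sum),
                     stringsAsFactors = FALSE),
          cls_df)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run counts per chromosome per breed
#'
#' @param runs ROH segment data.frame.
#' @param meta [sample_metadata()].
#' @param chroms chromosomes to tabulate (default: those present in `runs`).
#' @return matrix populations x chromosomes of run counts.
#' @export
runs_per_chromosome <- function(runs, meta, chroms = NULL) {
  check_meta(runs$animal_id, meta)
  if (is.null(chroms)) chroms <- sort(unique(runs$chrom))
  pop <- meta$population[match(runs$animal_id, meta$animal_id)]
  tab <- table(factor(pop, levels = sort(unique(meta$population))),
               factor(runs$chrom, levels = chroms))
  m <- as.matrix(unclass(tab))
  dimnames(m) <- list(population = rownames(tab), chrom = colnames(tab))
  m
}
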