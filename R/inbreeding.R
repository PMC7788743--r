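#' ROH-based inbreeding coefficient for one animal
#'
#' F_ROH = L_ROH / L_AUTO, the total autosomal ROH length divided by the
#' SNP-covered autosome length. The conventional OvineSNP50 constant for
#' L_AUTO is 2453 Mb; for panels with a different span use
#' [l_auto_from_map()].
#'
#' @param runs ROH segment data.frame for a single animal (non-overlapping).
#' @param l_auto autosome length in bp (default 2.453e9).
#' @return numeric F_ROH in \[0, 1\].
#' @export
f_roh <- function(runs, l_auto = 2.453e9) {
  stopifnot(l_auto > 0)
  if (nrow(runs) == 0) return(0)
  if (length(unique(runs$animal_id)) > 1) {
    stop("f_roh expects runs for a single animal; see inbreeding_table()")
  }
  sp <- split(seq_len(nrow(runs)), runs$chrom)
  for (ii in sp) {
    o <- ii[order(runs$start_bp[ii])]
    if (length(o) > 1 && any(runs$start_bp[o][-1] <= runs$end_bp[o][-length(o)])) {
      stop("overlapping runs within one animal")
    }
  }
  sum(runs$length_bp) / l_auto
}

#' SNP-covered autosome length from a marker map
#'
#' Sum over chromosomes of (max position - min position + 1).
#'
#' @param map a [snp_map()].
#' @return length in bp.
#' @export
l_auto_from_map <- function(map) {
  sum(vapply(split(map$pos_bp, map$chrom),
             function(p) max(p) - min(p) + 1, numeric(1)))
}

#' B-allele frequencies of a panel
#'
#' Estimated from non-missing calls over all animals.
#'
#' @param panel a [geno_panel()].
#' @return numeric vector, one frequency per marker.
#' @export
allele_freqs <- function(panel) {
  colMeans(panel$calls, na.rm = TRUE) / 2
}

#' Excess-homozygosity inbreeding coefficient for one animal
#'
#' Method-of-moments estimator from observed versus expected homozygosity:
#' F_HOM = (O_hom - E_hom) / (N - E_hom), where over the animal's N
#' non-missing markers O_hom is the observed homozygote count and
#' E_hom = sum_j (1 - 2 p_j q_j) the count expected under Hardy-Weinberg
#' proportions at the panel allele frequencies.
#'
#' @param calls integer status vector for one animal (see [genotype-codes]).
#' @param freqs per-marker B-allele frequencies (from [allele_freqs()],
#'   estimated on the full post-QC panel).
#' @return numeric F_HOM in \[-1, 1\], or NA (with a warning) when
#'   N = E_hom (all informative markers monomorphic).
#' @export
f_hom <- function(calls, freqs) {
  stopifnot(length(calls) == length(freqs))
  nm <- !is.na(calls)
  n <- sum(nm)
  e_het <- 2 * freqs[nm] * (1 - freqs[nm])
  e_hom <- sum(1 - e_het)
  o_hom <- sum(calls[nm] != 1L)
  if (abs(n - e_hom) < .Machine$double.eps * n) {
    warning("F_HOM undefined: expected homozygosity equals marker count")
    return(NA_real_)
  }
  (o_hom - e_hom) / (n - e_hom)
}

#' Per-animal inbreeding table
#'
#' Computes F_ROH for every animal (zero when it has no run) and, when a
#' panel is supplied, F_HOM from the panel allele frequencies.
#'
#' @param runs ROH segment data.frame (all animals).
#' @param meta [sample_metadata()] defining the animal set.
#' @param panel optional [geno_panel()] for F_HOM and for the map-based
#'   L_AUTO.
#' @param l_auto autosome length in bp; `NULL` (default) computes it from
#'   the panel map via [l_auto_from_map()] when a panel is given, else falls
#'   back to the 2453 Mb constant. The mode used is recorded in the
#'   `l_auto` and `l_auto_mode` attributes.
#' @return data.frame: `animal_id`, `population`, `l_roh_bp`, `f_roh`,
#'   and with a panel `o_hom`, `e_hom`, `n_genotyped`, `f_hom`.
#' @export
inbreeding_table <- function(runs, meta, panel = NULL, l_auto = NULL) {
  mode <- if (!is.null(l_auto)) "supplied"
          else if (!is.null(panel)) "map" else "constant"
  if (is.null(l_auto)) {
    l_auto <- if (!is.null(panel)) l_auto_from_map(panel$map) else 2.453e9
  }
  ids <- meta$animal_id
  l_roh <- vapply(ids, function(id)
    sum(runs$length_bp[runs$animal_id == id]), numeric(1))
  out <- data.frame(animal_id = ids, population = meta$population,
                    l_roh_bp = unname(l_roh),
                    f_roh = unname(l_roh) / l_auto,
                    stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    freqs <- allele_freqs(panel)
    idx <- match(ids, panel$animal_ids)
    if (anyNA(idx)) stop("metadata animals missing from panel: ",
                         paste(ids[is.na(idx)], collapse = ", "))
    nmmat <- !is.na(panel$calls)
    e_het <- sweep(nmmat, 2, 2 * freqs * (1 - freqs), `*`)
    e_hom_all <- rowSums(nmmat) - rowSums(e_het)
    o_hom_all <- rowSums(panel$calls != 1L, na.rm = TRUE)
    n_all <- rowSums(nmmat)
    out$o_hom <- o_hom_all[idx]
    out$e_hom <- e_hom_all[idx]
    out$n_genotyped <- n_all[idx]
    denom <- out$n_genotyped - out$e_hom
    out$f_hom <- ifelse(abs(denom) < 1e-12, NA_real_,
                        (out$o_hom - out$e_hom) / denom)
  }
  attr(out, "l_auto") <- l_auto
  attr(out, "l_auto_mode") <- mode
  out
}

#' Per-breed inbreeding summary
#'
#' Mean and sample standard deviation (n - 1 denominator) of F_ROH (and
#' F_HOM when present) per population. Breeds with a single animal report
#' the SD as NA.
#'
#' @param records output of [inbreeding_table()].
#' @param meta [sample_metadata()] (used for the population ordering).
#' @return data.frame: population, n, mean/sd of each coefficient.
#' @export
summarize_inbreeding <- function(records, meta = NULL) {
  pops <- if (is.null(meta)) sort(unique(records$population))
          else sort(unique(meta$population))
  sd1 <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
  rows <- lapply(pops, function(bp) {
    r <- records[records$population == bp, , drop = FALSE]
    d <- data.frame(population = bp, n = nrow(r),
                    mean_f_roh = mean(r$f_roh), sd_f_roh = sd1(r$f_roh),
                    stringsAsFactors = FALSE)
    if ("f_hom" %in% names(r)) {
      d$mean_f_hom <- mean(r$f_hom, na.rm = TRUE)
      d$sd_f_hom <- sd1(r$f_hom[!is.na(r$f_hom)])
    }
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
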