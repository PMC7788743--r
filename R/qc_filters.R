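#' Marker call-rate filter
#'
#' Retains marker j iff its call rate (non-missing calls / animals) is at
#' least `min_rate`. The removal rule is the strict inequality
#' "call rate < min_rate", so a marker exactly at the threshold is kept.
#'
#' @param panel a [geno_panel()].
#' @param min_rate minimum call rate, default 0.95.
#' @return Filtered panel; attribute `n_removed` carries the count.
#' @export
filter_snps_call_rate <- function(panel, min_rate = 0.95) {
  stopifnot(min_rate > 0, min_rate <= 1)
  if (nrow(panel$calls) == 0 || ncol(panel$calls) == 0) {
    warning("empty genotype matrix")
    attr(panel, "n_removed") <- 0L
    return(panel)
  }
  rate <- colMeans(!is.na(panel$calls))
  keep <- rate >= min_rate
  out <- subset_snps(panel, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Minor-allele-frequency filter
#'
#' MAF is computed from non-missing calls only. Retains marker iff
#' MAF >= `min_maf` (strict "< min_maf" removal), so monomorphic markers are
#' always removed. A marker with zero non-missing calls (which the call-rate
#' filter should already have removed) is removed with a warning.
#'
#' @param panel a [geno_panel()].
#' @param min_maf minimum MAF, default 0.01.
#' @return Filtered panel; attribute `n_removed` carries the count.
#' @export
filter_snps_maf <- function(panel, min_maf = 0.01) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  maf <- snp_maf(panel)
  if (anyNA(maf)) {
    warning(sprintf("%d marker(s) with no non-missing calls removed", sum(is.na(maf))))
  }
  keep <- !is.na(maf) & maf >= min_maf
  out <- subset_snps(panel, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-marker minor allele frequency
#'
#' @param panel a [geno_panel()].
#' @return numeric vector, NA for markers with no non-missing calls.
#' @export
snp_maf <- function(panel) {
  p <- colMeans(panel$calls, na.rm = TRUE) / 2  # B-allele frequency
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Animal missingness filter
#'
#' Retains an animal iff its missing-genotype fraction is at most
#' `max_missing` (strict "more than max_missing" removal).
#'
#' @param panel a [geno_panel()].
#' @param max_missing maximum missing fraction, default 0.02.
#' @return Filtered panel; attribute `n_removed` carries the count.
#' @export
filter_animals_missingness <- function(panel, max_missing = 0.02) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  if (ncol(panel$calls) == 0) {
    attr(panel, "n_removed") <- 0L
    return(panel)
  }
  frac <- rowMeans(is.na(panel$calls))
  keep <- frac <= max_missing
  out <- subset_animals(panel, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Apply the full quality-control pipeline
#'
#' Filter order: (markers restricted to autosomes at read time) ->
#' marker call rate -> MAF -> animal missingness. The order is configurable
#' through `order` because marginal removal counts depend on it.
#'
#' @param panel a [geno_panel()] (autosome-restricted, as produced by
#'   [read_ped_map()]).
#' @param min_rate marker call-rate threshold (default 0.95).
#' @param min_maf MAF threshold (default 0.01).
#' @param max_missing animal missingness threshold (default 0.02).
#' @param n_nonautosomal count of markers already dropped for being
#'   non-autosomal (defaults to the panel's `n_nonautosomal` attribute).
#' @param order character vector permutation of
#'   `c("call_rate", "maf", "animal_missing")`.
#' @return list with elements `panel` (filtered) and `report` (a
#'   `qc_report`: in/out dimensions and per-filter removal counts).
#' @export
qc_apply <- function(panel, min_rate = 0.95, min_maf = 0.01, max_missing = 0.02,
                     n_nonautosomal = NULL,
                     order = c("call_rate", "maf", "animal_missing")) {
  stopifnot(setequal(order, c("call_rate", "maf", "animal_missing")))
  if (is.null(n_nonautosomal)) {
    n_nonautosomal <- attr(panel, "n_nonautosomal")
    if (is.null(n_nonautosomal)) n_nonautosomal <- 0L
  }
  n_snps_in <- ncol(panel$calls) + n_nonautosomal
  n_animals_in <- nrow(panel$calls)
  removed <- c(call_rate = 0L, maf = 0L, animal_missing = 0L)
  for (step in order) {
    panel <- switch(step,
      call_rate = filter_snps_call_rate(panel, min_rate),
      maf = filter_snps_maf(panel, min_maf),
      animal_missing = filter_animals_missingness(panel, max_missing))
    removed[step] <- attr(panel, "n_removed")
  }
  report <- structure(list(
    n_snps_in = n_snps_in,
    n_snps_out = ncol(panel$calls),
    n_animals_in = n_animals_in,
    n_animals_out = nrow(panel$calls),
    removed_nonautosomal = as.integer(n_nonautosomal),
    removed_snps_callrate = unname(removed["call_rate"]),
    removed_snps_maf = unname(removed["maf"]),
    removed_animals_missing = unname(removed["animal_missing"]),
    filter_order = order,
    thresholds = c(min_rate = min_rate, min_maf = min_maf,
                   max_missing = max_missing)
  ), class = "qc_report")
  list(panel = panel, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control\n")
  cat(sprintf("  markers:  %d in -> %d out (%d non-autosomal, %d call rate, %d MAF)\n",
              x$n_snps_in, x$n_snps_out, x$removed_nonautosomal,
              x$removed_snps_callrate, x$removed_snps_maf))
  cat(sprintf("  animals:  %d in -> %d out (%d high missingness)\n",
              x$n_animals_in, x$n_animals_out, x$removed_animals_missing))
  cat(sprintf("  order: %s\n", paste(x$filter_order, collapse = " -> ")))
  invisible(x)
}

#' Write a QC report as a two-column TSV
#' @param report a `qc_report` from [qc_apply()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  flat <- report[c("n_snps_in", "n_snps_out", "n_animals_in", "n_animals_out",
                   "removed_nonautosomal", "removed_snps_callrate",
                   "removed_snps_maf", "removed_animals_missing")]
  utils::write.table(
    data.frame(field = names(flat), value = unlist(flat)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
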