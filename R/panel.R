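#' Genotype status codes
#'
#' Genotypes are stored as integer status codes relative to the
#' lexicographically smaller observed allele at each marker: `0` = homozygous
#' for the reference ("A") allele, `1` = heterozygous, `2` = homozygous for
#' the alternate ("B") allele, `NA` = missing. All downstream analyses
#' (ROH detection, F_ROH, F_HOM, islands) depend only on the
#' homozygous/heterozygous/missing status, never on which allele is which.
#'
#' @name genotype-codes
NULL

#' Construct a SNP map
#'
#' An ordered marker panel: one row per marker with chromosome, base-pair
#' position (1-based) and marker id. Rows are sorted by (chrom, pos_bp) and
#' duplicate positions on a chromosome are rejected.
#'
#' @param chrom integer vector of autosome labels (e.g. 1..26 for sheep).
#' @param pos_bp integer vector of 1-based base-pair positions.
#' @param snp_id character vector of unique marker ids.
#' @return A `data.frame` with columns `chrom`, `pos_bp`, `snp_id`, sorted by
#'   (chrom, pos_bp), of class `c("snp_map", "data.frame")`.
#' @export
snp_map <- function(chrom, pos_bp, snp_id) {
  stopifnot(length(chrom) == length(pos_bp), length(pos_bp) == length(snp_id))
  chrom <- as.integer(chrom)
  pos_bp <- as.integer(pos_bp)
  if (any(is.na(chrom)) || any(is.na(pos_bp))) {
    stop("snp_map: chrom and pos_bp must be integer and non-missing")
  }
  if (any(pos_bp < 1L)) stop("snp_map: pos_bp must be >= 1")
  if (anyDuplicated(snp_id)) stop("snp_map: duplicate snp_id")
  m <- data.frame(chrom = chrom, pos_bp = pos_bp,
                  snp_id = as.character(snp_id), stringsAsFactors = FALSE)
  m <- m[order(m$chrom, m$pos_bp), , drop = FALSE]
  rownames(m) <- NULL
  if (anyDuplicated(m[, c("chrom", "pos_bp")])) {
    stop("snp_map: duplicate (chrom, pos_bp)")
  }
  class(m) <- c("snp_map", "data.frame")
  m
}

#' Construct a genotype panel
#'
#' Couples a [snp_map()] with an animals x markers matrix of genotype status
#' codes (see [genotype-codes]). Column j of `calls` corresponds to row j of
#' `map`; row names of `calls` are the animal ids.
#'
#' @param map a [snp_map()].
#' @param calls integer matrix, animals x markers, values in {0, 1, 2, NA};
#'   rownames are unique animal ids.
#' @return An object of class `geno_panel`: a list with elements `map`,
#'   `calls`, `animal_ids`.
#' @export
geno_panel <- function(map, calls) {
  if (!inherits(map, "snp_map")) map <- snp_map(map$chrom, map$pos_bp, map$snp_id)
  if (!is.matrix(calls)) stop("geno_panel: calls must be a matrix")
  storage.mode(calls) <- "integer"
  if (ncol(calls) != nrow(map)) {
    stop(sprintf("geno_panel: %d call columns but %d map rows",
                 ncol(calls), nrow(map)))
  }
  ids <- rownames(calls)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("geno_panel: calls must have unique rownames (animal ids)")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("geno_panel: genotype codes must be 0, 1, 2 or NA")
  }
  colnames(calls) <- map$snp_id
  structure(list(map = map, calls = calls, animal_ids = ids),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("geno_panel: %d animals x %d markers on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing rate %.4f, heterozygosity %.4f\n",
              miss, mean(x$calls == 1L, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.geno_panel <- function(x) dim(x$calls)

#' Subset a panel by marker or animal
#'
#' @param panel a [geno_panel()].
#' @param keep logical or integer index over markers (`subset_snps`) or
#'   animals (`subset_animals`).
#' @return A new `geno_panel`.
#' @export
subset_snps <- function(panel, keep) {
  m <- panel$map[keep, , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("snp_map", "data.frame")
  geno_panel(m, panel$calls[, keep, drop = FALSE])
}

#' @rdname subset_snps
#' @export
subset_animals <- function(panel, keep) {
  geno_panel(panel$map, panel$calls[keep, , drop = FALSE])
}

#' Sample metadata table
#'
#' @param animal_id character vector of unique ids.
#' @param population breed/population label per animal.
#' @param production_system optional label per animal
#'   (e.g. mutton / wool / pelt / dual / non-descript).
#' @return data.frame with one row per animal.
#' @export
sample_metadata <- function(animal_id, population, production_system = NA_character_) {
  if (anyDuplicated(animal_id)) stop("sample_metadata: duplicate animal_id")
  data.frame(animal_id = as.character(animal_id),
             population = as.character(population),
             production_system = rep_len(as.character(production_system),
                                         length(animal_id)),
             stringsAsFactors = FALSE)
}

# internal: check every animal in the panel/run table has exactly one metadata row
check_meta <- function(ids, meta) {
  miss <- setdiff(unique(ids), meta$animal_id)
  if (length(miss)) {
    stop("no metadata for animal(s): ", paste(utils::head(miss, 10), collapse = ", "))
  }
  invisible(TRUE)
}
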