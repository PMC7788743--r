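#' Read PLINK text PED/MAP files into a genotype panel
#'
#' Parses a whitespace-delimited MAP file (chrom, snp_id, cM, bp) and the
#' matching PED file (6 leading columns, then two allele columns per marker).
#' Genotypes are recoded to status codes (see [genotype-codes]) relative to
#' the lexicographically smaller observed allele at each marker. Markers are
#' returned sorted by (chrom, pos_bp) with the PED columns reordered to
#' match; animals keep file order. Markers whose chromosome is not in
#' `autosomes` (sex chromosomes, unmapped contigs coded 0) are dropped and
#' counted.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param autosomes integer vector of chromosome labels to keep
#'   (default `1:26`, the sheep autosomes).
#' @return A [geno_panel()]. Attributes: `n_nonautosomal` (markers dropped),
#'   `n_half_missing` (half-called genotypes such as "A 0", set to missing),
#'   `ped_fam` (the six leading PED columns as a data.frame).
#' @export
read_ped_map <- function(ped_path, map_path, autosomes = 1:26) {
  map_raw <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) != 4L) {
    stop(sprintf("MAP file %s: expected 4 columns, found %d", map_path, ncol(map_raw)))
  }
  names(map_raw) <- c("chrom", "snp_id", "cm", "pos_bp")
  pos <- suppressWarnings(as.numeric(map_raw$pos_bp))
  if (any(is.na(pos))) {
    bad <- which(is.na(pos))[1]
    stop(sprintf("MAP file %s line %d: non-numeric bp position '%s'",
                 map_path, bad, map_raw$pos_bp[bad]))
  }
  chrom <- suppressWarnings(as.integer(map_raw$chrom))
  chrom[is.na(chrom)] <- -1L   # non-numeric contig labels never match autosomes
  n_map <- nrow(map_raw)

  ped <- data.table::fread(ped_path, header = FALSE, data.table = FALSE,
                           colClasses = "character", sep = " ", quote = "")
  if (ncol(ped) == 1L) {  # tab-delimited fallback
    ped <- data.table::fread(ped_path, header = FALSE, data.table = FALSE,
                             colClasses = "character", quote = "")
  }
  if (ncol(ped) != 6L + 2L * n_map) {
    stop(sprintf(
      "PED file %s: %d columns do not match 6 + 2 x %d MAP markers (expected %d)",
      ped_path, ncol(ped), n_map, 6L + 2L * n_map))
  }
  fam <- ped[, 1:6, drop = FALSE]
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "pheno")
  ids <- fam$iid
  if (anyDuplicated(ids)) ids <- paste(fam$fid, fam$iid, sep = "_")

  a1 <- as.matrix(ped[, 6L + 2L * seq_len(n_map) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(n_map), drop = FALSE])
  half <- xor(a1 == "0", a2 == "0")
  n_half <- sum(half)
  if (n_half > 0) {
    warning(sprintf("%d half-missing genotype(s) treated as missing", n_half))
    a1[half] <- "0"
    a2[half] <- "0"
  }
  calls <- matrix(NA_integer_, nrow = nrow(ped), ncol = n_map)
  for (j in seq_len(n_map)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- x1 != "0"
    alleles <- sort(unique(c(x1[ok], x2[ok])))
    if (length(alleles) > 2L) {
      stop(sprintf("marker %s: more than two alleles observed (%s)",
                   map_raw$snp_id[j], paste(alleles, collapse = ",")))
    }
    if (length(alleles) == 0L) next  # all missing
    ref <- alleles[1L]
    calls[ok, j] <- (x1[ok] != ref) + (x2[ok] != ref)
  }
  rownames(calls) <- ids

  keep <- chrom %in% as.integer(autosomes)
  n_drop <- sum(!keep)
  m <- snp_map(chrom[keep], as.integer(pos[keep]), map_raw$snp_id[keep])
  # reorder calls to the sorted map order
  ord <- match(m$snp_id, map_raw$snp_id[keep])
  panel <- geno_panel(m, calls[, which(keep)[ord], drop = FALSE])
  attr(panel, "n_nonautosomal") <- n_drop
  attr(panel, "n_half_missing") <- n_half
  attr(panel, "ped_fam") <- fam
  panel
}

#' Write a genotype panel as PLINK text PED/MAP
#'
#' Alleles are written as "1" (reference status allele) and "2"; missing
#' genotypes as "0 0". Re-reading the files with [read_ped_map()] reproduces
#' the status codes exactly.
#'
#' @param panel a [geno_panel()].
#' @param ped_path,map_path output paths.
#' @param meta optional [sample_metadata()]; when given, the PED family id
#'   column carries the population label.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(panel, ped_path, map_path, meta = NULL) {
  m <- panel$map
  utils::write.table(
    data.frame(m$chrom, m$snp_id, 0L, m$pos_bp),
    map_path, sep = " ", quote = FALSE, row.names = FALSE, col.names = FALSE)

  calls <- panel$calls
  n <- nrow(calls)
  fid <- rep("FAM1", n)
  if (!is.null(meta)) {
    check_meta(panel$animal_ids, meta)
    fid <- meta$population[match(panel$animal_ids, meta$animal_id)]
    fid <- gsub("[[:space:]]", "_", fid)
  }
  a1 <- matrix("0", n, ncol(calls)); a2 <- a1
  a1[!is.na(calls) & calls <= 1L] <- "1"
  a1[!is.na(calls) & calls == 2L] <- "2"
  a2[!is.na(calls) & calls == 0L] <- "1"
  a2[!is.na(calls) & calls >= 1L] <- "2"
  geno <- matrix("", n, 2L * ncol(calls))
  geno[, seq(1L, by = 2L, length.out = ncol(calls))] <- a1
  geno[, seq(2L, by = 2L, length.out = ncol(calls))] <- a2
  lines <- paste(fid, panel$animal_ids, 0L, 0L, 0L, -9L,
                 apply(geno, 1L, paste, collapse = " "))
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a sample-metadata TSV
#'
#' Expects a header and columns `animal_id`, `population`, optionally
#' `production_system`.
#'
#' @param path TSV path.
#' @return A [sample_metadata()] data.frame.
#' @export
read_metadata <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("animal_id", "population")
  if (!all(need %in% names(d))) {
    stop("metadata must have columns animal_id, population")
  }
  sample_metadata(d$animal_id, d$population,
                  if ("production_system" %in% names(d)) d$production_system else NA)
}

#' Write a metadata TSV
#' @param meta a [sample_metadata()] data.frame.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ROH segment table as TSV
#'
#' Columns: animal_id, population, chrom, start_bp, end_bp, n_snps,
#' length_bp, length_class; 1-based inclusive coordinates; rows sorted by
#' (animal_id, chrom, start_bp).
#'
#' @param runs a ROH segment data.frame from [detect_roh()].
#' @param path output path.
#' @export
write_roh_table <- function(runs, path) {
  cols <- c("animal_id", "population", "chrom", "start_bp", "end_bp",
            "n_snps", "length_bp", "length_class")
  if (nrow(runs) == 0) {
    out <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  } else {
    out <- runs[order(runs$animal_id, runs$chrom, runs$start_bp), cols]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ROH segment table written by [write_roh_table()]
#' @param path TSV path.
#' @return data.frame of runs.
#' @export
read_roh_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("chrom", "start_bp", "end_bp", "n_snps", "length_bp")) {
    if (col %in% names(d)) d[[col]] <- as.integer(d[[col]])
  }
  d
}

#' Export runs in BED-like 0-based half-open coordinates
#'
#' Converts the internal 1-based inclusive intervals to the browser
#' convention: `bed_start = start_bp - 1`, `bed_end = end_bp`.
#'
#' @param runs ROH segment data.frame.
#' @param path output path.
#' @export
write_roh_bed <- function(runs, path) {
  bed <- data.frame(chrom = runs$chrom,
                    start = runs$start_bp - 1L,
                    end = runs$end_bp,
                    name = paste(runs$animal_id, runs$length_class, sep = "|"))
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
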