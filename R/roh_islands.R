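#' Incidence of common runs per SNP
#'
#' For every marker, the number of distinct animals with at least one ROH
#' covering its position (1-based inclusive interval containment). An animal
#' counts at most once per marker even if (invalid) overlapping runs cover
#' it twice. Optionally restricted to animals from given production systems.
#'
#' @param runs ROH segment data.frame.
#' @param map a [snp_map()] (the post-QC marker panel).
#' @param meta optional [sample_metadata()]; required when `systems` is used.
#' @param systems optional character vector of production-system labels; only
#'   animals from these systems are counted.
#' @return data.frame `chrom`, `pos_bp`, `snp_id`, `incidence` in map order.
#' @export
incidence_per_snp <- function(runs, map, meta = NULL, systems = NULL) {
  if (!is.null(systems)) {
    if (is.null(meta)) stop("meta is required when restricting by production system")
    keep_ids <- meta$animal_id[meta$production_system %in% systems]
    runs <- runs[runs$animal_id %in% keep_ids, , drop = FALSE]
  }
  if (nrow(runs) && !all(runs$chrom %in% map$chrom)) {
    stop("runs reference chromosome(s) absent from the map: ",
         paste(setdiff(unique(runs$chrom), map$chrom), collapse = ", "))
  }
  inc <- integer(nrow(map))
  for (ch in unique(runs$chrom)) {
    midx <- which(map$chrom == ch)
    pos <- map$pos_bp[midx]
    r <- runs[runs$chrom == ch, , drop = FALSE]
    # union of intervals per animal so one animal counts once per marker
    for (id in unique(r$animal_id)) {
      ra <- r[r$animal_id == id, , drop = FALSE]
      ra <- ra[order(ra$start_bp), , drop = FALSE]
      cov <- logical(length(midx))
      for (k in seq_len(nrow(ra))) {
        lo <- findInterval(ra$start_bp[k] - 1L, pos) + 1L
        hi <- findInterval(ra$end_bp[k], pos)
        if (hi >= lo) cov[lo:hi] <- TRUE
      }
      inc[midx] <- inc[midx] + cov
    }
  }
  data.frame(chrom = map$chrom, pos_bp = map$pos_bp, snp_id = map$snp_id,
             incidence = inc, stringsAsFactors = FALSE)
}

#' Call ROH islands from per-SNP incidence
#'
#' An island is a maximal stretch of consecutive markers whose incidence
#' exceeds `min_samples`, reported iff its span (end - start + 1) exceeds
#' `min_span_bp` and it holds at least `min_snps` member markers. With
#' `max_gap_bp > 0`, adjacent above-threshold stretches separated by no more
#' than `max_gap_bp` are merged (member markers remain the above-threshold
#' ones only); the default 0 keeps strict consecutiveness.
#'
#' @param inc incidence table from [incidence_per_snp()].
#' @param min_samples incidence threshold; membership requires
#'   incidence strictly greater than this (default 20).
#' @param min_span_bp minimum island span, strict (default 1e6).
#' @param min_snps minimum member markers (default 30).
#' @param max_gap_bp merge distance for adjacent stretches (default 0 = off).
#' @return data.frame of islands: `island_id`, `chrom`, `start_bp`,
#'   `end_bp`, `span_bp`, `n_snps`, `min_incidence`, `max_incidence`,
#'   `mean_incidence`, sorted by (chrom, start_bp). Attribute
#'   `member_snps`: list of member snp_id vectors per island.
#' @export
call_islands <- function(inc, min_samples = 20, min_span_bp = 1e6,
                         min_snps = 30, max_gap_bp = 0) {
  empty <- data.frame(island_id = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      span_bp = numeric(), n_snps = integer(),
                      min_incidence = integer(), max_incidence = integer(),
                      mean_incidence = numeric(), stringsAsFactors = FALSE)
  if (nrow(inc) == 0) { attr(empty, "member_snps") <- list(); return(empty) }
  rows <- list(); members <- list()
  for (ch in unique(inc$chrom)) {
    d <- inc[inc$chrom == ch, , drop = FALSE]
    above <- d$incidence > min_samples
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seg <- cbind(starts[r$values], ends[r$values])  # index stretches above threshold
    # optional merge across narrow sub-threshold gaps
    if (max_gap_bp > 0 && nrow(seg) > 1) {
      merged <- seg[1, , drop = FALSE]
      for (k in 2:nrow(seg)) {
        gap <- d$pos_bp[seg[k, 1]] - d$pos_bp[merged[nrow(merged), 2]]
        if (gap <= max_gap_bp) merged[nrow(merged), 2] <- seg[k, 2]
        else merged <- rbind(merged, seg[k, ])
      }
      seg <- merged
    }
    for (k in seq_len(nrow(seg))) {
      ii <- seg[k, 1]:seg[k, 2]
      ii <- ii[d$incidence[ii] > min_samples]  # members stay above threshold
      span <- d$pos_bp[max(ii)] - d$pos_bp[min(ii)] + 1
      if (span <= min_span_bp || length(ii) < min_snps) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_bp = d$pos_bp[min(ii)], end_bp = d$pos_bp[max(ii)],
        span_bp = span, n_snps = length(ii),
        min_incidence = min(d$incidence[ii]),
        max_incidence = max(d$incidence[ii]),
        mean_incidence = mean(d$incidence[ii]), stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- d$snp_id[ii]
    }
  }
  if (!length(rows)) { attr(empty, "member_snps") <- list(); return(empty) }
  out <- do.call(rbind, rows)
  o <- order(out$chrom, out$start_bp)
  out <- out[o, , drop = FALSE]
  members <- members[o]
  out <- cbind(island_id = paste0("ROH", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  names(members) <- out$island_id
  attr(out, "member_snps") <- members
  out
}

# internal: member marker positions of one island row
island_member_pos <- function(island, map, member_snps = NULL) {
  if (!is.null(member_snps)) {
    map$pos_bp[match(member_snps, map$snp_id)]
  } else {
    map$pos_bp[map$chrom == island$chrom &
               map$pos_bp >= island$start_bp & map$pos_bp <= island$end_bp]
  }
}

#' Classify islands by population sharing
#'
#' A population contributes to an island iff at least one of its animals has
#' a ROH overlapping at least one member marker. Classes: `unique` (1
#' population), `shared` (2-3), `common` (>3).
#'
#' @param islands island table from [call_islands()].
#' @param runs ROH segment data.frame.
#' @param meta [sample_metadata()].
#' @param map the [snp_map()] used for incidence.
#' @return the island table with added columns `n_populations`,
#'   `sharing_class` and `populations` (comma-separated), plus the
#'   `member_snps` attribute carried through.
#' @export
classify_island_sharing <- function(islands, runs, meta, map) {
  check_meta(runs$animal_id, meta)
  members <- attr(islands, "member_snps")
  pop_of <- meta$population[match(runs$animal_id, meta$animal_id)]
  n_pop <- integer(nrow(islands)); pops_str <- character(nrow(islands))
  for (i in seq_len(nrow(islands))) {
    pos <- island_member_pos(islands[i, ], map,
                             if (!is.null(members)) members[[i]] else NULL)
    rsel <- which(runs$chrom == islands$chrom[i] &
                  runs$start_bp <= max(pos) & runs$end_bp >= min(pos))
    hit <- vapply(rsel, function(k)
      any(pos >= runs$start_bp[k] & pos <= runs$end_bp[k]), logical(1))
    pops <- sort(unique(pop_of[rsel[hit]]))
    n_pop[i] <- length(pops)
    pops_str[i] <- paste(pops, collapse = ",")
  }
  islands$n_populations <- n_pop
  islands$sharing_class <- cut(n_pop, breaks = c(0, 1, 3, Inf),
                               labels = c("unique", "shared", "common"))
  islands$populations <- pops_str
  attr(islands, "member_snps") <- members
  islands
}

#' Per-sample proportion of island SNPs covered by ROH
#'
#' For each island and each animal, the fraction of the island's member
#' markers that fall inside at least one of the animal's runs (0..1).
#'
#' @param islands island table from [call_islands()].
#' @param runs ROH segment data.frame.
#' @param meta [sample_metadata()] (defines the sample set; animals with no
#'   run score 0).
#' @param map the [snp_map()].
#' @return long data.frame: `island_id`, `animal_id`, `population`,
#'   `proportion`.
#' @export
island_snp_proportions <- function(islands, runs, meta, map) {
  members <- attr(islands, "member_snps")
  out <- vector("list", nrow(islands))
  for (i in seq_len(nrow(islands))) {
    pos <- island_member_pos(islands[i, ], map,
                             if (!is.null(members)) members[[i]] else NULL)
    r <- runs[runs$chrom == islands$chrom[i] &
              runs$start_bp <= max(pos) & runs$end_bp >= min(pos), , drop = FALSE]
    prop <- vapply(meta$animal_id, function(id) {
      ra <- r[r$animal_id == id, , drop = FALSE]
      if (!nrow(ra)) return(0)
      cov <- rep(FALSE, length(pos))
      for (k in seq_len(nrow(ra))) {
        cov <- cov | (pos >= ra$start_bp[k] & pos <= ra$end_bp[k])
      }
      mean(cov)
    }, numeric(1))
    out[[i]] <- data.frame(island_id = islands$island_id[i],
                           animal_id = meta$animal_id,
                           population = meta$population,
                           proportion = unname(prop),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(island_id = character(), animal_id = character(),
                      population = character(), proportion = numeric())
  }
  rownames(res) <- NULL
  res
}

#' One-way breed-effect model on island SNP proportions
#'
#' Fits proportion = mu + B_i + e per island by least squares with a
#' sum-to-zero constraint on the breed effects B_i, and tests the breed
#' effect with the ANOVA F-test.
#'
#' @param proportions data.frame with columns `population` and `proportion`
#'   (one island's rows from [island_snp_proportions()]).
#' @return list of class `island_breed_model`: `mu`, `effects` (named,
#'   summing to zero), `sigma2` (residual variance), `f_statistic`,
#'   `df`, `p_value`, `n_per_breed`. `NULL` with a message if fewer than two
#'   breeds have at least two samples.
#' @export
fit_breed_model <- function(proportions) {
  d <- data.frame(population = factor(proportions$population),
                  proportion = proportions$proportion)
  tab <- table(d$population)
  if (sum(tab >= 2) < 2) {
    message("breed model skipped: need >= 2 breeds with >= 2 samples")
    return(NULL)
  }
  d <- droplevels(d[d$population %in% names(tab)[tab >= 1], , drop = FALSE])
  fit <- stats::lm(proportion ~ population, data = d,
                   contrasts = list(population = "contr.sum"))
  av <- stats::anova(fit)
  cf <- stats::coef(fit)
  eff <- c(cf[-1], -sum(cf[-1]))
  names(eff) <- levels(d$population)
  structure(list(mu = unname(cf[1]),
                 effects = eff,
                 sigma2 = av["Residuals", "Mean Sq"],
                 f_statistic = av["population", "F value"],
                 df = unname(unlist(av[["Df"]])),
                 p_value = av["population", "Pr(>F)"],
                 n_per_breed = c(table(d$population))),
            class = "island_breed_model")
}

#' @export
print.island_breed_model <- function(x, ...) {
  cat(sprintf("island breed model: mu = %.4f, F(%d, %d) = %.3f, p = %.3g\n",
              x$mu, x$df[1], x$df[2], x$f_statistic, x$p_value))
  print(round(x$effects, 4))
  invisible(x)
}

#' Fit the breed model for every island
#'
#' @param prop_table long table from [island_snp_proportions()].
#' @return data.frame: island_id, f_statistic, p_value, mu, n_breeds; one
#'   row per island for which the model could be fitted.
#' @export
fit_breed_models <- function(prop_table) {
  ids <- unique(prop_table$island_id)
  rows <- lapply(ids, function(id) {
    m <- suppressMessages(
      fit_breed_model(prop_table[prop_table$island_id == id, , drop = FALSE]))
    if (is.null(m)) return(NULL)
    data.frame(island_id = id, mu = m$mu, f_statistic = m$f_statistic,
               p_value = m$p_value, n_breeds = length(m$effects),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(island_id = character(), mu = numeric(),
                                      f_statistic = numeric(),
                                      p_value = numeric(), n_breeds = integer())
  rownames(out) <- NULL
  out
}

#' Per-breed mean and SD of island SNP proportions
#'
#' @param prop_table long table from [island_snp_proportions()].
#' @return data.frame: island_id, population, n, mean_proportion,
#'   sd_proportion.
#' @export
island_breed_proportions <- function(prop_table) {
  agg <- stats::aggregate(proportion ~ island_id + population, data = prop_table,
                          FUN = function(x) c(n = length(x), mean = mean(x),
                                              sd = stats::sd(x)))
  out <- data.frame(island_id = agg$island_id, population = agg$population,
                    n = agg$proportion[, "n"],
                    mean_proportion = agg$proportion[, "mean"],
                    sd_proportion = agg$proportion[, "sd"],
                    stringsAsFactors = FALSE)
  out[order(out$island_id, out$population), ]
}
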