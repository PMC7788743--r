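# Independent oracles and fixture builders for the test suite.
#
# The brute-force routines deliberately re-derive every run/incidence
# definition from scratch (explicit window enumeration, double loops) so the
# package implementation is checked against an independent code path.

# status-code shorthands for hand-built fixtures
HOM <- 0L; HET <- 1L; MIS <- NA_integer_

# Is the window calls[i..j] a compliant run? Direct predicate evaluation.
window_ok <- function(calls, pos, i, j, p) {
  g <- calls[i:j]
  if (is.na(g[1]) || g[1] == 1L) return(FALSE)
  gl <- g[length(g)]
  if (is.na(gl) || gl == 1L) return(FALSE)
  if (sum(g == 1L, na.rm = TRUE) > p$max_het) return(FALSE)
  if (sum(is.na(g)) > p$max_missing) return(FALSE)
  span <- pos[j] - pos[i] + 1
  if (span < p$min_length_bp) return(FALSE)
  if ((j - i + 1L) < p$min_snps) return(FALSE)
  if (span / (j - i + 1L) > p$min_density_bp_per_snp) return(FALSE)
  nm <- pos[i:j][!is.na(g)]
  if (length(nm) > 1 && any(diff(nm) > p$max_gap_bp)) return(FALSE)
  TRUE
}

# Shared selection rule: given all compliant windows, pick non-overlapping
# runs leftmost-start first (ties: largest end).
select_nonoverlapping <- function(wins) {
  sel <- list()
  while (length(wins)) {
    starts <- vapply(wins, `[`, integer(1), 1L)
    ends <- vapply(wins, `[`, integer(1), 2L)
    cand <- which(starts == min(starts))
    pick <- cand[which.max(ends[cand])]
    w <- wins[[pick]]
    sel[[length(sel) + 1L]] <- w
    wins <- wins[starts > w[2]]
  }
  if (!length(sel)) {
    return(data.frame(start_idx = integer(), end_idx = integer()))
  }
  m <- do.call(rbind, sel)
  data.frame(start_idx = m[, 1], end_idx = m[, 2])
}

# Brute-force consecutive-runs oracle: enumerate every (i, j) window with a
# direct per-window predicate, then apply the selection rule.
brute_force_runs <- function(calls, pos, p = rohscan::roh_params()) {
  n <- length(calls)
  wins <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L < p$min_snps) next
      if (window_ok(calls, pos, i, j, p)) {
        wins[[length(wins) + 1L]] <- c(i, j)
      }
    }
  }
  select_nonoverlapping(wins)
}

# Same enumeration with O(1) per-window checks from cumulative counts, so
# chromosomes of ~500 markers stay tractable. Still checks every window;
# independent of the detector's scan logic.
brute_force_runs_fast <- function(calls, pos, p = rohscan::roh_params()) {
  n <- length(calls)
  is_hom <- !is.na(calls) & calls != 1L
  ch <- cumsum(c(0L, !is.na(calls) & calls == 1L))   # hets up to index
  cm <- cumsum(c(0L, is.na(calls)))                  # missing up to index
  nm_rank <- cumsum(!is.na(calls))                   # rank among non-missing
  nm_idx <- which(!is.na(calls))
  # bad gap between consecutive non-missing markers t and t+1
  bad <- if (length(nm_idx) > 1) diff(pos[nm_idx]) > p$max_gap_bp else logical(0)
  cbad <- cumsum(c(0L, bad))
  wins <- list()
  for (i in seq_len(n)) {
    if (!is_hom[i]) next
    js <- (i + p$min_snps - 1L):n
    if (!length(js) || js[1] > n) next
    nsnp <- js - i + 1L
    span <- pos[js] - pos[i] + 1
    a <- nm_rank[i]
    b <- nm_rank[js]
    ok <- is_hom[js] &
      (ch[js + 1L] - ch[i] <= p$max_het) &
      (cm[js + 1L] - cm[i] <= p$max_missing) &
      span >= p$min_length_bp &
      span / nsnp <= p$min_density_bp_per_snp &
      (cbad[b] - cbad[a] == 0L)
    for (j in js[ok]) wins[[length(wins) + 1L]] <- c(i, j)
  }
  select_nonoverlapping(wins)
}

# Brute-force per-SNP incidence: double loop over (animal, marker).
brute_force_incidence <- function(runs, map) {
  ids <- unique(runs$animal_id)
  inc <- integer(nrow(map))
  for (s in seq_len(nrow(map))) {
    for (id in ids) {
      r <- runs[runs$animal_id == id & runs$chrom == map$chrom[s], , drop = FALSE]
      if (any(r$start_bp <= map$pos_bp[s] & r$end_bp >= map$pos_bp[s])) {
        inc[s] <- inc[s] + 1L
      }
    }
  }
  inc
}

# Random one-chromosome genotype vector for property tests: homozygous
# stretches embedded in heterozygous-rich background, sprinkled missing.
random_chrom <- function(n_snps, p_het = 0.3, p_miss = 0.02,
                         spacing = 5e4, jitter = 2.5e4, p_biggap = 0.01) {
  gaps <- floor(runif(n_snps, spacing - jitter, spacing + jitter))
  big <- runif(n_snps) < p_biggap
  gaps[big] <- 3e5
  pos <- cumsum(gaps)
  u <- runif(n_snps)
  calls <- ifelse(u < p_het, 1L, ifelse(u < p_het + (1 - p_het) / 2, 0L, 2L))
  calls[runif(n_snps) < p_miss] <- NA_integer_
  # embed a couple of long homozygous stretches so runs actually occur
  for (k in 1:2) {
    at <- sample(n_snps - 60L, 1L)
    len <- sample(30:60, 1L)
    calls[at:(at + len - 1L)] <- sample(c(0L, 2L), len, replace = TRUE)
  }
  list(calls = calls, pos = pos)
}

# Tiny panel built by hand from a status matrix (one chromosome).
toy_panel <- function(status, pos = NULL, chrom = 1L) {
  if (is.null(pos)) pos <- seq_len(ncol(status)) * 50000L
  m <- rohscan::snp_map(rep(chrom, ncol(status)), pos,
                        sprintf("s%d", seq_len(ncol(status))))
  if (is.null(rownames(status))) {
    rownames(status) <- sprintf("a%d", seq_len(nrow(status)))
  }
  rohscan::geno_panel(m, status)
}

# Planted-segment recovery bookkeeping: for each truth interval with at
# least min_snps covered markers, span >= min_len and no internal marker gap
# above max_gap (an interval straddling a super-threshold gap cannot be one
# run under the gap rule, by definition), find whether a detected run of the
# same animal covers its first..last covered marker.
recovery_status <- function(truth_iv, runs, map, min_snps = 30, min_len = 1e6,
                            max_gap = 2.5e5) {
  out <- lapply(seq_len(nrow(truth_iv)), function(k) {
    tv <- truth_iv[k, ]
    pos <- map$pos_bp[map$chrom == tv$chrom &
                      map$pos_bp >= tv$start_bp & map$pos_bp <= tv$end_bp]
    eligible <- length(pos) >= min_snps &&
      (tv$end_bp - tv$start_bp + 1) >= min_len &&
      (length(pos) < 2 || max(diff(pos)) <= max_gap)
    if (!eligible || !length(pos)) {
      return(data.frame(eligible = eligible, recovered = NA,
                        exact = NA, slack_bp = NA_real_))
    }
    r <- runs[runs$animal_id == tv$animal_id & runs$chrom == tv$chrom, , drop = FALSE]
    hit <- r$start_bp <= min(pos) & r$end_bp >= max(pos)
    if (!any(hit)) {
      return(data.frame(eligible = TRUE, recovered = FALSE,
                        exact = FALSE, slack_bp = NA_real_))
    }
    rr <- r[which(hit)[1], ]
    data.frame(eligible = TRUE, recovered = TRUE,
               exact = rr$start_bp == min(pos) && rr$end_bp == max(pos),
               slack_bp = (min(pos) - rr$start_bp) + (rr$end_bp - max(pos)))
  })
  do.call(rbind, out)
}
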