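# Permutation (shuffle) association tests between interval sets.
#
# Shuffling is genome-wide: each interval keeps its length and is dropped
# uniformly at random onto any chromosome where it fits (weighted by the
# number of admissible start positions), optionally avoiding an excluded
# interval set by rejection sampling. For the large shuffle counts used in
# the null-model tests the placements and overlap counts are fully
# vectorized in a concatenated coordinate space.

.concat_offsets <- function(sizes) {
  off <- cumsum(c(0, as.numeric(sizes)))
  setNames(off[seq_along(sizes)], names(sizes))
}

# merged intervals in concatenated space: matrix with columns s, e (closed)
.concat_merged <- function(gr, sizes) {
  if (length(gr) == 0) return(cbind(s = numeric(0), e = numeric(0)))
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  off <- .concat_offsets(sizes)
  ch <- as.character(GenomicRanges::seqnames(red))
  if (!all(ch %in% names(sizes))) stop("intervals on chromosomes absent from `sizes`")
  s <- off[ch] + GenomicRanges::start(red)
  o <- order(s)
  cbind(s = s[o], e = (off[ch] + GenomicRanges::end(red))[o])
}

# do closed intervals [s, s+len-1] (concatenated coords) hit any merged peak?
.hits_merged <- function(s, len, merged) {
  if (nrow(merged) == 0) return(rep(FALSE, length(s)))
  e <- s + len - 1
  idx <- findInterval(e, merged[, "s"])
  idx > 0 & merged[, "e"][pmax(idx, 1)] >= s
}

# sample start positions: chromosome chosen with probability proportional to
# the number of admissible starts for each interval's length; returns
# concatenated coordinates. lens recycled over n placements.
.sample_starts <- function(lens, sizes, n_rep) {
  sizes_n <- as.numeric(sizes)
  off <- .concat_offsets(sizes)
  lens_all <- rep(lens, n_rep)
  ulen <- sort(unique(lens))
  out <- numeric(length(lens_all))
  for (L in ulen) {
    sel <- which(lens_all == L)
    room <- pmax(sizes_n - L + 1, 0)
    if (sum(room) <= 0) stop("an interval of ", L, " nt fits on no chromosome")
    ci <- sample.int(length(sizes_n), length(sel), replace = TRUE,
                     prob = room)
    st <- floor(runif(length(sel)) * room[ci]) + 1
    out[sel] <- unname(off[ci]) + st
  }
  out
}

#' Randomly shuffle an interval set across the genome
#'
#' Produces a random interval set with the same multiset of lengths as the
#' input, placed uniformly over all admissible positions genome-wide
#' (optionally avoiding an excluded set, e.g. assembly gaps). Reproducible
#' under `seed`.
#'
#' @param sites `GRanges` to shuffle (only the lengths are used).
#' @param sizes Named chromosome sizes.
#' @param excluded Optional `GRanges` that shuffled intervals must not touch.
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling cap when `excluded` is dense.
#' @return A `GRanges` with the same number and lengths of intervals.
#' @export
shuffle_intervals <- function(sites, sizes, excluded = NULL, seed = NULL,
                              max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  lens <- GenomicRanges::width(sites)
  excl <- if (is.null(excluded)) {
    cbind(s = numeric(0), e = numeric(0))
  } else {
    .concat_merged(excluded, sizes)
  }
  s <- .sample_starts(lens, sizes, 1L)
  for (k in seq_len(max_tries)) {
    bad <- .hits_merged(s, lens, excl)
    if (!any(bad)) break
    s[bad] <- .sample_starts(lens[bad], sizes, 1L)
    if (k == max_tries) stop("could not place all intervals outside `excluded`")
  }
  .starts_to_granges(s, lens, sizes)
}

.starts_to_granges <- function(s, lens, sizes) {
  off <- .concat_offsets(sizes)
  brk <- c(unname(off), sum(as.numeric(sizes)))
  ci <- findInterval(s - 0.5, brk)
  GenomicRanges::GRanges(
    names(sizes)[ci],
    IRanges::IRanges(start = as.integer(s - unname(off)[ci]), width = lens)
  )
}

.enrichment_result <- function(observed, null, n_shuffles, seed, flag = NULL) {
  null_mean <- mean(null)
  structure(
    list(
      observed = observed,
      null_mean = null_mean,
      null_sd = sd(null),
      fold_enrichment = if (null_mean > 0) observed / null_mean else NA_real_,
      empirical_p = (1 + sum(null >= observed)) / (1 + n_shuffles),
      n_shuffles = n_shuffles,
      seed = seed,
      flag = flag
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: observed %.4g, null %.4g +/- %.3g -> fold %.3f (p = %.2g, %d shuffles)\n",
    x$observed, x$null_mean, x$null_sd, x$fold_enrichment, x$empirical_p,
    x$n_shuffles))
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Shuffle enrichment of site/peak overlap
#'
#' Counts the sites overlapping at least one peak (by >= 1 bp) and compares
#' it to the same count for randomly shuffled site sets of identical number
#' and lengths. Fold enrichment is observed / mean(null); the empirical
#' p-value uses the add-one estimator `(1 + #{null >= observed}) /
#' (1 + n_shuffles)` and so is never zero.
#'
#' @param sites `GRanges` query sites.
#' @param peaks `GRanges` reference features (e.g. Pol II ChIP-seq peaks).
#' @param sizes Named chromosome sizes.
#' @param n_shuffles Number of random placements (>= 100).
#' @param seed Optional integer seed.
#' @param excluded Optional `GRanges` to avoid when shuffling.
#' @return An `enrichment_result`.
#' @export
peak_overlap_enrichment <- function(sites, peaks, sizes, n_shuffles = 10000,
                                    seed = NULL, excluded = NULL) {
  if (n_shuffles < 100) stop("`n_shuffles` must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  lens <- GenomicRanges::width(sites)
  n_sites <- length(sites)
  merged <- .concat_merged(peaks, sizes)
  flag <- if (length(peaks) == 0) "empty peak set: fold undefined" else NULL
  obs_s <- .concat_merged_sites(sites, sizes)
  observed <- sum(.hits_merged(obs_s, lens, merged))
  if (!is.null(excluded)) {
    null <- vapply(seq_len(n_shuffles), function(k) {
      sh <- shuffle_intervals(sites, sizes, excluded = excluded)
      ss <- .concat_merged_sites(sh, sizes)
      sum(.hits_merged(ss, GenomicRanges::width(sh), merged))
    }, numeric(1))
  } else {
    s_all <- .sample_starts(lens, sizes, n_shuffles)
    hit <- .hits_merged(s_all, rep(lens, n_shuffles), merged)
    null <- as.numeric(rowsum(as.numeric(hit),
                              rep(seq_len(n_shuffles), each = n_sites)))
  }
  .enrichment_result(observed, null, n_shuffles, seed, flag)
}

# concatenated start coordinates of actual sites (not merged; order kept)
.concat_merged_sites <- function(sites, sizes) {
  off <- .concat_offsets(sizes)
  ch <- as.character(GenomicRanges::seqnames(sites))
  unname(off[ch]) + GenomicRanges::start(sites)
}

#' Shuffle enrichment of read coverage under sites
#'
#' Total read coverage under the sites compared to the mean total under
#' randomly shuffled site sets of the same number and lengths. Scale
#' invariant: doubling all counts leaves the fold unchanged.
#'
#' @param sites `GRanges` query sites.
#' @param reads A [coverage_track()] (unstranded) or a `GRanges` of read
#'   intervals, typically restricted to peak regions.
#' @param sizes Named chromosome sizes.
#' @param n_shuffles Number of random placements.
#' @param seed Optional integer seed.
#' @return An `enrichment_result` (`observed` is the read total under sites).
#' @export
coverage_enrichment <- function(sites, reads, sizes, n_shuffles = 1000,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vecs <- if (inherits(reads, "coverage_track")) {
    if (reads$stranded) {
      mapply(function(a, b) a + b, reads$data[["+"]], reads$data[["-"]],
             SIMPLIFY = FALSE)
    } else {
      reads$data
    }
  } else {
    cov <- lapply(names(sizes), function(chrom) {
      sub <- reads[as.character(GenomicRanges::seqnames(reads)) == chrom]
      v <- numeric(sizes[[chrom]])
      if (length(sub)) {
        for (i in seq_along(sub)) {
          s <- max(1L, GenomicRanges::start(sub)[i])
          e <- min(sizes[[chrom]], GenomicRanges::end(sub)[i])
          v[s:e] <- v[s:e] + 1
        }
      }
      v
    })
    setNames(cov, names(sizes))
  }
  csum <- cumsum(c(0, unlist(vecs[names(sizes)], use.names = FALSE)))
  total <- csum[length(csum)]
  flag <- if (total == 0) "zero total coverage" else NULL
  lens <- GenomicRanges::width(sites)
  n_sites <- length(sites)
  obs_s <- .concat_merged_sites(sites, sizes)
  observed <- sum(csum[obs_s + lens] - csum[obs_s])
  s_all <- .sample_starts(lens, sizes, n_shuffles)
  per <- csum[s_all + rep(lens, n_shuffles)] - csum[s_all]
  null <- as.numeric(rowsum(per, rep(seq_len(n_shuffles), each = n_sites)))
  .enrichment_result(observed, null, n_shuffles, seed, flag)
}
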