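#' Candidate pause loci from GRO-seq / Pol II peak overlap
#'
#' Retains GRO-seq peaks whose intersection with some single Pol II ChIP-seq
#' peak exceeds `min_frac` of the GRO peak's length (strictly greater:
#' exactly 50% does not qualify at the default).
#'
#' @param gro_peaks `GRanges` GRO-seq peaks (strand = nascent-RNA strand).
#' @param polII_peaks `GRanges` Pol II ChIP-seq peaks.
#' @param min_frac Overlap fraction that must be exceeded.
#' @return The qualifying subset of `gro_peaks`.
#' @export
overlap_filter <- function(gro_peaks, polII_peaks, min_frac = 0.5) {
  if (length(gro_peaks) == 0 || length(polII_peaks) == 0)
    return(gro_peaks[integer(0)])
  hits <- GenomicRanges::findOverlaps(gro_peaks, polII_peaks,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(gro_peaks[integer(0)])
  qh <- S4Vectors::queryHits(hits)
  ov <- GenomicRanges::pintersect(gro_peaks[qh],
                                  polII_peaks[S4Vectors::subjectHits(hits)],
                                  ignore.strand = TRUE)
  w <- GenomicRanges::width(ov)
  best <- tapply(w, qh, max)
  idx <- as.integer(names(best))
  keep <- idx[best > min_frac * GenomicRanges::width(gro_peaks)[idx]]
  gro_peaks[sort(keep)]
}

#' Fit a power-law null to an mNET-seq coverage histogram
#'
#' Models the low-coverage noise floor as `N_x = a * x^-b` and estimates
#' (a, b) by least squares on log N vs log x over the fit range (coverage
#' counts 3 to 100 by default). The input histogram is fit as given — pass
#' normalized frequencies to recover density-scale parameters.
#'
#' @param coverage_freq The coverage histogram: a two-column data frame
#'   (`coverage`, `freq`), or a named numeric vector / `table` with coverage
#'   values as names.
#' @param fit_range Inclusive coverage range used for the fit.
#' @return An object of class `powerlaw_null`: `a`, `b`, `a_err`, `b_err`
#'   (standard errors), `fit_range`, `n_points`.
#' @export
fit_powerlaw_null <- function(coverage_freq, fit_range = c(3, 100)) {
  if (is.table(coverage_freq) || (is.numeric(coverage_freq) &&
                                  !is.null(names(coverage_freq)))) {
    coverage_freq <- data.frame(
      coverage = as.numeric(names(coverage_freq)),
      freq = as.numeric(coverage_freq))
  }
  stopifnot(is.data.frame(coverage_freq),
            all(c("coverage", "freq") %in% names(coverage_freq)))
  d <- coverage_freq[coverage_freq$coverage >= fit_range[1] &
                       coverage_freq$coverage <= fit_range[2] &
                       coverage_freq$freq > 0, ]
  if (length(unique(d$coverage)) < 10)
    stop("need >= 10 distinct coverage values with positive frequency in the fit range")
  fit <- lm(log(freq) ~ log(coverage), data = d)
  # noiseless tabulations fit exactly; the SE machinery still applies
  sm <- suppressWarnings(summary(fit))$coefficients
  structure(
    list(
      a = exp(unname(coef(fit)[1])),
      b = -unname(coef(fit)[2]),
      a_err = exp(unname(coef(fit)[1])) * sm[1, 2],
      b_err = sm[2, 2],
      fit_range = fit_range,
      n_points = nrow(d)
    ),
    class = "powerlaw_null"
  )
}

#' @export
print.powerlaw_null <- function(x, ...) {
  cat(sprintf("powerlaw_null: N_x = %.4f * x^-%.4f (fit on %d..%d, %d points)\n",
              x$a, x$b, x$fit_range[1], x$fit_range[2], x$n_points))
  invisible(x)
}

#' Upper-tail probability under a power-law null
#'
#' P(X >= x) for the discrete null with pmf proportional to `k^-b` on
#' integer support `k >= fit_range[1]`, extended analytically beyond the fit
#' range (tail sums, the default p-value convention). Coverage below the fit
#' range gets p = 1.
#'
#' @param null A [fit_powerlaw_null()] object.
#' @param x Coverage values (non-integers are rounded up).
#' @return Vector of tail probabilities in (0, 1].
#' @export
pl_tail_prob <- function(null, x) {
  lo <- null$fit_range[1]
  b <- null$b
  kmax <- max(10000, ceiling(max(x, na.rm = TRUE)) + 10)
  k <- lo:kmax
  w <- k^(-b)
  # analytic continuation of the far tail (integral approximation)
  far <- if (b > 1) (kmax + 0.5)^(1 - b) / (b - 1) else 0
  z <- sum(w) + far
  tail_from <- rev(cumsum(rev(w))) + far
  xi <- ceiling(x)
  p <- rep(1, length(x))
  inside <- !is.na(xi) & xi >= lo & xi <= kmax
  p[inside] <- tail_from[xi[inside] - lo + 1] / z
  p[!is.na(xi) & xi > kmax] <- far / z
  p
}

#' FDR filter of candidate loci by mNET-seq coverage
#'
#' Computes per-locus p-values from the power-law noise null (upper tail at
#' the locus's mNET coverage), corrects them by Benjamini-Hochberg and keeps
#' loci with q at or below the FDR cutoff.
#'
#' @param loci `GRanges` candidate loci.
#' @param mnet Either a numeric vector of per-locus mNET coverage statistics
#'   or a stranded [coverage_track()] from which the maximum single-base
#'   coverage on each locus's strand is taken.
#' @param null A [fit_powerlaw_null()] object.
#' @param fdr FDR cutoff.
#' @return The retained loci with `mnet_cov`, `p_value`, `mnet_fdr_q`
#'   metadata columns.
#' @export
mnet_fdr_filter <- function(loci, mnet, null, fdr = 0.05) {
  stopifnot(inherits(null, "powerlaw_null"))
  cov <- if (inherits(mnet, "coverage_track")) {
    vapply(seq_along(loci), function(i) {
      v <- .cov_get(mnet, as.character(GenomicRanges::seqnames(loci)[i]),
                    GenomicRanges::start(loci)[i],
                    GenomicRanges::end(loci)[i],
                    strand = .locus_strand(loci, i))
      if (all(is.na(v))) 0 else max(v, na.rm = TRUE)
    }, numeric(1))
  } else {
    as.numeric(mnet)
  }
  stopifnot(length(cov) == length(loci))
  p <- pl_tail_prob(null, cov)
  q <- p.adjust(p, method = "BH")
  GenomicRanges::mcols(loci)$mnet_cov <- cov
  GenomicRanges::mcols(loci)$p_value <- p
  GenomicRanges::mcols(loci)$mnet_fdr_q <- q
  loci[q <= fdr]
}

.locus_strand <- function(loci, i) {
  st <- as.character(GenomicRanges::strand(loci)[i])
  if (st == "*") NULL else st
}

#' Rank pause loci by combined signal strength
#'
#' Each locus's signal in each assay is its total coverage within the locus;
#' per-assay ranks run from 1 (strongest) with ties averaged. Loci are
#' ordered by the sum of the four ranks (Pol II ChIP, GRO, NET, mNET), ties
#' broken by mNET rank and then genomic position; `final_rank` 1 is the
#' strongest locus.
#'
#' @param loci `GRanges` (typically after [mnet_fdr_filter()]).
#' @param tracks Named list of [coverage_track()]s with elements `chip`,
#'   `gro`, `net`, `mnet`; stranded tracks are read on each locus's strand.
#' @return `loci` reordered by `final_rank`, with per-assay `signal_*` and
#'   `rank_*` columns, `sum_rank` and `final_rank`.
#' @export
rank_loci <- function(loci, tracks) {
  need <- c("chip", "gro", "net", "mnet")
  if (!all(need %in% names(tracks)))
    stop("`tracks` must contain: ", paste(need, collapse = ", "))
  if (length(loci) == 0) return(loci)
  mc <- GenomicRanges::mcols(loci)
  ranks <- matrix(NA_real_, length(loci), length(need),
                  dimnames = list(NULL, need))
  for (a in need) {
    sig <- .cov_sum(tracks[[a]], loci)
    mc[[paste0("signal_", a)]] <- sig
    ranks[, a] <- rank(-sig, ties.method = "average")
    mc[[paste0("rank_", a)]] <- ranks[, a]
  }
  mc$sum_rank <- rowSums(ranks)
  GenomicRanges::mcols(loci) <- mc
  ord <- order(mc$sum_rank, ranks[, "mnet"],
               as.character(GenomicRanges::seqnames(loci)),
               GenomicRanges::start(loci))
  loci <- loci[ord]
  GenomicRanges::mcols(loci)$final_rank <- seq_along(loci)
  loci
}

#' Strongest (and second) mNET-seq spike within loci
#'
#' The pause-site coordinate: the position of maximal single-nucleotide
#' mNET-seq coverage within each locus on its own strand. Ties resolve to
#' the 5'-most position in transcription orientation. The second spike is
#' the next-highest position at least 1 nt away; the signed spike distance
#' (second minus first, transcription-oriented) probes possible backtracking.
#'
#' @param loci `GRanges` loci with strand.
#' @param mnet A stranded [coverage_track()].
#' @return Data frame with `spike_pos`, `spike_height`, `second_spike_pos`,
#'   `second_spike_height`, `spike_distance`; all-`NA` rows flag loci with
#'   no mNET signal.
#' @export
strongest_spike <- function(loci, mnet) {
  out <- data.frame(
    spike_pos = rep(NA_integer_, length(loci)),
    spike_height = NA_real_,
    second_spike_pos = NA_integer_,
    second_spike_height = NA_real_,
    spike_distance = NA_integer_
  )
  for (i in seq_along(loci)) {
    chrom <- as.character(GenomicRanges::seqnames(loci)[i])
    st <- as.character(GenomicRanges::strand(loci)[i])
    s <- GenomicRanges::start(loci)[i]
    e <- GenomicRanges::end(loci)[i]
    v <- .cov_get(mnet, chrom, s, e, strand = .locus_strand(loci, i))
    v[is.na(v)] <- 0
    if (max(v) <= 0) next
    cand <- which(v == max(v))
    k1 <- if (st == "-") max(cand) else min(cand)  # 5'-most
    out$spike_pos[i] <- s + k1 - 1L
    out$spike_height[i] <- v[k1]
    v2 <- v
    v2[k1] <- -Inf
    if (max(v2) > 0) {
      cand2 <- which(v2 == max(v2))
      k2 <- if (st == "-") max(cand2) else min(cand2)
      out$second_spike_pos[i] <- s + k2 - 1L
      out$second_spike_height[i] <- v2[k2]
      d <- (k2 - k1)
      out$spike_distance[i] <- if (st == "-") -d else d
    }
  }
  out
}

#' Classify pause loci as intragenic or intergenic
#'
#' A locus is intragenic when its midpoint lies within an annotated
#' transcript. Distances to the nearest gene's TSS and TTS are signed in
#' that gene's transcription orientation (positive = downstream of the TSS /
#' TTS).
#'
#' @param loci `GRanges` loci.
#' @param genes `GRanges` gene models (after [select_transcripts()]).
#' @return `loci` with `genic_class`, `dist_tss`, `dist_tts` columns.
#' @export
classify_genic <- function(loci, genes) {
  if (length(loci) == 0) {
    GenomicRanges::mcols(loci)$genic_class <- character(0)
    return(loci)
  }
  mids <- floor((GenomicRanges::start(loci) + GenomicRanges::end(loci)) / 2)
  midgr <- GenomicRanges::GRanges(GenomicRanges::seqnames(loci),
                                  IRanges::IRanges(mids, mids))
  inside <- IRanges::overlapsAny(midgr, genes, ignore.strand = TRUE)
  tss <- .tss(genes)
  tts <- .tts(genes)
  gstrand <- as.character(GenomicRanges::strand(genes))
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  lchrom <- as.character(GenomicRanges::seqnames(midgr))
  dist_tss <- rep(NA_real_, length(loci))
  dist_tts <- rep(NA_real_, length(loci))
  for (i in seq_along(loci)) {
    same <- which(gchrom == lchrom[i])
    if (!length(same)) next
    # nearest gene by TSS distance; for intragenic midpoints restrict to
    # covering transcripts
    cand <- same
    if (inside[i]) {
      cov <- same[GenomicRanges::start(genes)[same] <= mids[i] &
                    GenomicRanges::end(genes)[same] >= mids[i]]
      if (length(cov)) cand <- cov
    }
    dd <- abs(mids[i] - tss[cand])
    j <- cand[which.min(dd)]
    sgn <- if (gstrand[j] == "-") -1 else 1
    dist_tss[i] <- sgn * (mids[i] - tss[j])
    dist_tts[i] <- sgn * (mids[i] - tts[j])
  }
  GenomicRanges::mcols(loci)$genic_class <-
    ifelse(inside, "intragenic", "intergenic")
  GenomicRanges::mcols(loci)$dist_tss <- dist_tss
  GenomicRanges::mcols(loci)$dist_tts <- dist_tts
  loci
}

#' Annotation-free pause-site calling pipeline
#'
#' Chains the pause-site operations: GRO peaks filtered for > 50% overlap
#' with Pol II ChIP peaks, an mNET-seq power-law noise null (fitted from the
#' genome-wide histogram of nonzero per-base mNET coverage when not
#' supplied), the 5% FDR coverage filter, signal-sum ranking, and strongest
#' mNET spike localization.
#'
#' @param gro_peaks,chip_peaks `GRanges` peak sets.
#' @param tracks Named list with `chip`, `gro`, `net`, `mnet`
#'   [coverage_track()]s (`mnet` stranded).
#' @param null Optional precomputed [fit_powerlaw_null()].
#' @param fdr FDR cutoff for the mNET filter.
#' @param min_frac Overlap fraction for the candidate filter.
#' @return Ranked `GRanges` of pause loci with spike columns attached.
#' @export
call_pause_sites <- function(gro_peaks, chip_peaks, tracks, null = NULL,
                             fdr = 0.05, min_frac = 0.5) {
  loci <- overlap_filter(gro_peaks, chip_peaks, min_frac = min_frac)
  if (is.null(null)) {
    null <- fit_powerlaw_null(mnet_coverage_histogram(tracks$mnet))
  }
  loci <- mnet_fdr_filter(loci, tracks$mnet, null, fdr = fdr)
  loci <- rank_loci(loci, tracks)
  sp <- strongest_spike(loci, tracks$mnet)
  GenomicRanges::mcols(loci) <- cbind(GenomicRanges::mcols(loci), sp)
  loci
}

#' Histogram of nonzero per-base mNET coverage
#'
#' Pools both strands of a stranded track and tabulates the frequency of
#' each positive integer coverage value among positions with any signal —
#' the input [fit_powerlaw_null()] expects.
#'
#' @param mnet A [coverage_track()].
#' @return Data frame with `coverage` and `freq` (fractions summing to 1).
#' @export
mnet_coverage_histogram <- function(mnet) {
  vals <- if (mnet$stranded) {
    c(unlist(mnet$data[["+"]], use.names = FALSE),
      unlist(mnet$data[["-"]], use.names = FALSE))
  } else {
    unlist(mnet$data, use.names = FALSE)
  }
  vals <- vals[vals > 0]
  if (!length(vals)) stop("track has no positive coverage")
  tab <- table(round(vals))
  data.frame(coverage = as.numeric(names(tab)),
             freq = as.numeric(tab) / length(vals))
}
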