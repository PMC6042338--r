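#' Genome-wide stability threshold from the lower quantile
#'
#' The threshold separating "highly stable" windows: the q-quantile of all
#' non-missing window dG values pooled across profiles (lower tail = most
#' stable, since more negative dG means a more stable structure). The
#' empirical type-1 quantile is used, with ties counted on the stable side
#' when sites are called (`dG <= threshold`).
#'
#' @param profiles One [fe_profile()] or a list of them (as returned by
#'   [scan_genome()]).
#' @param q Lower-tail fraction; 0.05 marks the lowest 5% of all values.
#' @return The dG threshold (kcal/mol).
#' @export
genome_quantile_threshold <- function(profiles, q = 0.05) {
  if (inherits(profiles, "fe_profile")) profiles <- list(profiles)
  vals <- unlist(lapply(profiles, function(p) p$values), use.names = FALSE)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("all window values are missing")
  if (length(vals) < 20) stop("need at least 20 non-missing window values")
  quantile(vals, q, type = 1, names = FALSE)
}

#' Call highly stable secondary-structure sites
#'
#' A site is a maximal run of at least `min_run` consecutive windows whose
#' dG is at or below the threshold; it spans from the first window's start
#' to the last window's end, so with 300-nt windows at 150-nt step the
#' shortest callable site is 1200 nt and a run of k windows spans
#' `(k - 1) * step + window` nt. Missing windows (N-containing) break runs.
#'
#' @param profile One [fe_profile()] or a list of them.
#' @param threshold dG cutoff (kcal/mol), e.g. from
#'   [genome_quantile_threshold()].
#' @param min_run Minimum number of consecutive qualifying windows.
#' @return A sorted `GRanges` of sites with `n_windows` and `min_dg`
#'   metadata columns; sites never overlap.
#' @export
call_stable_sites <- function(profile, threshold, min_run = 7) {
  if (inherits(profile, "fe_profile")) profile <- list(profile)
  per_chrom <- lapply(profile, function(p) {
    v <- p$values
    below <- !is.na(v) & v <= threshold
    if (!any(below)) return(GenomicRanges::GRanges())
    r <- rle(below)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    if (!any(keep)) return(GenomicRanges::GRanges())
    i0 <- starts_i[keep]
    i1 <- ends_i[keep]
    gs <- p$start + (i0 - 1L) * p$step
    ge <- p$start + (i1 - 1L) * p$step + p$window - 1L
    GenomicRanges::GRanges(
      p$chrom, IRanges::IRanges(gs, ge),
      n_windows = i1 - i0 + 1L,
      min_dg = vapply(seq_along(i0),
                      function(k) min(v[i0[k]:i1[k]]), numeric(1))
    )
  })
  out <- do.call(c, unname(per_chrom))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

# strand-aware functional regions of a gene set (1-based closed),
# clipped to [1, chromosome length] when sizes are supplied
.gene_regions <- function(genes, sizes = NULL) {
  tss <- .tss(genes)
  tts <- .tts(genes)
  strand <- as.character(GenomicRanges::strand(genes))
  chrom <- as.character(GenomicRanges::seqnames(genes))
  mk <- function(span, keep = rep(TRUE, length(genes))) {
    s <- span[, "start"]
    e <- span[, "end"]
    keep <- keep & (s <= e)
    if (!any(keep)) return(GenomicRanges::GRanges())
    s <- s[keep]; e <- e[keep]; ch <- chrom[keep]
    if (!is.null(sizes)) {
      lim <- unname(sizes[ch])
      s <- pmax(1, pmin(s, lim))
      e <- pmax(1, pmin(e, lim))
    } else {
      s <- pmax(1, s)
      e <- pmax(1, e)
    }
    GenomicRanges::GRanges(ch, IRanges::IRanges(s, e))
  }
  list(
    TSS = mk(.oriented_span(tss, strand, -250L, 250L)),
    TTS = mk(.oriented_span(tts, strand, -250L, 250L)),
    promoter = mk(.oriented_span(tss, strand, -1000L, -251L)),
    gene_body = mk(.oriented_span(tss, strand, 251L, abs(tts - tss) - 251L),
                   keep = abs(tts - tss) >= 502L)
  )
}

#' Annotate stable sites against gene models
#'
#' Assigns each site to exactly one functional class with precedence
#' TSS > TTS > promoter > gene body > intergenic: sites overlapping a TSS
#' region (TSS +/- 250 nt) take that class first, the remainder are compared
#' to TTS regions (TTS +/- 250 nt), then promoters (-1 knt to -250 nt of the
#' TSS, in transcription orientation), then gene bodies (TSS + 250 to
#' TTS - 250). Class densities are normalized by the class territory — the
#' union of the class's regions after removing territory already claimed by
#' higher-precedence classes, so territories partition the genome and
#' densities are comparable across classes.
#'
#' @param sites `GRanges` of sites (e.g. from [call_stable_sites()]).
#' @param genes `GRanges` gene models with strand.
#' @param sizes Named chromosome sizes, required to measure the intergenic
#'   territory.
#' @return A list with `site_class` (factor, one entry per site) and
#'   `summary` (data frame: class, n_sites, territory_bp, density_per_mb).
#' @export
annotate_sites <- function(sites, genes, sizes) {
  regions <- .gene_regions(genes, sizes)
  classes <- c("TSS", "TTS", "promoter", "gene_body")
  # precedence: first matching class wins
  cls <- rep("intergenic", length(sites))
  unassigned <- rep(TRUE, length(sites))
  for (cl in classes) {
    hit <- unassigned &
      IRanges::overlapsAny(sites, regions[[cl]], ignore.strand = TRUE)
    cls[hit] <- cl
    unassigned <- unassigned & !hit
  }
  cls <- factor(cls, levels = c(classes, "intergenic"))

  genome_gr <- GenomicRanges::GRanges(
    names(sizes), IRanges::IRanges(1L, unname(sizes)))
  claimed <- GenomicRanges::GRanges()
  territory <- numeric(0)
  for (cl in classes) {
    ter <- GenomicRanges::setdiff(
      GenomicRanges::reduce(regions[[cl]], ignore.strand = TRUE), claimed,
      ignore.strand = TRUE)
    territory[cl] <- sum(GenomicRanges::width(ter))
    claimed <- GenomicRanges::reduce(c(claimed, ter), ignore.strand = TRUE)
  }
  inter <- GenomicRanges::setdiff(genome_gr, claimed, ignore.strand = TRUE)
  territory["intergenic"] <- sum(GenomicRanges::width(inter))

  counts <- table(cls)
  summary <- data.frame(
    class = names(territory),
    n_sites = as.integer(counts[names(territory)]),
    territory_bp = as.numeric(territory),
    row.names = NULL
  )
  summary$density_per_mb <- ifelse(summary$territory_bp > 0,
                                   summary$n_sites / (summary$territory_bp / 1e6),
                                   NA_real_)
  list(site_class = cls, summary = summary)
}
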