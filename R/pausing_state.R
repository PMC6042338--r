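#' Select one transcript per gene and apply analysis filters
#'
#' Keeps the longest transcript of each gene (ties broken by leftmost start,
#' then lexicographic transcript id), removes transcripts shorter than
#' 660 nt (twice the TSS-window span, so pausing status can be assessed),
#' and, when a genome is supplied, removes genes with undetermined bases (N)
#' within TSS +/- `flank`.
#'
#' @param genes `GRanges` with a `gene_id` column (and optionally `tx_id`).
#' @param genome Optional `DNAStringSet` or FASTA path for the N filter.
#' @param min_length Minimum transcript length (nt).
#' @param flank Half-width of the N-screened TSS region (nt); spans reaching
#'   past a chromosome end are clipped before screening.
#' @return The filtered `GRanges`, one range per retained gene.
#' @export
select_transcripts <- function(genes, genome = NULL, min_length = 660,
                               flank = 2000) {
  stopifnot(!is.null(genes$gene_id))
  tx_id <- if (!is.null(genes$tx_id)) genes$tx_id else
    as.character(seq_along(genes))
  ord <- order(genes$gene_id,
               -GenomicRanges::width(genes),
               GenomicRanges::start(genes),
               tx_id)
  g <- genes[ord]
  g <- g[!duplicated(g$gene_id)]
  g <- g[GenomicRanges::width(g) >= min_length]
  if (!is.null(genome) && length(g)) {
    gen <- read_genome(genome)
    sz <- chrom_sizes(gen)
    tss <- .tss(g)
    chrom <- as.character(GenomicRanges::seqnames(g))
    has_n <- vapply(seq_along(g), function(i) {
      s <- max(1L, tss[i] - as.integer(flank))
      e <- min(sz[[chrom[i]]], tss[i] + as.integer(flank))
      sub <- Biostrings::subseq(gen[[chrom[i]]], s, e)
      Biostrings::countPattern("N", sub) > 0
    }, logical(1))
    g <- g[!has_n]
  }
  GenomicRanges::sort(g, ignore.strand = TRUE)
}

#' Traveling ratio of genes from Pol II coverage
#'
#' The traveling ratio (TR) is the read density (per-base coverage divided
#' by region length) over the TSS window (-30 to +300 nt from the TSS, in
#' transcription orientation, anchored on the TSS and not clipped to the
#' transcript) divided by the density over the rest of the gene body
#' (TSS + 301 to the transcript end). TR is `Inf` when the body density is
#' zero but the TSS window holds signal, and `NaN` when the gene carries no
#' coverage at all.
#'
#' @param genes `GRanges` gene models (length > 330 nt each, guaranteed by
#'   the 660-nt filter of [select_transcripts()]).
#' @param coverage A [coverage_track()] (typically Pol II ChIP-seq,
#'   unstranded).
#' @param tss_window Oriented offset range of the TSS window.
#' @return A data frame with `gene_id`, `tss_density`, `body_density`, `tr`.
#' @export
traveling_ratio <- function(genes, coverage, tss_window = c(-30, 300)) {
  strand <- as.character(GenomicRanges::strand(genes))
  chrom <- as.character(GenomicRanges::seqnames(genes))
  tss <- .tss(genes)
  tts <- .tts(genes)
  win <- .oriented_span(tss, strand, tss_window[1], tss_window[2])
  body <- .oriented_span(tss, strand, tss_window[2] + 1L, abs(tts - tss))
  win_len <- tss_window[2] - tss_window[1] + 1L
  res <- vapply(seq_along(genes), function(i) {
    wv <- .cov_get(coverage, chrom[i], win[i, "start"], win[i, "end"])
    bv <- .cov_get(coverage, chrom[i], body[i, "start"], body[i, "end"])
    c(sum(wv, na.rm = TRUE) / win_len,
      sum(bv, na.rm = TRUE) / length(bv))
  }, numeric(2))
  tssd <- res[1, ]
  bodyd <- res[2, ]
  data.frame(
    gene_id = genes$gene_id,
    tss_density = tssd,
    body_density = bodyd,
    tr = tssd / bodyd,
    stringsAsFactors = FALSE
  )
}

#' Classify genes into pausing states
#'
#' Genes are first stratified by Pol II binding: a gene overlapping no Pol II
#' peak is `NP2` (no Pol II). Bound genes are split by traveling ratio into
#' paused (`PAU`, TR > 2; an infinite TR counts as paused) and non-paused
#' (`NPA`, TR <= 2). A bound gene with no coverage at all (undefined TR) is
#' called `NPA`: its binding is the only evidence and it shows no
#' promoter-proximal accumulation.
#'
#' @param genes `GRanges` gene models (after [select_transcripts()]).
#' @param peaks `GRanges` of Pol II ChIP-seq peaks.
#' @param coverage Pol II [coverage_track()].
#' @param tr_cutoff Pausing threshold on TR.
#' @return A data frame (one row per gene) with densities, `tr`, `bound` and
#'   `state`; the named fractions of the three states (summing to 1) are
#'   attached as attribute `"fractions"`.
#' @export
classify_pausing <- function(genes, peaks, coverage, tr_cutoff = 2) {
  tr <- traveling_ratio(genes, coverage)
  bound <- IRanges::overlapsAny(genes, peaks, ignore.strand = TRUE)
  state <- ifelse(!bound, "NP2",
                  ifelse(!is.nan(tr$tr) & tr$tr > tr_cutoff, "PAU", "NPA"))
  out <- cbind(tr,
               chrom = as.character(GenomicRanges::seqnames(genes)),
               strand = as.character(GenomicRanges::strand(genes)),
               bound = bound,
               state = factor(state, levels = c("NP2", "NPA", "PAU")))
  frac <- prop.table(table(out$state))
  attr(out, "fractions") <- frac
  out
}

#' Concordance of pausing across samples
#'
#' Spearman rank correlation of traveling ratios over the genes bound by
#' Pol II in both members of each sample pair, plus the number of genes that
#' switch state (PAU -> NPA or NPA -> PAU) between the two samples.
#'
#' @param tables A named list of [classify_pausing()] outputs (>= 2) sharing
#'   gene ids.
#' @return A list with `correlation` (Spearman matrix), `switched` (data
#'   frame of pairwise switch counts and shared-gene counts). Pairs sharing
#'   fewer than 10 bound genes are flagged with `NA` correlation.
#' @export
concordance <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2)
  nm <- names(tables)
  if (is.null(nm)) nm <- paste0("sample", seq_along(tables))
  k <- length(tables)
  cmat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(cmat) <- 1
  sw <- data.frame(sample_a = character(0), sample_b = character(0),
                   n_shared = integer(0), n_switched = integer(0))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    ta <- tables[[a]]
    tb <- tables[[b]]
    shared <- intersect(ta$gene_id[ta$state != "NP2"],
                        tb$gene_id[tb$state != "NP2"])
    ia <- match(shared, ta$gene_id)
    ib <- match(shared, tb$gene_id)
    if (length(shared) >= 10) {
      cmat[a, b] <- cmat[b, a] <-
        cor(rank(ta$tr[ia]), rank(tb$tr[ib]))
    } else {
      warning("fewer than 10 shared Pol II-bound genes for ",
              nm[a], " vs ", nm[b])
    }
    switched <- sum((ta$state[ia] == "PAU" & tb$state[ib] == "NPA") |
                      (ta$state[ia] == "NPA" & tb$state[ib] == "PAU"))
    sw <- rbind(sw, data.frame(sample_a = nm[a], sample_b = nm[b],
                               n_shared = length(shared),
                               n_switched = switched))
  }
  list(correlation = cmat, switched = sw)
}
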