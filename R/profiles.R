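#' Anchored per-base signal matrix
#'
#' Builds a loci x offsets matrix of track values around anchor points
#' (TSS, mNET spike, or peak summit), transcription-oriented: rows of
#' minus-strand anchors are flipped so negative offsets are always upstream.
#' Positions beyond a chromosome edge are `NA`.
#'
#' @param anchors `GRanges` of single-base anchor positions with strand
#'   (`*` treated as `+`). Row names come from a `name` or `gene_id` column
#'   when present.
#' @param track A [coverage_track()]; stranded tracks are read on each
#'   anchor's strand.
#' @param flank Half-width in nt; offsets run `-flank..+flank`.
#' @param order_by Optional numeric vector (one per anchor); rows are sorted
#'   by it increasingly.
#' @return A numeric matrix with offset column names, class
#'   `profile_matrix`.
#' @export
anchored_matrix <- function(anchors, track, flank, order_by = NULL) {
  n <- length(anchors)
  offs <- seq.int(-flank, flank)
  m <- matrix(NA_real_, n, length(offs),
              dimnames = list(.anchor_ids(anchors), offs))
  for (i in seq_len(n)) {
    chrom <- as.character(GenomicRanges::seqnames(anchors)[i])
    st <- as.character(GenomicRanges::strand(anchors)[i])
    pos <- GenomicRanges::start(anchors)[i]
    v <- .cov_get(track, chrom, pos - flank, pos + flank,
                  strand = if (track$stranded && st != "*") st else NULL)
    if (st == "-") v <- rev(v)
    m[i, ] <- v
  }
  if (!is.null(order_by)) m <- m[order(order_by), , drop = FALSE]
  class(m) <- c("profile_matrix", class(m))
  m
}

.anchor_ids <- function(anchors) {
  mc <- GenomicRanges::mcols(anchors)
  if ("name" %in% names(mc)) return(as.character(mc$name))
  if ("gene_id" %in% names(mc)) return(as.character(mc$gene_id))
  as.character(seq_along(anchors))
}

#' Anchored free-energy (or GC) profile matrix
#'
#' For each anchor, folds 30-nt windows sliding 1 nt at a time over the
#' non-template strand around the anchor and assigns each window's dG to its
#' middle (15th) nucleotide, yielding per-base dG values at offsets
#' `-flank..+flank` (minus-strand anchors oriented so negative offsets are
#' upstream in transcription direction). `what = "gc"` returns the windowed
#' GC fraction on the identical geometry, so GC and dG profiles are directly
#' comparable.
#'
#' @param anchors `GRanges` single-base anchors with strand.
#' @param genome `DNAStringSet` or FASTA path.
#' @param params [fold_params()].
#' @param flank Half-width in nt.
#' @param window Window width (30-nt default; the 15th-nt rule assumes it).
#' @param what `"dg"` (fold) or `"gc"` (GC fraction).
#' @return A `profile_matrix` (loci x offsets).
#' @export
anchored_dg_matrix <- function(anchors, genome, params = fold_params(),
                               flank = 200, window = 30,
                               what = c("dg", "gc")) {
  what <- match.arg(what)
  g <- read_genome(genome)
  sz <- chrom_sizes(g)
  half_lo <- 14L
  half_hi <- window - 15L
  offs <- seq.int(-flank, flank)
  n <- length(anchors)
  m <- matrix(NA_real_, n, length(offs),
              dimnames = list(.anchor_ids(anchors), offs))
  tab <- energy_tables(params)
  for (i in seq_len(n)) {
    chrom <- as.character(GenomicRanges::seqnames(anchors)[i])
    st <- as.character(GenomicRanges::strand(anchors)[i])
    pos <- GenomicRanges::start(anchors)[i]
    lo_off <- -flank - half_lo
    hi_off <- flank + half_hi
    span <- if (st == "-") c(pos - hi_off, pos - lo_off) else
      c(pos + lo_off, pos + hi_off)
    cs <- max(1L, span[1])
    ce <- min(sz[[chrom]], span[2])
    if (ce - cs + 1L < window) next
    s <- as.character(Biostrings::subseq(g[[chrom]], cs, ce))
    if (st == "-") s <- .revcomp(s)
    # oriented offset of the first base of the extracted sequence
    first_off <- if (st == "-") -(min(sz[[chrom]], span[2]) - pos) else
      cs - pos
    si <- .dna_int(s)
    starts0 <- seq.int(0L, length(si) - window)
    vals <- if (what == "dg") {
      .dg_windows(si, starts0, window, params, tables = tab, seq_chr = s)
    } else {
      .gc_windows(si, starts0, window)
    }
    centers <- first_off + starts0 + half_lo
    keep <- centers >= -flank & centers <= flank
    m[i, as.character(centers[keep])] <- vals[keep]
  }
  class(m) <- c("profile_matrix", class(m))
  m
}

.gc_windows <- function(si, starts0, window) {
  isgc <- as.numeric(si == 1L | si == 2L)
  bad <- si > 3L
  cg <- cumsum(c(0, isgc))
  cb <- cumsum(c(0, bad))
  v <- (cg[starts0 + window + 1L] - cg[starts0 + 1L]) / window
  v[(cb[starts0 + window + 1L] - cb[starts0 + 1L]) > 0] <- NA_real_
  v
}

#' Column means of a profile matrix
#'
#' Missing-aware average profile: per-offset means ignoring `NA`, with the
#' number of contributing loci reported per offset.
#'
#' @param mat A `profile_matrix` (or any loci x offsets matrix with offset
#'   column names).
#' @return Data frame with `offset`, `mean`, `n`.
#' @export
average_profile <- function(mat) {
  data.frame(
    offset = as.numeric(colnames(mat)),
    mean = colMeans(mat, na.rm = TRUE),
    n = colSums(!is.na(mat)),
    row.names = NULL
  )
}

#' Locate the minimum of an average free-energy profile
#'
#' Returns the contiguous offset interval around the deepest point of the
#' profile: all offsets whose value is within `eps` of the minimum and
#' connected to the argmin. A profile flat over the whole search window is
#' flagged degenerate.
#'
#' @param avg Output of [average_profile()], or a named numeric vector.
#' @param search Optional `c(lo, hi)` offset range to search within.
#' @param eps Tolerance (kcal/mol) defining the minimum plateau.
#' @return List with `interval` (offset range), `offset` (argmin), `value`
#'   and `degenerate`.
#' @export
locate_min <- function(avg, search = NULL, eps = 0.25) {
  if (is.data.frame(avg)) {
    offs <- avg$offset
    v <- avg$mean
  } else {
    offs <- as.numeric(names(avg))
    v <- as.numeric(avg)
  }
  keep <- !is.na(v)
  if (!is.null(search)) keep <- keep & offs >= search[1] & offs <= search[2]
  offs <- offs[keep]
  v <- v[keep]
  if (!length(v)) stop("no values in the search window")
  imin <- which.min(v)
  near <- v <= v[imin] + eps
  # contiguous run containing the argmin
  r <- rle(near)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blk <- which(starts <= imin & ends >= imin)
  lo <- starts[blk]
  hi <- ends[blk]
  list(
    interval = c(offs[lo], offs[hi]),
    offset = offs[imin],
    value = v[imin],
    degenerate = all(near)
  )
}

#' Strand bias of secondary-structure stability near the TSS
#'
#' Compares the mean 30-nt windowed dG over a TSS-proximal region between
#' the non-template strand (free to fold during transcription) and the
#' template strand, gene by gene, with a paired t-test summary. A negative
#' mean difference says the non-template strand folds more stably.
#'
#' @param genes `GRanges` gene models (after [select_transcripts()]).
#' @param genome `DNAStringSet` or FASTA path.
#' @param params [fold_params()].
#' @param region Oriented offset range relative to the TSS.
#' @param window Fold window (nt); windows are fully inside `region`.
#' @return List with `per_gene` (data frame of per-strand means and their
#'   difference), `mean_difference`, `statistic`, `p_value`.
#' @export
strand_bias <- function(genes, genome, params = fold_params(),
                        region = c(-30, 300), window = 30) {
  g <- read_genome(genome)
  nt <- numeric(length(genes))
  tp <- numeric(length(genes))
  for (i in seq_along(genes)) {
    s <- non_template_sequence(genes[i], g, region[1], region[2] + 1L)
    vals_nt <- dg_sliding(s, params, window = window, step = 1)
    vals_tp <- rev(dg_sliding(.revcomp(s), params, window = window, step = 1))
    nt[i] <- mean(vals_nt, na.rm = TRUE)
    tp[i] <- mean(vals_tp, na.rm = TRUE)
  }
  per_gene <- data.frame(
    gene_id = if (!is.null(genes$gene_id)) genes$gene_id else
      as.character(seq_along(genes)),
    dg_non_template = nt,
    dg_template = tp,
    difference = nt - tp
  )
  tt <- if (length(genes) >= 2 && sd(per_gene$difference) > 0) {
    t.test(nt, tp, paired = TRUE)
  }
  list(
    per_gene = per_gene,
    mean_difference = mean(per_gene$difference),
    statistic = if (!is.null(tt)) unname(tt$statistic) else NA_real_,
    p_value = if (!is.null(tt)) tt$p.value else NA_real_
  )
}

#' Positional density of extreme free-energy windows
#'
#' For a pooled dG matrix, marks the windows falling in a global percentile
#' band (lowest 2% = most stable structures by default, or highest 2%) and
#' returns the per-offset frequency of band membership — a flat line for
#' exchangeable values, peaks where extreme structures concentrate.
#'
#' @param mat A `profile_matrix` of dG values.
#' @param tail `"low"` (most stable) or `"high"`.
#' @param frac Band mass (0.02 = 2%).
#' @return Data frame with `offset` and `frequency` (fraction of non-missing
#'   loci in the band at each offset).
#' @export
extreme_density <- function(mat, tail = c("low", "high"), frac = 0.02) {
  tail <- match.arg(tail)
  pooled <- as.numeric(mat)
  pooled <- pooled[!is.na(pooled)]
  if (!length(pooled)) stop("matrix has no values")
  inband <- if (tail == "low") {
    thr <- quantile(pooled, frac, type = 1, names = FALSE)
    mat <= thr
  } else {
    thr <- quantile(pooled, 1 - frac, type = 1, names = FALSE)
    mat >= thr
  }
  data.frame(
    offset = as.numeric(colnames(mat)),
    frequency = colMeans(inband, na.rm = TRUE),
    row.names = NULL
  )
}
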