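#' Free-energy profile container
#'
#' Holds the dG values of a regular sliding-window scan over one
#' chromosome (or any single sequence). Windows containing ambiguous bases
#' carry `NA` (sites of incomplete sequence are excluded from analyses, and
#' they break runs when sites are called).
#'
#' @param chrom Chromosome / sequence identifier.
#' @param values Numeric dG vector, one entry per complete window (`NA` =
#'   missing).
#' @param window,step Window geometry in nt.
#' @param start 1-based genomic position of the first window's first base.
#' @param strand Strand the folded sequence was taken from.
#' @return An object of class `fe_profile`.
#' @export
fe_profile <- function(chrom, values, window = 300, step = 150,
                       start = 1L, strand = "+") {
  stopifnot(window >= 1, step >= 1, start >= 1)
  structure(
    list(chrom = chrom, values = as.numeric(values),
         window = as.integer(window), step = as.integer(step),
         start = as.integer(start), strand = strand),
    class = "fe_profile"
  )
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf(
    "fe_profile: %s (%s), %d windows of %d nt / step %d; dG range [%.1f, %.1f]\n",
    x$chrom, x$strand, length(x$values), x$window, x$step,
    suppressWarnings(min(x$values, na.rm = TRUE)),
    suppressWarnings(max(x$values, na.rm = TRUE))
  ))
  invisible(x)
}

#' Genomic intervals of a profile's windows
#'
#' @param profile An [fe_profile()].
#' @return A `GRanges`, one range per window, with the window dG as `score`.
#' @export
profile_windows <- function(profile) {
  stopifnot(inherits(profile, "fe_profile"))
  n <- length(profile$values)
  starts <- profile$start + (seq_len(n) - 1L) * profile$step
  GenomicRanges::GRanges(
    profile$chrom,
    IRanges::IRanges(starts, width = profile$window),
    strand = profile$strand,
    score = profile$values
  )
}

#' Genome-wide sliding-window free-energy scan
#'
#' Folds every complete window of every chromosome on the plus (reference)
#' strand — the geometry used for genome-wide landscapes: 300-nt windows
#' advancing in 150-nt steps. A chromosome of L nt yields
#' `floor((L - window) / step) + 1` windows; incomplete trailing windows are
#' dropped. Windows containing N are reported as missing (`NA`).
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @param params [fold_params()].
#' @param window,step Scan geometry (nt); `window >= step`.
#' @return A named list of [fe_profile()] objects, one per chromosome.
#' @export
scan_genome <- function(genome, params = fold_params(),
                        window = 300, step = 150) {
  g <- read_genome(genome)
  if (window < step) stop("`window` must be >= `step`")
  out <- lapply(names(g), function(chrom) {
    len <- Biostrings::width(g[chrom])
    if (len < window) {
      warning("chromosome ", chrom, " shorter than one window; empty profile")
      return(fe_profile(chrom, numeric(0), window, step))
    }
    nw <- (len - window) %/% step + 1L
    starts0 <- (seq_len(nw) - 1L) * step
    schr <- as.character(g[[chrom]])
    vals <- .dg_windows(.dna_int(schr), starts0, window, params,
                        seq_chr = schr)
    fe_profile(chrom, vals, window, step)
  })
  names(out) <- names(g)
  out
}

#' Non-template strand sequence of a gene region
#'
#' Extracts the sequence that matches the nascent RNA (the coding /
#' non-template strand), oriented 5'->3' in the direction of transcription,
#' over a transcription-oriented offset range relative to the TSS (negative
#' offsets are upstream). For minus-strand genes this is the reverse
#' complement of the corresponding reference span.
#'
#' @param gene A single-range `GRanges` gene model.
#' @param genome A `DNAStringSet` or FASTA path.
#' @param from_off,to_off Half-open oriented offset range `[from_off,
#'   to_off)` relative to the TSS (offset 0 = the TSS base).
#' @return A DNA character string of length `to_off - from_off`; spans
#'   reaching beyond the chromosome are clipped with a warning.
#' @export
non_template_sequence <- function(gene, genome, from_off, to_off) {
  g <- read_genome(genome)
  stopifnot(length(gene) == 1, from_off < to_off)
  chrom <- as.character(GenomicRanges::seqnames(gene))
  strand <- as.character(GenomicRanges::strand(gene))
  if (!chrom %in% names(g)) stop("chromosome not in genome: ", chrom)
  len <- Biostrings::width(g[chrom])
  tss <- .tss(gene)
  if (strand == "-") {
    gs <- tss - to_off + 1L
    ge <- tss - from_off
  } else {
    gs <- tss + from_off
    ge <- tss + to_off - 1L
  }
  if (gs < 1 || ge > len) {
    warning("requested span clipped to chromosome bounds")
    gs <- max(1L, gs)
    ge <- min(len, ge)
  }
  if (gs > ge) return("")
  s <- as.character(Biostrings::subseq(g[[chrom]], gs, ge))
  if (strand == "-") .revcomp(s) else s
}

#' High-resolution TSS-proximal free-energy scan
#'
#' Folds 30-nt windows advancing 1 nt at a time over the TSS +/- `flank`
#' region of one gene, on the non-template (default) or template strand,
#' assigning each window's dG to its middle (15th) nucleotide. The scanned
#' span is the closed offset interval `[-flank, +flank]` (2*flank + 1 nt),
#' giving `2*flank - 28` windows for the default 30/1 geometry with assigned
#' offsets running from `-(flank - 14)` to `+(flank - 15)` — e.g. 3972
#' windows spanning offsets -1986..+1985 for `flank = 2000`.
#'
#' @param gene A single-range `GRanges` gene model (should have passed
#'   [select_transcripts()]).
#' @param genome A `DNAStringSet` or FASTA path.
#' @param params [fold_params()].
#' @param flank Half-width of the scanned region (nt).
#' @param window,step Scan geometry; the 15th-nt assignment assumes the
#'   default 30-nt window.
#' @param strand `"non_template"` (free to fold during transcription) or
#'   `"template"`.
#' @return An object of class `tss_profile`: list with `gene_id`, `offsets`
#'   (assigned transcription-oriented offsets), `values` (dG, kcal/mol) and
#'   the scan geometry. Regions containing N are rejected (gene filters
#'   remove such genes).
#' @export
scan_tss_highres <- function(gene, genome, params = fold_params(),
                             flank = 2000, window = 30, step = 1,
                             strand = c("non_template", "template")) {
  strand <- match.arg(strand)
  seq <- non_template_sequence(gene, genome, -flank, flank + 1L)
  if (nchar(seq) != 2L * flank + 1L)
    stop("TSS +/- flank region extends beyond the chromosome")
  if (grepl("N", seq, fixed = TRUE))
    stop("TSS-proximal region contains undetermined sequence (N)")
  fold_seq <- if (strand == "template") .revcomp(seq) else seq
  vals <- dg_sliding(fold_seq, params, window = window, step = step)
  if (strand == "template") vals <- rev(vals)
  starts_off <- seq.int(-flank, flank - window + 1L, by = step)
  structure(
    list(
      gene_id = if (!is.null(gene$gene_id)) gene$gene_id else NA_character_,
      chrom = as.character(GenomicRanges::seqnames(gene)),
      gene_strand = as.character(GenomicRanges::strand(gene)),
      scan_strand = strand,
      window = as.integer(window), step = as.integer(step),
      offsets = starts_off + 14L,
      values = vals
    ),
    class = "tss_profile"
  )
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf(
    "tss_profile: %s (%s strand scan), %d windows, offsets %d..%d\n",
    x$gene_id, x$scan_strand, length(x$values),
    min(x$offsets), max(x$offsets)
  ))
  invisible(x)
}
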