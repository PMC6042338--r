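# Genome, coverage-track and interval I/O helpers.
#
# Intervals live in GRanges (1-based, closed) in memory; BED-family files on
# disk keep their native 0-based half-open convention via rtracklayer.
# Coverage tracks are kept as plain per-chromosome numeric vectors (optionally
# one set per strand): test- and simulation-scale genomes are a few Mb, where
# dense vectors are simpler and faster than run-length containers.

#' Read a genome from FASTA
#'
#' @param x A FASTA path or a [Biostrings::DNAStringSet] (returned as is,
#'   with names trimmed to the first whitespace-delimited token).
#' @return A `DNAStringSet`.
#' @export
read_genome <- function(x) {
  if (is(x, "DNAStringSet")) {
    names(x) <- sub("\\s.*$", "", names(x))
    return(x)
  }
  if (!is.character(x) || !file.exists(x)) stop("genome FASTA not found: ", x)
  g <- Biostrings::readDNAStringSet(x)
  if (length(g) == 0) stop("empty FASTA: ", x)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Chromosome sizes of a genome
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_sizes <- function(genome) {
  g <- read_genome(genome)
  setNames(Biostrings::width(g), names(g))
}

#' Construct a coverage track
#'
#' @param data For an unstranded track, a named list of per-chromosome
#'   numeric vectors (one value per base). For a stranded track, a list with
#'   elements `"+"` and `"-"`, each such a named list.
#' @param stranded Logical.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(data, stranded = FALSE) {
  if (stranded) {
    stopifnot(all(c("+", "-") %in% names(data)))
  } else {
    stopifnot(length(names(data)) == length(data))
  }
  structure(list(data = data, stranded = stranded), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  chroms <- if (x$stranded) names(x$data[["+"]]) else names(x$data)
  cat(sprintf("coverage_track: %s, %d chromosome(s): %s\n",
              if (x$stranded) "stranded" else "unstranded",
              length(chroms), paste(head(chroms, 4), collapse = ", ")))
  invisible(x)
}

.track_chroms <- function(track) {
  if (track$stranded) names(track$data[["+"]]) else names(track$data)
}

# per-base values over [start, end] (1-based closed); NA outside chromosome.
# strand NULL or "*" on a stranded track sums the two strands.
.cov_get <- function(track, chrom, start, end, strand = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  pick <- function(side) {
    v <- track$data[[side]][[chrom]]
    if (is.null(v)) rep(0, 0) else v
  }
  vec <- if (!track$stranded) {
    v <- track$data[[chrom]]
    if (is.null(v)) stop("chromosome not in track: ", chrom)
    v
  } else if (is.null(strand) || identical(strand, "*")) {
    vp <- pick("+"); vm <- pick("-")
    if (!length(vp) && !length(vm)) stop("chromosome not in track: ", chrom)
    if (!length(vp)) vm else if (!length(vm)) vp else vp + vm
  } else {
    v <- track$data[[as.character(strand)]][[chrom]]
    if (is.null(v)) stop("chromosome/strand not in track: ", chrom, strand)
    v
  }
  n <- length(vec)
  idx <- start:end
  out <- rep(NA_real_, length(idx))
  ok <- idx >= 1 & idx <= n
  out[ok] <- vec[idx[ok]]
  out
}

# total coverage under each range of a GRanges (clipped to the chromosome);
# stranded tracks are read on each range's own strand unless strand = "*".
.cov_sum <- function(track, gr, strand_aware = TRUE) {
  vapply(seq_along(gr), function(i) {
    chrom <- as.character(GenomicRanges::seqnames(gr)[i])
    st <- if (strand_aware) as.character(GenomicRanges::strand(gr)[i]) else "*"
    v <- .cov_get(track, chrom,
                  GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
                  strand = if (identical(st, "*")) NULL else st)
    sum(v, na.rm = TRUE)
  }, numeric(1))
}

.track_to_granges <- function(vecs, strand = "*") {
  grl <- lapply(names(vecs), function(chrom) {
    v <- vecs[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(starts[keep], ends[keep]),
                           strand = strand, score = r$values[keep])
  })
  do.call(c, grl)
}

#' Write a coverage track as bedGraph
#'
#' Stranded tracks are written as two files with `_plus` / `_minus` inserted
#' before the extension (the conventional layout for stranded bedGraph).
#'
#' @param track A [coverage_track()].
#' @param path Output path (used as a template for stranded tracks).
#' @return Invisibly, the path(s) written.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  if (!track$stranded) {
    gr <- .track_to_granges(track$data)
    rtracklayer::export(gr, path, format = "bedGraph")
    return(invisible(path))
  }
  stub <- sub("\\.[^.]+$", "", path)
  ext <- sub("^.*\\.", "", path)
  paths <- c(paste0(stub, "_plus.", ext), paste0(stub, "_minus.", ext))
  rtracklayer::export(.track_to_granges(track$data[["+"]]), paths[1],
                      format = "bedGraph")
  rtracklayer::export(.track_to_granges(track$data[["-"]]), paths[2],
                      format = "bedGraph")
  invisible(paths)
}

.granges_to_vecs <- function(gr, sizes) {
  vecs <- lapply(sizes, function(n) numeric(n))
  for (chrom in names(sizes)) {
    sub <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    if (!length(sub)) next
    v <- vecs[[chrom]]
    s <- pmax(1L, GenomicRanges::start(sub))
    e <- pmin(sizes[[chrom]], GenomicRanges::end(sub))
    sc <- sub$score
    for (i in seq_along(sub)) v[s[i]:e[i]] <- v[s[i]:e[i]] + sc[i]
    vecs[[chrom]] <- v
  }
  vecs
}

#' Read bedGraph coverage into a track
#'
#' @param path Path for an unstranded track, or a length-2 character vector
#'   `c(plus, minus)` for a stranded one.
#' @param sizes Named chromosome sizes (see [chrom_sizes()]).
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, sizes) {
  if (length(path) == 2) {
    dat <- list(
      "+" = .granges_to_vecs(rtracklayer::import(path[1], format = "bedGraph"), sizes),
      "-" = .granges_to_vecs(rtracklayer::import(path[2], format = "bedGraph"), sizes)
    )
    return(coverage_track(dat, stranded = TRUE))
  }
  coverage_track(
    .granges_to_vecs(rtracklayer::import(path, format = "bedGraph"), sizes))
}

#' Read narrowPeak intervals
#'
#' @param path A BED6+4 narrowPeak file.
#' @return A `GRanges` with `signalValue`, `pValue`, `qValue` and `peak`
#'   (summit offset) columns.
#' @export
read_narrowpeak <- function(path) {
  rtracklayer::import(path, format = "BED",
                      extraCols = c(signalValue = "numeric", pValue = "numeric",
                                    qValue = "numeric", peak = "integer"))
}

#' Write narrowPeak intervals
#'
#' rtracklayer imports but does not export the narrowPeak dialect, so the
#' BED6+4 columns are laid out directly.
#'
#' @param gr A `GRanges`, optionally with `signalValue`, `pValue`, `qValue`
#'   and `peak` metadata columns (defaults: 0, -1, -1, midpoint).
#' @param path Output path.
#' @export
write_narrowpeak <- function(gr, path) {
  n <- length(gr)
  mc <- GenomicRanges::mcols(gr)
  getcol <- function(nm, default) if (nm %in% names(mc)) mc[[nm]] else rep(default, n)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if ("name" %in% names(mc)) mc$name else paste0("peak_", seq_len(n)),
    score = getcol("score", 0),
    strand = as.character(GenomicRanges::strand(gr)),
    signalValue = getcol("signalValue", 0),
    pValue = getcol("pValue", -1),
    qValue = getcol("qValue", -1),
    peak = getcol("peak", floor((GenomicRanges::width(gr) - 1) / 2))
  )
  df$strand[df$strand == "*"] <- "."
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED
#'
#' @param path BED6 (or BED12; only the outer transcript span is used).
#' @return A `GRanges` with a `gene_id` column taken from the BED name.
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::mcols(gr)$gene_id <- gr$name
  gr
}

#' Write gene models as BED6
#'
#' @param genes `GRanges` with a `gene_id` column.
#' @param path Output path.
#' @export
write_genes_bed <- function(genes, path) {
  gr <- genes
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    name = genes$gene_id,
    score = rep(0, length(genes))
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# TSS / TTS positions (1-based) of stranded gene models
.tss <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::end(genes), GenomicRanges::start(genes))
}
.tts <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::start(genes), GenomicRanges::end(genes))
}

# oriented offset -> genomic position: pos = tss + off (+) or tss - off (-)
.oriented_pos <- function(tss, strand, off) {
  ifelse(strand == "-", tss - off, tss + off)
}

# genomic interval covering oriented offsets [lo, hi] around an anchor
.oriented_span <- function(anchor, strand, lo, hi) {
  s <- ifelse(strand == "-", anchor - hi, anchor + lo)
  e <- ifelse(strand == "-", anchor - lo, anchor + hi)
  cbind(start = s, end = e)
}
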