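# Synthetic genomes, annotations and signal tracks with a truth manifest.
#
# The generator emulates the statistical structure the pipeline assumes:
# a GC-controlled i.i.d. background genome; non-overlapping genes whose
# TSS +/- 2 knt regions never collide; for paused genes a pause position
# +75 nt downstream of the TSS, a stable GC-rich hairpin written on the
# non-template strand centered 30 nt upstream of the pause, Gaussian Pol II
# ChIP coverage over the pause, promoter-proximal GRO/NET coverage on the
# coding strand, and an mNET track carrying a tall single-nucleotide spike
# at the pause over a genome-wide discrete power-law noise floor
# (N_x = a * x^-b on coverage 3..100, completed below 3 with the same law).

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 1-Mb single-chromosome genome at 50% GC carrying 100
#' non-overlapping genes (60% paused, 15% without Pol II), pauses at
#' TSS + 75 nt, 12-bp-stem/6-nt-loop hairpins centered 30 nt upstream of
#' each pause, and mNET noise with the power-law parameters
#' a = 0.965, b = 2.443 over coverage 3..100.
#'
#' @param seed Integer seed controlling every random choice.
#' @param chrom_lengths Named (or auto-named) chromosome lengths (nt).
#' @param background_gc Background GC fraction.
#' @param n_genes Number of genes.
#' @param gene_length `c(min, max)` transcript length (nt).
#' @param paused_fraction,np2_fraction Fractions of PAU and NP2 genes
#'   (the remainder is NPA).
#' @param pause_offset Pause position downstream of the TSS (nt).
#' @param hairpin_stem,hairpin_loop Stem and loop lengths of the planted
#'   hairpin (nt).
#' @param hairpin_offset Offset of the hairpin center upstream of the pause
#'   (negative nt).
#' @param g4_fraction Fraction of paused genes additionally given a
#'   G-quadruplex motif upstream of the hairpin.
#' @param noise_a,noise_b,noise_range mNET noise power law `a * x^-b` and
#'   its coverage support.
#' @param noise_density Fraction of positions (per strand) carrying noise.
#' @param chip_height,chip_sd,chip_baseline Pol II ChIP Gaussian peak
#'   height, width (sd, nt) and uniform gene-body baseline.
#' @param npa_height Uniform Pol II coverage over non-paused gene bodies.
#' @param gro_height,net_height Promoter-proximal GRO/NET coverage heights.
#' @param mnet_spike,mnet_second_height,mnet_second_offset Heights of the
#'   planted first and second mNET spikes and their separation (nt).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chrS1 = 1000000L),
                       background_gc = 0.5,
                       n_genes = 100,
                       gene_length = c(2000, 4000),
                       paused_fraction = 0.6,
                       np2_fraction = 0.15,
                       pause_offset = 75,
                       hairpin_stem = 12,
                       hairpin_loop = 6,
                       hairpin_offset = -30,
                       g4_fraction = 0.2,
                       noise_a = 0.965,
                       noise_b = 2.443,
                       noise_range = c(3, 100),
                       noise_density = 0.02,
                       chip_height = 30,
                       chip_sd = 60,
                       chip_baseline = 1,
                       npa_height = 5,
                       gro_height = 20,
                       net_height = 10,
                       mnet_spike = 200,
                       mnet_second_height = 80,
                       mnet_second_offset = 3) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chrS", seq_along(chrom_lengths))
  stopifnot(all(chrom_lengths > 0), background_gc > 0, background_gc < 1,
            paused_fraction >= 0, paused_fraction <= 1,
            np2_fraction >= 0, paused_fraction + np2_fraction <= 1,
            gene_length[1] <= gene_length[2])
  structure(as.list(environment()), class = "sim_config")
}

.sample_dna <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a background genome
#'
#' I.i.d. bases at the configured GC fraction, with optional N-gap blocks.
#' Byte-identical under a fixed seed.
#'
#' @param config A [sim_config()].
#' @param gaps Optional `GRanges` of N-gap intervals to blank out.
#' @return A list with `genome` (`DNAStringSet`) and `gaps`.
#' @export
make_genome <- function(config, gaps = NULL) {
  set.seed(config$seed)
  chroms <- lapply(config$chrom_lengths, function(len) {
    paste(.sample_dna(len, config$background_gc), collapse = "")
  })
  chroms <- unlist(chroms)
  names(chroms) <- names(config$chrom_lengths)
  if (!is.null(gaps) && length(gaps)) {
    for (i in seq_along(gaps)) {
      chrom <- as.character(GenomicRanges::seqnames(gaps)[i])
      s <- GenomicRanges::start(gaps)[i]
      e <- GenomicRanges::end(gaps)[i]
      substr(chroms[[chrom]], s, e) <- strrep("N", e - s + 1L)
    }
  }
  g <- Biostrings::DNAStringSet(chroms)
  list(genome = g, gaps = if (is.null(gaps)) GenomicRanges::GRanges() else gaps)
}

# non-overlapping gene placement on slots with guard gaps wide enough that
# TSS +/- 2 knt regions never overlap
.place_genes <- function(config) {
  margin <- 2100L
  lens <- config$chrom_lengths
  n_per <- round(config$n_genes * as.numeric(lens) / sum(as.numeric(lens)))
  n_per[length(n_per)] <- config$n_genes - sum(n_per[-length(n_per)])
  out <- list()
  gi <- 0L
  for (ci in seq_along(lens)) {
    n <- n_per[ci]
    if (n <= 0) next
    slot <- (lens[[ci]]) %/% n
    if (slot < config$gene_length[2] + 2L * margin)
      stop("chromosome too short for ", n, " genes with non-overlapping TSS regions")
    for (k in seq_len(n)) {
      gi <- gi + 1L
      glen <- sample(seq(config$gene_length[1], config$gene_length[2]), 1)
      lo <- (k - 1L) * slot + margin
      room <- slot - glen - 2L * margin
      gstart <- lo + sample.int(max(room, 1L), 1)
      out[[gi]] <- data.frame(
        chrom = names(lens)[ci],
        start = gstart,
        end = gstart + glen - 1L,
        strand = sample(c("+", "-"), 1),
        gene_id = sprintf("gene%03d", gi)
      )
    }
  }
  df <- do.call(rbind, out)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         strand = df$strand, gene_id = df$gene_id)
}

#' Plant secondary structures for paused genes
#'
#' Writes, for each paused gene, a GC-only-stem hairpin (inverted repeat) on
#' the non-template strand centered `hairpin_offset` nt from the pause
#' position, and for a configured fraction of paused genes an additional
#' canonical G-quadruplex motif further upstream. Minus-strand genes receive
#' the reverse complement on the reference strand.
#'
#' @param genome `DNAStringSet` to modify.
#' @param manifest Truth manifest data frame (from [simulate_dataset()]'s
#'   internal construction) with pause positions and states.
#' @param genes `GRanges` gene models.
#' @param config A [sim_config()].
#' @return List with the modified `genome` and the updated `manifest`
#'   (hairpin coordinates filled in).
#' @export
plant_structures <- function(genome, manifest, genes, config) {
  strand <- as.character(GenomicRanges::strand(genes))
  stem <- config$hairpin_stem
  loop <- config$hairpin_loop
  hlen <- 2L * stem + loop
  half <- hlen %/% 2L
  g4seq <- "GGGTTAGGGTTAGGGTTAGGG"
  gchr <- setNames(as.character(genome), names(genome))
  for (i in seq_len(nrow(manifest))) {
    if (manifest$state[i] != "PAU") next
    stem_seq <- paste(sample(c("G", "C"), stem, replace = TRUE), collapse = "")
    hp <- paste0(stem_seq, strrep("T", loop), .revcomp(stem_seq))
    center_off <- config$pause_offset + config$hairpin_offset
    tssi <- manifest$tss[i]
    sti <- strand[i]
    span <- .oriented_span(tssi, sti, center_off - half,
                           center_off - half + hlen - 1L)
    ins <- if (sti == "-") .revcomp(hp) else hp
    chrom <- manifest$chrom[i]
    substr(gchr[[chrom]], span[, "start"], span[, "end"]) <- ins
    manifest$hairpin_start[i] <- span[, "start"]
    manifest$hairpin_end[i] <- span[, "end"]
    if (manifest$g4[i]) {
      g4span <- .oriented_span(tssi, sti, center_off - half - 80L,
                               center_off - half - 80L + nchar(g4seq) - 1L)
      insg4 <- if (sti == "-") .revcomp(g4seq) else g4seq
      substr(gchr[[chrom]], g4span[, "start"], g4span[, "end"]) <- insg4
    }
  }
  out_genome <- Biostrings::DNAStringSet(gchr)
  names(out_genome) <- names(genome)
  list(genome = out_genome, manifest = manifest)
}

.add_gaussian <- function(v, center, height, sdv) {
  lo <- max(1L, center - 4L * sdv)
  hi <- min(length(v), center + 4L * sdv)
  if (lo > hi) return(v)
  idx <- lo:hi
  v[idx] <- v[idx] + round(height * exp(-((idx - center)^2) / (2 * sdv^2)))
  v
}

.add_flat <- function(v, s, e, height) {
  s <- max(1L, s)
  e <- min(length(v), e)
  if (s > e) return(v)
  v[s:e] <- v[s:e] + height
  v
}

# discrete power-law noise values on 1..hi: proportional to a*x^-b on
# [lo, hi], with the mass below lo completed by the same x^-b shape
.sample_noise_values <- function(n, config) {
  lo <- config$noise_range[1]
  hi <- config$noise_range[2]
  x <- seq_len(hi)
  p <- config$noise_a * x^(-config$noise_b)
  main_mass <- sum(p[lo:hi])
  low <- seq_len(lo - 1)
  p[low] <- (1 - main_mass) * low^(-config$noise_b) / sum(low^(-config$noise_b))
  sample.int(hi, n, replace = TRUE, prob = p)
}

#' Simulate signal tracks and peak calls
#'
#' Emits the per-assay tracks implied by the manifest: Gaussian Pol II ChIP
#' coverage centered on each pause with peak calls, strand-specific
#' promoter-proximal GRO and NET coverage with GRO peak calls for paused
#' genes, uniform gene-body coverage for non-paused (Pol II-bound) genes,
#' nothing for NP2 genes, and a stranded mNET track with single-nucleotide
#' spikes at the pauses over sparse genome-wide power-law noise.
#'
#' @param genome `DNAStringSet` (only the sizes are used).
#' @param manifest Truth manifest with states and pause positions.
#' @param genes `GRanges` gene models.
#' @param config A [sim_config()].
#' @return List with `tracks` (list of `chip`, `gro`, `net`, `mnet`
#'   [coverage_track()]s), `chip_peaks` and `gro_peaks` (`GRanges`).
#' @export
simulate_tracks <- function(genome, manifest, genes, config) {
  sizes <- chrom_sizes(genome)
  zero <- lapply(sizes, function(n) numeric(n))
  chip <- zero
  gro <- list("+" = zero, "-" = zero)
  net <- list("+" = zero, "-" = zero)
  mnet <- list("+" = zero, "-" = zero)
  chip_peaks <- list()
  gro_peaks <- list()
  strand <- as.character(GenomicRanges::strand(genes))
  gstart <- GenomicRanges::start(genes)
  gend <- GenomicRanges::end(genes)
  for (i in seq_len(nrow(manifest))) {
    st <- manifest$state[i]
    if (st == "NP2") next
    chrom <- manifest$chrom[i]
    sti <- strand[i]
    if (st == "NPA") {
      chip[[chrom]] <- .add_flat(chip[[chrom]], gstart[i], gend[i],
                                 config$npa_height)
      gro[[sti]][[chrom]] <- .add_flat(gro[[sti]][[chrom]], gstart[i], gend[i],
                                       max(1, round(config$npa_height / 2)))
      chip_peaks[[length(chip_peaks) + 1L]] <- data.frame(
        chrom = chrom, start = gstart[i], end = gend[i], strand = "*",
        signalValue = config$npa_height,
        peak = (gend[i] - gstart[i]) %/% 2L)
      next
    }
    pause <- manifest$pause_pos[i]
    tssi <- manifest$tss[i]
    chip[[chrom]] <- .add_gaussian(chip[[chrom]], pause, config$chip_height,
                                   config$chip_sd)
    chip[[chrom]] <- .add_flat(chip[[chrom]], gstart[i], gend[i],
                               config$chip_baseline)
    gro_span <- .oriented_span(tssi, sti, -20L, config$pause_offset + 105L)
    gro[[sti]][[chrom]] <- .add_flat(gro[[sti]][[chrom]],
                                     gro_span[, "start"], gro_span[, "end"],
                                     config$gro_height)
    net_span <- .oriented_span(tssi, sti, 0L, config$pause_offset + 25L)
    net[[sti]][[chrom]] <- .add_flat(net[[sti]][[chrom]],
                                     net_span[, "start"], net_span[, "end"],
                                     config$net_height)
    mnet[[sti]][[chrom]][pause] <-
      mnet[[sti]][[chrom]][pause] + config$mnet_spike
    second <- .oriented_pos(pause, sti, config$mnet_second_offset)
    if (second >= 1 && second <= sizes[[chrom]]) {
      mnet[[sti]][[chrom]][second] <-
        mnet[[sti]][[chrom]][second] + config$mnet_second_height
    }
    chip_span <- c(pause - 150L, pause + 150L)
    chip_peaks[[length(chip_peaks) + 1L]] <- data.frame(
      chrom = chrom, start = max(1L, chip_span[1]),
      end = min(sizes[[chrom]], chip_span[2]), strand = "*",
      signalValue = config$chip_height, peak = pause - max(1L, chip_span[1]))
    gro_peaks[[length(gro_peaks) + 1L]] <- data.frame(
      chrom = chrom, start = gro_span[, "start"], end = gro_span[, "end"],
      strand = sti, signalValue = config$gro_height,
      peak = abs(pause - gro_span[, "start"]))
  }
  # sparse power-law mNET noise on both strands
  for (side in c("+", "-")) {
    for (chrom in names(sizes)) {
      n_noise <- rbinom(1, sizes[[chrom]], config$noise_density)
      if (n_noise == 0) next
      pos <- sample.int(sizes[[chrom]], n_noise)
      mnet[[side]][[chrom]][pos] <- mnet[[side]][[chrom]][pos] +
        .sample_noise_values(n_noise, config)
    }
  }
  peaks_gr <- function(lst) {
    if (!length(lst)) return(GenomicRanges::GRanges())
    df <- do.call(rbind, lst)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           strand = df$strand, signalValue = df$signalValue,
                           peak = df$peak)
  }
  list(
    tracks = list(
      chip = coverage_track(chip),
      gro = coverage_track(gro, stranded = TRUE),
      net = coverage_track(net, stranded = TRUE),
      mnet = coverage_track(mnet, stranded = TRUE)
    ),
    chip_peaks = peaks_gr(chip_peaks),
    gro_peaks = peaks_gr(gro_peaks)
  )
}

#' Simulate a complete data set with truth manifest
#'
#' Orchestrates [make_genome()], gene placement, [plant_structures()] and
#' [simulate_tracks()], optionally writing every piece to standard formats
#' (FASTA, BED, bedGraph, narrowPeak, TSV manifest).
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `genome`, `genes`, `manifest`, `tracks`, `chip_peaks`,
#'   `gro_peaks`, `sizes` and (when written) `files`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  gen <- make_genome(config)
  genes <- .place_genes(config)
  n <- length(genes)
  n_pau <- round(n * config$paused_fraction)
  n_np2 <- round(n * config$np2_fraction)
  states <- sample(c(rep("PAU", n_pau), rep("NP2", n_np2),
                     rep("NPA", n - n_pau - n_np2)))
  strand <- as.character(GenomicRanges::strand(genes))
  tss <- .tss(genes)
  manifest <- data.frame(
    gene_id = genes$gene_id,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    strand = strand,
    tss = tss,
    state = states,
    pause_pos = ifelse(states == "PAU",
                       .oriented_pos(tss, strand, config$pause_offset),
                       NA_integer_),
    hairpin_start = NA_integer_,
    hairpin_end = NA_integer_,
    g4 = states == "PAU" & runif(n) < config$g4_fraction,
    stringsAsFactors = FALSE
  )
  planted <- plant_structures(gen$genome, manifest, genes, config)
  sim <- simulate_tracks(planted$genome, planted$manifest, genes, config)
  out <- list(
    genome = planted$genome,
    genes = genes,
    manifest = planted$manifest,
    tracks = sim$tracks,
    chip_peaks = sim$chip_peaks,
    gro_peaks = sim$gro_peaks,
    sizes = chrom_sizes(planted$genome),
    config = config
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      genome = file.path(dir, "genome.fa"),
      genes = file.path(dir, "genes.bed"),
      manifest = file.path(dir, "truth_manifest.tsv"),
      chip = file.path(dir, "chip.bedgraph"),
      chip_peaks = file.path(dir, "chip_peaks.narrowPeak"),
      gro_peaks = file.path(dir, "gro_peaks.narrowPeak")
    )
    Biostrings::writeXStringSet(out$genome, files["genome"])
    write_genes_bed(out$genes, files["genes"])
    write_manifest(out$manifest, files["manifest"])
    write_bedgraph(out$tracks$chip, files["chip"])
    for (tr in c("gro", "net", "mnet")) {
      write_bedgraph(out$tracks[[tr]], file.path(dir, paste0(tr, ".bedgraph")))
    }
    write_narrowpeak(out$chip_peaks, files["chip_peaks"])
    write_narrowpeak(out$gro_peaks, files["gro_peaks"])
    out$files <- files
  }
  out
}

#' Write / read the truth manifest
#'
#' Plain-TSV round trip of the per-gene truth table (state, pause position,
#' hairpin interval, planted G4 flag).
#'
#' @param manifest Manifest data frame.
#' @param path TSV path.
#' @return `write_manifest` returns the path invisibly; `read_manifest`
#'   returns the data frame.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
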