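#' Minimum-free-energy fold of a single-stranded DNA sequence
#'
#' Computes the most stable secondary structure of a DNA single strand under
#' a nearest-neighbor thermodynamic model (Watson-Crick pairs only, no GU),
#' returning its free energy of formation relative to the unfolded strand.
#' If no structure has negative energy the unfolded state (dG = 0, all dots)
#' is returned. With `allow_g4 = TRUE` in `params`, one non-overlapping
#' G-quadruplex motif (scored by the simplified model of [g4_scan()]) may be
#' included when it lowers the total energy; G4 inclusion can therefore
#' never raise the reported dG.
#'
#' @param seq DNA string over ACGT, length 1 to 10000 nt. Windows containing
#'   N must be filtered by the caller.
#' @param params A [fold_params()] object.
#' @return An object of class `fold_result`: a list with `delta_g`
#'   (kcal/mol, <= 0), `structure` (dot-bracket string, `+` marking G4 tract
#'   positions when a motif is included), `seq_length`, `pairing` (1-based
#'   partner vector) and `g4` (the included motif row, or `NULL`).
#' @export
#' @examples
#' mfe_fold("GCGCTTTTGCGC")
#' mfe_fold(strrep("A", 30))  # no complementary pairs: dG = 0
mfe_fold <- function(seq, params = fold_params()) {
  seq <- .validate_dna(seq)
  n <- nchar(seq)
  if (n > 10000) stop("`seq` longer than 10000 nt")
  tab <- energy_tables(params)
  si <- .dna_int(seq)
  plain <- .fold_one_cpp(si, rep(FALSE, n), tab)
  best <- list(delta_g = plain$delta_g, pairing = plain$pairing, g4 = NULL)
  if (params$allow_g4) {
    motifs <- g4_scan(seq, params)
    for (k in seq_len(nrow(motifs))) {
      mask <- rep(FALSE, n)
      mask[(motifs$start[k] + 1L):motifs$end[k]] <- TRUE  # 0-based half-open
      res <- .fold_one_cpp(si, mask, tab)
      e <- res$delta_g + motifs$bonus_energy[k]
      if (e < best$delta_g) {
        best <- list(delta_g = e, pairing = res$pairing, g4 = motifs[k, ])
      }
    }
  }
  g4_pos <- if (!is.null(best$g4)) {
    .g4_tract_positions(seq, best$g4$start[1], best$g4$end[1])
  }
  structure(
    list(
      delta_g = best$delta_g,
      structure = dot_bracket(best$pairing, g4_pos),
      seq_length = n,
      pairing = best$pairing,
      g4 = best$g4
    ),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("fold_result: dG = %.3f kcal/mol over %d nt\n%s\n",
              x$delta_g, x$seq_length, x$structure))
  invisible(x)
}

#' Exhaustively enumerate admissible secondary structures
#'
#' Validation oracle for [mfe_fold()]: enumerates every non-crossing set of
#' Watson-Crick pairs respecting the minimum hairpin loop and (by default)
#' the no-lonely-pair rule, scoring each with [structure_energy()] — the same
#' energy function the dynamic program minimizes, reached by a completely
#' different route.
#'
#' @param seq DNA string, at most 18 nt (combinatorial explosion guard).
#' @param params A [fold_params()] object.
#' @return A data frame with columns `structure` (dot-bracket) and `energy`
#'   (kcal/mol), one row per admissible structure including the empty one.
#' @export
enumerate_structures_oracle <- function(seq, params = fold_params()) {
  seq <- .validate_dna(seq)
  n <- nchar(seq)
  if (n > 18) stop("oracle enumeration limited to sequences of <= 18 nt")
  si <- .dna_int(seq)
  minh <- params$min_hairpin_loop
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(integer(0)))
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1L, j)  # i unpaired
    if (i + minh + 1L <= j) {
      for (k in seq.int(i + minh + 1L, j)) {
        if (si[i] + si[k] == 3L) {
          left <- rec(i + 1L, k - 1L)
          right <- rec(k + 1L, j)
          for (a in left) for (bb in right) {
            out[[length(out) + 1L]] <- c(i, k, a, bb)
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  all_sets <- rec(1L, n)
  tab <- energy_tables(params)
  keep_lonely <- params$allow_lonely_pairs
  res_struct <- character(0)
  res_energy <- numeric(0)
  for (st in all_sets) {
    pairing <- rep(NA_integer_, n)
    if (length(st)) {
      io <- st[seq(1, length(st), by = 2)]
      jo <- st[seq(2, length(st), by = 2)]
      pairing[io] <- jo
      pairing[jo] <- io
      if (!keep_lonely) {
        lonely <- vapply(seq_along(io), function(k) {
          i <- io[k]; j <- jo[k]
          stack_in <- i + 1L <= n && !is.na(pairing[i + 1L]) && pairing[i + 1L] == j - 1L
          stack_out <- i - 1L >= 1L && !is.na(pairing[i - 1L]) && pairing[i - 1L] == j + 1L
          !(stack_in || stack_out)
        }, logical(1))
        if (any(lonely)) next
      }
    }
    res_struct <- c(res_struct, dot_bracket(pairing))
    res_energy <- c(res_energy,
                    structure_energy(seq, pairing, params, tables = tab))
  }
  data.frame(structure = res_struct, energy = res_energy,
             stringsAsFactors = FALSE)
}

.g4_tract_positions <- function(seq, start0, end0) {
  sub <- substr(seq, start0 + 1L, end0)
  g <- gregexpr("G{3,}", sub)[[1]]
  if (g[1] == -1) return(integer(0))
  unlist(lapply(seq_along(g), function(k) {
    (start0 + g[k]):(start0 + g[k] + attr(g, "match.length")[k] - 1L)
  }))
}

#' Scan a sequence for G-quadruplex-forming motifs
#'
#' Finds maximal matches of the canonical four-tract pattern: four runs of at
#' least three guanines separated by loops of 1-7 nt, total span at most
#' 45 nt. Each motif receives a stability bonus from a simplified model:
#' `-(tetrad_bonus * n_tetrads) + loop_penalty * total_loop_nt`, clamped at
#' zero so the bonus is never destabilizing to report.
#'
#' @param seq DNA string over ACGT.
#' @param params A [fold_params()] object (supplies the bonus parameters).
#' @return A data frame with columns `start`, `end` (0-based half-open
#'   sequence offsets), `n_tracts`, `n_tetrads`, `loop_nt` and
#'   `bonus_energy` (kcal/mol, <= 0). Zero rows when no motif matches.
#' @export
#' @examples
#' g4_scan("GGGTTAGGGTTAGGGTTAGGG")
g4_scan <- function(seq, params = fold_params()) {
  seq <- .validate_dna(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_tracts = integer(0), n_tetrads = integer(0),
                      loop_nt = integer(0), bonus_energy = numeric(0))
  g <- gregexpr("G{3,}", seq)[[1]]
  if (g[1] == -1) return(empty)
  run_start <- as.integer(g)
  run_len <- attr(g, "match.length")
  run_end <- run_start + run_len - 1L
  nruns <- length(run_start)
  out <- empty
  i <- 1L
  while (i <= nruns) {
    chain <- i
    while (chain[length(chain)] < nruns) {
      nxt <- chain[length(chain)] + 1L
      gap <- run_start[nxt] - run_end[chain[length(chain)]] - 1L
      if (gap >= 1L && gap <= 7L) chain <- c(chain, nxt) else break
    }
    if (length(chain) >= 4L) {
      # longest prefix with >= 4 tracts whose span stays within 45 nt
      m <- length(chain)
      while (m >= 4L && (run_end[chain[m]] - run_start[chain[1]] + 1L) > 45L)
        m <- m - 1L
      if (m >= 4L) {
        sel <- chain[1:m]
        span_start <- run_start[sel[1]]
        span_end <- run_end[sel[m]]
        tract_nt <- sum(run_len[sel])
        loop_nt <- (span_end - span_start + 1L) - tract_nt
        n_tetrads <- min(run_len[sel])
        bonus <- min(0, -params$g4_tetrad_bonus * n_tetrads +
                          params$g4_loop_penalty * loop_nt)
        out <- rbind(out, data.frame(
          start = span_start - 1L,          # 0-based half-open
          end = span_end,
          n_tracts = m,
          n_tetrads = n_tetrads,
          loop_nt = loop_nt,
          bonus_energy = bonus
        ))
        i <- sel[m] + 1L
        next
      }
    }
    i <- i + 1L
  }
  out
}

# Sliding-window dG over one integer-coded sequence; starts are 0-based.
# Windows touching an ambiguous base come back NA. When G4 scoring is on and
# the character sequence is available, windows overlapping a G4 motif are
# re-folded individually so the motif bonus can enter.
.dg_windows <- function(seq_int, starts0, window, params,
                        tables = energy_tables(params), seq_chr = NULL) {
  if (length(starts0) == 0) return(numeric(0))
  vals <- .fold_windows_cpp(seq_int, as.integer(starts0), as.integer(window),
                            tables)
  if (params$allow_g4 && !is.null(seq_chr)) {
    motifs <- g4_scan(seq_chr, params)
    if (nrow(motifs)) {
      # windows [s0+1, s0+window] (1-based) overlapping any motif
      hit <- rep(FALSE, length(starts0))
      for (k in seq_len(nrow(motifs))) {
        hit <- hit | (starts0 + window > motifs$start[k] &
                        starts0 < motifs$end[k])
      }
      for (i in which(hit & !is.na(vals))) {
        sub <- substr(seq_chr, starts0[i] + 1L, starts0[i] + window)
        vals[i] <- mfe_fold(sub, params)$delta_g
      }
    }
  }
  vals
}

#' Sliding-window free-energy scan of one sequence
#'
#' Folds every complete window of `seq` and returns the vector of minimum
#' free energies. The workhorse behind [scan_genome()] and
#' [scan_tss_highres()].
#'
#' @param seq DNA string (Ns allowed; windows containing N yield `NA`).
#' @param params A [fold_params()] object.
#' @param window Window width in nt.
#' @param step Step size in nt.
#' @return Numeric vector of dG values, one per complete window.
#' @export
dg_sliding <- function(seq, params = fold_params(), window = 30, step = 1) {
  seq <- .validate_dna(seq, allow_n = TRUE)
  n <- nchar(seq)
  if (n < window) return(numeric(0))
  starts0 <- seq.int(0L, n - window, by = step)
  .dg_windows(.dna_int(seq), starts0, window, params, seq_chr = seq)
}
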