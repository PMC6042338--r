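# Nearest-neighbor energy tables for single-stranded DNA folding.
#
# Stack free energies come from unified DNA nearest-neighbor dH/dS values
# (kcal/mol and cal/(mol K)); loop penalties are tabulated free energies at
# 37 C, linearly interpolated between published anchor sizes and treated as
# temperature-independent. Loops longer than 30 nt are extrapolated
# logarithmically (Jacobson-Stockmayer, 1.75*R*T*log(s/30)). The monovalent
# salt correction enters through the stack entropies
# (dS + 0.368 * ln[Na_eq] per stack).

.BASES <- c("A", "C", "G", "T")

.nn_dh <- local({
  m <- matrix(NA_real_, 4, 4, dimnames = list(.BASES, .BASES))
  m["A", "A"] <- -7.9;  m["T", "T"] <- -7.9
  m["A", "T"] <- -7.2
  m["T", "A"] <- -7.2
  m["C", "A"] <- -8.5;  m["T", "G"] <- -8.5
  m["G", "T"] <- -8.4;  m["A", "C"] <- -8.4
  m["C", "T"] <- -7.8;  m["A", "G"] <- -7.8
  m["G", "A"] <- -8.2;  m["T", "C"] <- -8.2
  m["C", "G"] <- -10.6
  m["G", "C"] <- -9.8
  m["G", "G"] <- -8.0;  m["C", "C"] <- -8.0
  m
})

.nn_ds <- local({
  m <- matrix(NA_real_, 4, 4, dimnames = list(.BASES, .BASES))
  m["A", "A"] <- -22.2; m["T", "T"] <- -22.2
  m["A", "T"] <- -20.4
  m["T", "A"] <- -21.3
  m["C", "A"] <- -22.7; m["T", "G"] <- -22.7
  m["G", "T"] <- -22.4; m["A", "C"] <- -22.4
  m["C", "T"] <- -21.0; m["A", "G"] <- -21.0
  m["G", "A"] <- -22.2; m["T", "C"] <- -22.2
  m["C", "G"] <- -27.2
  m["G", "C"] <- -24.4
  m["G", "G"] <- -19.9; m["C", "C"] <- -19.9
  m
})

# loop penalty anchors (size, dG37 in kcal/mol); interpolated to sizes 1..30
.hairpin_anchors <- data.frame(
  size = c(3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
  dg = c(3.5, 3.5, 3.3, 4.0, 4.2, 4.3, 4.5, 4.6, 5.0, 5.1, 5.3, 5.5, 5.7, 6.1, 6.3)
)
.bulge_anchors <- data.frame(
  size = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
  dg = c(4.0, 2.9, 3.1, 3.2, 3.3, 3.5, 3.7, 3.9, 4.1, 4.3, 4.5, 4.8, 5.0, 5.2, 5.3, 5.6, 5.9)
)
.internal_anchors <- data.frame(
  size = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 14, 16, 18, 20, 25, 30),
  dg = c(3.2, 3.2, 3.6, 4.0, 4.4, 4.6, 4.8, 4.9, 4.9, 5.2, 5.4, 5.6, 5.8, 5.9, 6.3, 6.6)
)

.GAS_CONSTANT <- 0.0019872  # kcal/(mol K)

.interp_loop <- function(anchors) {
  stats::approx(anchors$size, anchors$dg, xout = 1:30, rule = 2)$y
}

#' Evaluated nearest-neighbor energy tables
#'
#' Computes the stack and loop free-energy tables for a given set of folding
#' conditions. Mostly internal; exposed so the energy function backing both
#' [mfe_fold()] and the enumeration oracle can be inspected.
#'
#' @param params A [fold_params()] object.
#' @return A list with elements `stack` (4x4 matrix of stack dG, indexed by
#'   the two 5'->3' bases of the top strand), `hairpin`, `bulge`, `interior`
#'   (loop penalties for sizes 1..30), `extrap` (long-loop log coefficient),
#'   `ml_init`/`ml_branch` (affine multibranch loop costs), plus the
#'   structural constraint fields consumed by the dynamic program.
#' @export
energy_tables <- function(params = fold_params()) {
  stopifnot(inherits(params, "fold_params"))
  tk <- params$temperature + 273.15
  salt_ds <- 0.368 * log(params$na_eq)
  stack <- .nn_dh - tk * (.nn_ds + salt_ds) / 1000
  stack[is.na(stack)] <- Inf  # non-WC combinations never queried
  hairpin <- .interp_loop(.hairpin_anchors)
  if (params$min_hairpin_loop > 1)
    hairpin[seq_len(min(params$min_hairpin_loop - 1L, 30L))] <- Inf
  interior <- .interp_loop(.internal_anchors)
  interior[1] <- Inf  # an interior loop has >= 1 nt on each side
  list(
    stack = stack,
    hairpin = hairpin,
    bulge = .interp_loop(.bulge_anchors),
    interior = interior,
    extrap = 1.75 * .GAS_CONSTANT * tk,
    ml_init = 3.4,
    ml_branch = 0.4,
    min_hairpin = params$min_hairpin_loop,
    max_interior = params$max_interior_loop,
    no_lonely = !params$allow_lonely_pairs
  )
}

.loop_penalty <- function(tab, extrap, size) {
  if (size <= 0) return(Inf)
  if (size <= 30) return(tab[size])
  tab[30] + extrap * log(size / 30)
}

.dna_codes <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)

.dna_int <- function(seq) {
  x <- .dna_codes[strsplit(toupper(seq), "", fixed = TRUE)[[1]]]
  x[is.na(x)] <- 4L
  unname(x)
}

.validate_dna <- function(seq, allow_n = FALSE) {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq))
    stop("`seq` must be a single character string")
  seq <- toupper(seq)
  if (nchar(seq) == 0) stop("`seq` must be non-empty")
  ok <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(ok, seq))
    stop("`seq` contains characters outside ", if (allow_n) "ACGTN" else "ACGT")
  seq
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Free energy of a given secondary structure
#'
#' Scores one secondary structure (a set of Watson-Crick base pairs) with the
#' same nearest-neighbor energy function that the dynamic program minimizes:
#' stack terms between adjacent pairs, tabulated hairpin/bulge/internal loop
#' penalties, and an affine multibranch cost. Used as the shared scoring core
#' of the exhaustive [enumerate_structures_oracle()].
#'
#' @param seq DNA string over ACGT.
#' @param pairing Integer vector, one entry per base: the 1-based partner
#'   index, or `NA` for unpaired bases. Must be symmetric and non-crossing.
#' @param params A [fold_params()] object.
#' @param tables Precomputed [energy_tables()] (to avoid recomputation in
#'   tight loops).
#' @return The structure free energy in kcal/mol (0 for the empty structure).
#' @export
structure_energy <- function(seq, pairing,
                             params = fold_params(),
                             tables = energy_tables(params)) {
  seq <- .validate_dna(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  stopifnot(length(pairing) == n)
  e <- 0
  opens <- which(!is.na(pairing) & pairing > seq_len(n))
  for (i in opens) {
    j <- pairing[i]
    # immediate children of (i, j)
    kids_i <- integer(0)
    k <- i + 1L
    while (k < j) {
      if (!is.na(pairing[k]) && pairing[k] > k) {
        kids_i <- c(kids_i, k)
        k <- pairing[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    nk <- length(kids_i)
    if (nk == 0L) {
      e <- e + .loop_penalty(tables$hairpin, tables$extrap, j - i - 1L)
    } else if (nk == 1L) {
      p <- kids_i[1]
      q <- pairing[p]
      l1 <- p - i - 1L
      l2 <- j - q - 1L
      if (l1 == 0L && l2 == 0L) {
        e <- e + tables$stack[b[i], b[p]]
      } else if (l1 == 0L || l2 == 0L) {
        e <- e + .loop_penalty(tables$bulge, tables$extrap, l1 + l2)
      } else {
        e <- e + .loop_penalty(tables$interior, tables$extrap, l1 + l2)
      }
    } else {
      e <- e + tables$ml_init + tables$ml_branch * (nk + 1L)
    }
  }
  e
}

#' Convert a pairing vector to dot-bracket notation
#'
#' @param pairing Integer partner vector as in [structure_energy()].
#' @param g4_positions Optional integer positions marked `+` (G-quadruplex
#'   tracts).
#' @return A dot-bracket string.
#' @export
dot_bracket <- function(pairing, g4_positions = NULL) {
  out <- rep(".", length(pairing))
  out[!is.na(pairing) & pairing > seq_along(pairing)] <- "("
  out[!is.na(pairing) & pairing < seq_along(pairing)] <- ")"
  if (!is.null(g4_positions)) out[g4_positions] <- "+"
  paste(out, collapse = "")
}
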