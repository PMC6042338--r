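#' Folding parameters for single-stranded DNA
#'
#' Bundles the thermodynamic conditions and structural constraints used by
#' [mfe_fold()] and every scan built on it. The defaults reproduce the
#' conditions used for genome-wide scans: 1.0 M monovalent salt, no divalent
#' salt, 37 degrees C, GU and lonely pairs disallowed. Divalent cations are
#' folded into an equivalent monovalent concentration
#' (`Na_eq = monovalent + 3.795 * sqrt(divalent)`, concentrations in M).
#'
#' @param temperature Temperature in degrees Celsius, within \[0, 100\].
#' @param monovalent Monovalent cation concentration (M), >= 0.
#' @param divalent Divalent cation concentration (M), >= 0. The combined
#'   equivalent monovalent concentration must be positive.
#' @param allow_g4 Should [mfe_fold()] consider including one G-quadruplex
#'   motif (scored by the simplified tetrad/loop model of [g4_scan()])?
#' @param allow_lonely_pairs If `FALSE` (default) every helix must contain at
#'   least two stacked base pairs.
#' @param min_hairpin_loop Minimum number of unpaired bases in a hairpin
#'   loop; at least 3.
#' @param g4_tetrad_bonus Stability bonus (kcal/mol, positive number
#'   subtracted) per G-tetrad in the simplified G4 model.
#' @param g4_loop_penalty Destabilization (kcal/mol) per G4 loop nucleotide.
#' @param max_interior_loop Cap on the total size of interior/bulge loops
#'   searched by the dynamic program (standard speed/accuracy trade-off).
#'
#' @return An object of class `fold_params`.
#' @seealso [preset_in_vitro()] for the in vitro transcription condition
#'   preset (60 mM KCl, 7 mM MgCl2, 30 degrees C).
#' @export
#' @examples
#' fold_params()
#' fold_params(temperature = 30, monovalent = 0.06, divalent = 0.007)
fold_params <- function(temperature = 37,
                        monovalent = 1.0,
                        divalent = 0,
                        allow_g4 = FALSE,
                        allow_lonely_pairs = FALSE,
                        min_hairpin_loop = 3L,
                        g4_tetrad_bonus = 2.0,
                        g4_loop_penalty = 0.3,
                        max_interior_loop = 30L) {
  stopifnot(is.numeric(temperature), length(temperature) == 1)
  if (temperature < 0 || temperature > 100)
    stop("`temperature` must lie within [0, 100] degrees C")
  if (monovalent < 0 || divalent < 0)
    stop("salt concentrations must be non-negative")
  min_hairpin_loop <- as.integer(min_hairpin_loop)
  if (min_hairpin_loop < 3L)
    stop("`min_hairpin_loop` must be at least 3")
  na_eq <- monovalent + 3.795 * sqrt(divalent)
  if (na_eq <= 0)
    stop("equivalent monovalent salt must be positive")
  structure(
    list(
      temperature = temperature,
      monovalent = monovalent,
      divalent = divalent,
      na_eq = na_eq,
      allow_g4 = isTRUE(allow_g4),
      allow_lonely_pairs = isTRUE(allow_lonely_pairs),
      min_hairpin_loop = min_hairpin_loop,
      g4_tetrad_bonus = g4_tetrad_bonus,
      g4_loop_penalty = g4_loop_penalty,
      max_interior_loop = as.integer(max_interior_loop)
    ),
    class = "fold_params"
  )
}

#' @export
print.fold_params <- function(x, ...) {
  cat(sprintf(
    "fold_params: %.1f C, Na_eq %.3f M%s, min hairpin loop %d, lonely pairs %s\n",
    x$temperature, x$na_eq, if (x$allow_g4) ", G4 on" else "",
    x$min_hairpin_loop,
    if (x$allow_lonely_pairs) "allowed" else "disallowed"
  ))
  invisible(x)
}

#' In vitro transcription condition preset
#'
#' Folding parameters matching a HeLa nuclear-extract transcription buffer:
#' 60 mM KCl, 7 mM MgCl2, 30 degrees C.
#'
#' @param ... Overrides passed on to [fold_params()].
#' @return A `fold_params` object.
#' @export
preset_in_vitro <- function(...) {
  args <- list(temperature = 30, monovalent = 0.060, divalent = 0.007)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(fold_params, args)
}
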