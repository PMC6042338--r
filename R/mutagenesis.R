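#' Windows whose folding is affected by point mutations
#'
#' All start positions of sliding windows (30 nt by default) containing at
#' least one mutated position, clipped to complete windows — the window set
#' over which the cumulative free-energy difference is summed. An interior
#' mutation touches `window` windows; mutations within `window` nt of each
#' other share windows, so the union is smaller than the sum.
#'
#' @param seq_length Length of the region (nt).
#' @param positions 1-based mutated positions within the region.
#' @param window Window width (nt).
#' @return Sorted integer vector of 1-based window start positions.
#' @export
affected_windows <- function(seq_length, positions, window = 30) {
  stopifnot(all(positions >= 1), all(positions <= seq_length))
  if (seq_length < window) stop("region shorter than one window")
  starts <- unlist(lapply(positions, function(p) {
    seq.int(max(1L, p - window + 1L), min(p, seq_length - window + 1L))
  }))
  sort(unique(starts))
}

#' Cumulative free-energy difference of a mutant region
#'
#' Sums, over every window affected by the mutations, the difference in
#' minimum free energy between the mutant and the reference sequence
#' (mutant minus reference, so negative values mean the mutant folds more
#' stably). Both sequences are non-template strand, folded under the
#' supplied conditions (in vitro transcription preset by default).
#'
#' @param ref_seq,mut_seq Equal-length DNA strings differing only at the
#'   mutated positions.
#' @param params [fold_params()]; defaults to [preset_in_vitro()].
#' @param window Window width (nt).
#' @param windows Optional explicit window starts; defaults to
#'   [affected_windows()] of the observed differences.
#' @return The cumulative delta-delta-G in kcal/mol (0 when the sequences
#'   are identical).
#' @export
cumulative_ddg <- function(ref_seq, mut_seq, params = preset_in_vitro(),
                           window = 30, windows = NULL) {
  ref_seq <- .validate_dna(ref_seq)
  mut_seq <- .validate_dna(mut_seq)
  if (nchar(ref_seq) != nchar(mut_seq))
    stop("reference and mutant sequences must have equal length")
  rb <- strsplit(ref_seq, "")[[1]]
  mb <- strsplit(mut_seq, "")[[1]]
  diffs <- which(rb != mb)
  if (!length(diffs)) return(0)
  if (is.null(windows))
    windows <- affected_windows(nchar(ref_seq), diffs, window)
  tab <- energy_tables(params)
  starts0 <- as.integer(windows) - 1L
  dg_ref <- .dg_windows(.dna_int(ref_seq), starts0, window, params,
                        tables = tab, seq_chr = ref_seq)
  dg_mut <- .dg_windows(.dna_int(mut_seq), starts0, window, params,
                        tables = tab, seq_chr = mut_seq)
  sum(dg_mut - dg_ref)
}

#' Robust (Huber) regression of pausing on structure stability
#'
#' Fits pausing fraction against cumulative delta-delta-G by iteratively
#' reweighted least squares with Huber weights and MAD scale (via
#' [MASS::rlm()]); points whose final weight drops below 0.5 are flagged as
#' outliers. With no large residuals all weights are 1 and the fit equals
#' ordinary least squares.
#'
#' @param x Cumulative delta-delta-G per variant (kcal/mol).
#' @param y Measured paused fraction per variant, in \[0, 1\].
#' @param k Huber tuning constant (in units of the robust scale).
#' @param max_iter IRLS iteration cap; non-convergence is flagged and the
#'   last iterate returned.
#' @return List with `slope`, `intercept`, `weights`, `outliers` (logical),
#'   `converged` and the underlying `rlm` fit.
#' @export
robust_fit <- function(x, y, k = 1.345, max_iter = 50) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 variants")
  ols <- lm(y ~ x)
  if (max(abs(resid(ols))) < 1e-10 * max(1, max(abs(y)))) {
    # exactly collinear data: the robust scale degenerates to zero, and the
    # IRLS fixed point is OLS with unit weights
    return(list(slope = unname(coef(ols)[2]),
                intercept = unname(coef(ols)[1]),
                weights = rep(1, length(x)),
                outliers = rep(FALSE, length(x)),
                converged = TRUE,
                fit = ols))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.huber, k = k, maxit = max_iter)
  if (!fit$converged) warning("Huber IRLS did not converge; returning last iterate")
  w <- unname(fit$w)
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    weights = w,
    outliers = w < 0.5,
    converged = fit$converged,
    fit = fit
  )
}

#' Analyze a mutant panel
#'
#' Computes the cumulative delta-delta-G of each variant against the wild
#' type and regresses the measured paused fractions on it with
#' [robust_fit()].
#'
#' @param wt_seq Wild-type non-template sequence.
#' @param variants Data frame with `variant_id`, `offset` (1-based position
#'   in `wt_seq`; several rows per variant allowed), `ref`, `alt`, and one
#'   `paused_fraction` per variant.
#' @param params [fold_params()]; in vitro preset by default.
#' @param window Window width (nt).
#' @return List with `records` (per-variant data frame incl.
#'   `cumulative_ddg` and `outlier_flag`) and `fit` (the [robust_fit()]
#'   result).
#' @export
mutant_panel <- function(wt_seq, variants, params = preset_in_vitro(),
                         window = 30) {
  wt_seq <- .validate_dna(wt_seq)
  need <- c("variant_id", "offset", "ref", "alt", "paused_fraction")
  stopifnot(all(need %in% names(variants)))
  ids <- unique(variants$variant_id)
  wb <- strsplit(wt_seq, "")[[1]]
  ddg <- numeric(length(ids))
  pf <- numeric(length(ids))
  for (i in seq_along(ids)) {
    rows <- variants[variants$variant_id == ids[i], ]
    mb <- wb
    for (r in seq_len(nrow(rows))) {
      p <- rows$offset[r]
      if (wb[p] != toupper(rows$ref[r]))
        stop("variant ", ids[i], ": reference base mismatch at offset ", p)
      mb[p] <- toupper(rows$alt[r])
    }
    ddg[i] <- cumulative_ddg(wt_seq, paste(mb, collapse = ""),
                             params = params, window = window)
    pf[i] <- rows$paused_fraction[1]
  }
  fit <- robust_fit(ddg, pf)
  records <- data.frame(
    variant_id = ids,
    cumulative_ddg = ddg,
    paused_fraction = pf,
    weight = fit$weights,
    outlier_flag = fit$outliers
  )
  list(records = records, fit = fit)
}
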