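#' Fit a qPCR calibration (standard) curve
#'
#' Least-squares fit of threshold cycle against log10 template quantity
#' from a dilution series (typically 10-fold serial dilutions), as used by
#' calibration-curve ("standard curve") absolute quantification.
#'
#' @param quantity Known template quantities (> 0), at least 3 distinct
#'   values.
#' @param ct Measured threshold cycles, same length.
#' @return Object of class `standard_curve`: list with `slope` (Ct per
#'   log10 quantity, negative for a working assay), `intercept` (Ct at
#'   quantity 1), `r_squared`, `amplification_efficiency`
#'   (`10^(-1/slope) - 1`; 1 means perfect doubling), and `quantity_range`.
#'   A non-negative slope is kept but flagged via the `flag` field.
#' @export
#' @examples
#' q <- 10^(0:4)
#' fit_standard_curve(q, -3.3219 * log10(q) + 25)
fit_standard_curve <- function(quantity, ct) {
  if (length(quantity) != length(ct)) {
    stop("quantity and ct must have the same length", call. = FALSE)
  }
  if (any(!is.finite(quantity)) || any(quantity <= 0)) {
    stop("all standard quantities must be finite and > 0", call. = FALSE)
  }
  if (length(unique(quantity)) < 3L) {
    stop("at least 3 standard points with distinct quantities are required",
         call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10(quantity))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  r_squared <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(
    slope = slope,
    intercept = intercept,
    r_squared = r_squared,
    amplification_efficiency = 10^(-1 / slope) - 1,
    quantity_range = range(quantity),
    flag = if (slope >= 0) "nonnegative_slope" else NA_character_
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve: Ct = %.4f * log10(q) + %.4f  (R2 = %.4f, eff = %.3f)\n",
    x$slope, x$intercept, x$r_squared, x$amplification_efficiency))
  invisible(x)
}

#' Quantify template from a Ct value
#'
#' Inverts a calibration curve: `quantity = 10^((ct - intercept)/slope)`.
#' Extrapolation outside the standard range is permitted; the result
#' carries an `extrapolated` attribute when it occurs.
#'
#' @param ct Threshold cycle(s).
#' @param curve A [fit_standard_curve()] result.
#' @return Numeric quantity (vectorized over `ct`).
#' @export
quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  q <- 10^((ct - curve$intercept) / curve$slope)
  outside <- q < curve$quantity_range[1] | q > curve$quantity_range[2]
  if (any(outside)) attr(q, "extrapolated") <- which(outside)
  q
}

#' ACT1-normalized fold-difference between two samples
#'
#' The fold-difference `D` underlying every estimator in the pipeline:
#' the quantity of a target amplicon in a test sample over that in a
#' reference sample, each first normalized to the ACT1 amplicon of its own
#' sample.
#'
#' @param test_q,ref_q Target-amplicon quantities in test and reference
#'   samples.
#' @param test_act1_q,ref_act1_q Matching ACT1 quantities.
#' @return `D = (test_q / test_act1_q) / (ref_q / ref_act1_q)`.
#' @export
fold_difference <- function(test_q, ref_q, test_act1_q, ref_act1_q) {
  qs <- c(test_q, ref_q, test_act1_q, ref_act1_q)
  if (any(!is.finite(qs)) || any(qs <= 0)) {
    stop("all quantities must be finite and > 0", call. = FALSE)
  }
  (test_q / test_act1_q) / (ref_q / ref_act1_q)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Estimate SphI digestion efficiency from a no-DSB control
#'
#' With no break there is no ssDNA, so the digested/mock fold-difference
#' of a no-DSB (glucose) control directly measures the fraction of dsDNA
#' amplicons surviving digestion: `e = 1 - D`.
#'
#' @param d_no_dsb Fold-difference (digested vs mock) in the no-DSB
#'   control, `>= 0`.
#' @return List with `e` (clamped to `[0, 1]`), `raw` (unclamped), and
#'   logical `out_of_range`.
#' @export
estimate_digestion_efficiency <- function(d_no_dsb) {
  if (!is.numeric(d_no_dsb) || any(d_no_dsb < 0)) {
    stop("d_no_dsb must be >= 0", call. = FALSE)
  }
  raw <- 1 - d_no_dsb
  list(e = clamp01(raw), raw = raw, out_of_range = raw < 0 | raw > 1)
}

#' Estimate DSB formation frequency from a cut-spanning amplicon
#'
#' A break destroys the template of an amplicon spanning the cleavage
#' site, so on undigested samples the test/control fold-difference of that
#' amplicon gives `f = 1 - D`.
#'
#' @param d_cut_amplicon Fold-difference (test vs no-DSB control,
#'   undigested) at the cleavage-spanning amplicon, `>= 0`.
#' @return List with `f` (clamped to `[0, 1]`), `raw`, and `out_of_range`.
#' @export
estimate_dsb_frequency <- function(d_cut_amplicon) {
  if (!is.numeric(d_cut_amplicon) || any(d_cut_amplicon < 0)) {
    stop("d_cut_amplicon must be >= 0", call. = FALSE)
  }
  raw <- 1 - d_cut_amplicon
  list(f = clamp01(raw), raw = raw, out_of_range = raw < 0 | raw > 1)
}

#' Corrected resection-efficiency estimator
#'
#' Estimates the fraction `r` of DSB-bearing molecules whose resection
#' tract has passed an SphI site, from the digested/mock fold-difference
#' `D`, the digestion efficiency `e`, and the DSB formation frequency `f`:
#'
#' \deqn{r = \frac{2 (D - 1 + e)}{f (D - 1 + 2e)}}
#'
#' This is the digestion-efficiency-corrected form of the classical
#' ssDNA-qPCR estimator; at `e = 1` it reduces to the original
#' `2D / (f (D + 1))`. It is the exact inverse of
#' [expected_fold_difference()].
#'
#' @param D Fold-difference, digested over mock.
#' @param e Digestion efficiency in `(0, 1]`.
#' @param f DSB formation frequency in `(0, 1]`.
#' @param tol Degenerate-denominator guard: `|D - 1 + 2e|` below this
#'   raises an error instead of returning an unbounded estimate.
#' @return List with `r` (clamped to `[0, 1]`), `raw` (unclamped, the
#'   value used by downstream normalizations), and `out_of_range`.
#' @export
#' @examples
#' D <- expected_fold_difference(f = 0.5, r = 0.6, e = 0.98)
#' estimate_resection(D, e = 0.98, f = 0.5)$raw  # 0.6
estimate_resection <- function(D, e, f, tol = 1e-9) {
  if (!is.numeric(f) || any(f <= 0)) {
    stop("f must be > 0 (no DSBs means resection is undefined)",
         call. = FALSE)
  }
  if (!is.numeric(e) || any(e <= 0)) stop("e must be > 0", call. = FALSE)
  denom <- D - 1 + 2 * e
  if (any(abs(denom) < tol)) {
    stop("degenerate denominator: |D - 1 + 2e| below tolerance",
         call. = FALSE)
  }
  raw <- 2 * (D - 1 + e) / (f * denom)
  list(r = clamp01(raw), raw = raw, out_of_range = raw < 0 | raw > 1)
}

#' Within-sample normalization of resection efficiency
#'
#' Divides the resection efficiency at a site by that at the most
#' DSB-proximal site (SphI-1) of the same sample, which no roadblock can
#' shield, making samples with different overall resection comparable.
#'
#' @param r_site Raw resection efficiency at the site of interest.
#' @param r_sphi1 Raw resection efficiency at SphI-1 in the same sample
#'   (> 0).
#' @return `r_site / r_sphi1`.
#' @export
normalize_within_sample <- function(r_site, r_sphi1) {
  if (any(!is.finite(r_sphi1)) || any(r_sphi1 <= 0)) {
    stop("SphI-1 resection efficiency must be > 0 for normalization",
         call. = FALSE)
  }
  r_site / r_sphi1
}

#' Reference-strain normalization of resection efficiency
#'
#' Divides the within-sample-normalized resection efficiency at a site by
#' that at the same site in the DSB reference strain (roadblock targeted
#' to an unrelated locus), removing the distance dependence of natural
#' resection.
#'
#' @param norm_test Within-sample-normalized value in the test strain.
#' @param norm_ref Matching value in the reference strain (> 0).
#' @return `norm_test / norm_ref`.
#' @export
normalize_to_reference <- function(norm_test, norm_ref) {
  if (any(!is.finite(norm_ref)) || any(norm_ref <= 0)) {
    stop("reference normalized resection must be > 0", call. = FALSE)
  }
  norm_test / norm_ref
}

#' Blocking efficiency from doubly normalized resection
#'
#' The fraction of resection events halted by the roadblock: one minus the
#' doubly normalized resection efficiency distal to it.
#'
#' @param normalized_r Doubly normalized resection efficiency.
#' @return List with `b` (clamped to `[0, 1]`) and `raw` (unclamped).
#' @export
blocking_efficiency <- function(normalized_r) {
  if (any(!is.finite(normalized_r))) {
    stop("normalized_r must be finite", call. = FALSE)
  }
  raw <- 1 - normalized_r
  list(b = clamp01(raw), raw = raw)
}

#' Combine blocking efficiencies under independence
#'
#' If each roadblock site halts an arriving resection machine
#' independently with probability `b_i`, the combined blocking efficiency
#' of targeting all sites simultaneously is `1 - prod(1 - b_i)`. With the
#' single-site efficiencies 0.53 and 0.47 this predicts 75% (at
#' integer-percent rounding) for dual targeting.
#'
#' @param b_list Numeric vector of per-site blocking efficiencies in
#'   `[0, 1]`.
#' @return Combined blocking efficiency.
#' @export
combine_independent_blocks <- function(b_list) {
  if (length(b_list) < 1L || any(!is.finite(b_list)) ||
      any(b_list < 0 | b_list > 1)) {
    stop("all blocking efficiencies must be in [0, 1]", call. = FALSE)
  }
  1 - prod(1 - b_list)
}
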