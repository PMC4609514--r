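# The three-step TBP-binding affinity model.
#
# For a 26-bp window the predicted affinity is
#
#   -ln KD = c0 - stoich * (ln K_SLIDE + ln K_STOP + ln K_BEND)
#
# where
#   -ln K_SLIDE = mean over all 24 placements (12 offsets x 2 orientations)
#                 of a 15-bp site of
#                 slide_ta * [TA count, 3'-half]
#                 + slide_mgw * [mean minor-groove width, central steps]
#                 + slide_const
#   -ln K_STOP  = maximal PWM score over the same 24 placements
#   -ln K_BEND  = mean over both strands of the best-placed site of
#                 bend_wr * [WR count, flank steps]
#                 + bend_tv * [TV count, core steps]
#                 + bend_const
#
# Each ln K falls when the window looks more like a canonical TATA box, so
# the predicted affinity rises. A promoter is scanned at window centers
# -70..-20 and the maximum -ln KD is reported with an uncertainty delta,
# the spread of -ln KD over all 78 single-base substitutions of the best
# window.

.SCAN_CENTERS <- -70L:-20L

# Evaluate every per-placement quantity of one 26-bp window in vectorized
# form. Placement value vectors are ordered plus-strand offsets 0..11 then
# minus-strand offsets 0..11; the best-placement tie-break is offset-major
# with plus strand before minus (matching .best_placement_codes).
.window_kernel <- function(codes, params) {
  weights <- params$pwm$weights
  co <- params$coefficients
  rg <- params$regions
  width <- params$pwm$width
  idx <- params$.site_idx                      # width x n_offsets
  n_plc <- 2L * ncol(idx)
  rc <- .revcomp_codes(codes)
  sites <- cbind(matrix(codes[idx], width), matrix(rc[idx], width))

  scores <- colSums(matrix(
    weights[cbind(as.vector(sites), rep.int(seq_len(width), n_plc))], width))

  r <- rg$three_prime_half
  ta <- colSums(sites[r, , drop = FALSE] == 4L &
                sites[r + 1L, , drop = FALSE] == 1L)
  sc <- rg$slide_center
  mg <- colSums(matrix(
    params$.mgw_mat[cbind(as.vector(sites[sc, , drop = FALSE]),
                          as.vector(sites[sc + 1L, , drop = FALSE]))],
    length(sc))) / length(sc)
  slide_vals <- co$slide_ta * ta + co$slide_mgw * mg + co$slide_const
  ln_k_slide <- -(sum(slide_vals) / n_plc)

  half <- n_plc %/% 2L
  ord <- as.vector(rbind(seq_len(half), half + seq_len(half)))
  k <- ord[which.max(scores[ord])]
  strand <- if (k <= half) "+" else "-"
  offset <- (k - 1L) %% half
  site <- sites[, k]
  ln_k_stop <- -scores[k]

  ln_k_bend <- -((.bend_site_value(site, params) +
                  .bend_site_value(.revcomp_codes(site), params)) / 2)

  minus_ln_kd <- co$c0 - co$stoich * (ln_k_slide + ln_k_stop + ln_k_bend)
  list(strand = strand, offset = offset, site_codes = site,
       ln_k_slide = ln_k_slide, ln_k_stop = ln_k_stop,
       ln_k_bend = ln_k_bend, minus_ln_kd = minus_ln_kd)
}

.bend_site_value <- function(site, params) {
  co <- params$coefficients
  rg <- params$regions
  wr <- sum(params$.wr_mat[cbind(site[rg$bend_flank],
                                 site[rg$bend_flank + 1L])])
  tv <- sum(params$.tv_mat[cbind(site[rg$bend_center],
                                 site[rg$bend_center + 1L])])
  co$bend_wr * wr + co$bend_tv * tv + co$bend_const
}

#' Sliding term of the three-step model
#'
#' \eqn{\ln K_{SLIDE}} for a 26-bp window: the negated mean, over all 12
#' offsets and both orientations of the 15-bp site, of the sliding
#' regression (TA count in the 3'-half, mean minor-groove width over the
#' central steps, intercept).
#'
#' @param window a 26-character DNA string
#' @param params a `tbp_parameters` object
#' @return `ln_k_slide` (ln units)
#' @export
slide_term <- function(window, params = load_default_parameters()) {
  codes <- .encode_dna(.check_window26(window))
  .window_kernel(codes, params)$ln_k_slide
}

#' Bending term of the three-step model
#'
#' \eqn{\ln K_{BEND}} for a 26-bp window: the bending regression (WR count
#' over the flank steps, TV count over the TATA-core steps, intercept)
#' evaluated on the best PWM placement and on its reverse complement,
#' averaged over the two strands and negated.
#'
#' @inheritParams slide_term
#' @return `ln_k_bend` (ln units)
#' @export
bend_term <- function(window, params = load_default_parameters()) {
  codes <- .encode_dna(.check_window26(window))
  .window_kernel(codes, params)$ln_k_bend
}

#' Predicted TBP affinity of one 26-bp window
#'
#' Combines the sliding, stopping and bending terms into
#' \eqn{-\ln K_D = c_0 - stoich\,(\ln K_{SLIDE} + \ln K_{STOP} + \ln K_{BEND})}.
#'
#' @inheritParams slide_term
#' @param center optional TSS-relative center recorded in the result
#' @return an object of class `window_eval` with elements `center`,
#'   `strand` (strand of the best PWM placement), `offset`, `ln_k_slide`,
#'   `ln_k_stop`, `ln_k_bend` and `minus_ln_kd`
#' @export
window_affinity <- function(window, params = load_default_parameters(),
                            center = NA_integer_) {
  codes <- .encode_dna(.check_window26(window))
  ev <- .window_kernel(codes, params)
  structure(list(center = as.integer(center), strand = ev$strand,
                 offset = ev$offset,
                 ln_k_slide = ev$ln_k_slide, ln_k_stop = ev$ln_k_stop,
                 ln_k_bend = ev$ln_k_bend, minus_ln_kd = ev$minus_ln_kd),
            class = "window_eval")
}

#' @export
print.window_eval <- function(x, ...) {
  cat(sprintf(
    "window_eval center=%s strand=%s -ln(KD)=%.4f (slide=%.4f stop=%.4f bend=%.4f)\n",
    ifelse(is.na(x$center), "?", x$center), x$strand, x$minus_ln_kd,
    x$ln_k_slide, x$ln_k_stop, x$ln_k_bend))
  invisible(x)
}

#' Scan a promoter and report its best TBP-affinity estimate
#'
#' Evaluates [window_affinity()] at every window center \eqn{-70..-20} (51
#' windows; both strands are handled inside each window term) and returns
#' the maximum \eqn{-\ln K_D} together with the uncertainty
#' [delta_estimate()] at the winning center. Ties between centers are
#' broken toward the most upstream center.
#'
#' @param seq a `promoter_seq` (or DNA text acceptable to
#'   [promoter_sequence()])
#' @param params a `tbp_parameters` object
#' @return an object of class `affinity_estimate` with elements
#'   `minus_ln_kd`, `delta`, `kd_molar` (\eqn{e^{\ln K_D}}, mol/L) and
#'   `best` (the winning `window_eval`)
#' @examples
#' p <- load_default_parameters()
#' prom <- generate_promoter(fixture_spec(seed = 7, embedded_motif = "TATAAAAG",
#'                                        motif_position = -31))
#' scan_promoter(prom, p)
#' @export
scan_promoter <- function(seq, params = load_default_parameters()) {
  seq <- promoter_sequence(seq)
  n <- promoter_length(seq)
  codes_all <- .encode_dna(seq$bases)
  best <- NULL
  best_center <- NA_integer_
  for (center in .SCAN_CENTERS) {
    lo_idx <- n + (center - 13L) + 1L
    ev <- .window_kernel(codes_all[lo_idx:(lo_idx + 25L)], params)
    if (is.null(best) || ev$minus_ln_kd > best$minus_ln_kd) {
      best <- ev
      best_center <- center
    }
  }
  delta <- delta_estimate(seq, best_center, params)
  structure(
    list(minus_ln_kd = best$minus_ln_kd, delta = delta,
         kd_molar = exp(-best$minus_ln_kd),
         best = structure(list(center = best_center, strand = best$strand,
                               offset = best$offset,
                               ln_k_slide = best$ln_k_slide,
                               ln_k_stop = best$ln_k_stop,
                               ln_k_bend = best$ln_k_bend,
                               minus_ln_kd = best$minus_ln_kd),
                          class = "window_eval"),
         label = seq$label),
    class = "affinity_estimate")
}

#' @export
print.affinity_estimate <- function(x, ...) {
  cat(sprintf(
    "affinity_estimate%s: -ln(KD) = %.4f +/- %.4f (KD = %.3g M), best window center %d (%s)\n",
    if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
    x$minus_ln_kd, x$delta, x$kd_molar, x$best$center, x$best$strand))
  invisible(x)
}

#' Perturbation uncertainty of a window's affinity estimate
#'
#' Builds all 78 single-base variants (3 alternative bases x 26 positions)
#' of the 26-bp window centered at `center`, evaluates
#' [window_affinity()] for each, and returns the spread of the 78
#' \eqn{-\ln K_D} values. The estimator is set by
#' `params$options$delta_method`: `"population"` (default; SD around the
#' variants' own mean, divisor 78), `"sample"` (divisor 77) or
#' `"around_base"` (RMS deviation from the unperturbed window's value,
#' divisor 78).
#'
#' @inheritParams scan_promoter
#' @param center TSS-relative window center
#' @return `delta` (ln units, nonnegative)
#' @export
delta_estimate <- function(seq, center, params = load_default_parameters()) {
  seq <- promoter_sequence(seq)
  codes <- .encode_dna(window_at(seq, center))
  vals <- .delta_values(codes, params)
  method <- params$options$delta_method
  if (method == "around_base") {
    base_val <- .window_kernel(codes, params)$minus_ln_kd
    sqrt(sum((vals - base_val)^2) / length(vals))
  } else {
    m <- sum(vals) / length(vals)
    div <- if (method == "sample") length(vals) - 1L else length(vals)
    sqrt(sum((vals - m)^2) / div)
  }
}

# -ln KD of every single-base variant of the window, ordered by position
# (5' to 3') and, within a position, by code of the substituted base
.delta_values <- function(codes, params) {
  n <- length(codes)
  vals <- numeric(3L * n)
  k <- 0L
  for (pos in seq_len(n)) {
    orig <- codes[pos]
    for (b in 1:4) {
      if (b == orig) next
      codes[pos] <- b
      k <- k + 1L
      vals[k] <- .window_kernel(codes, params)$minus_ln_kd
    }
    codes[pos] <- orig
  }
  vals
}
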