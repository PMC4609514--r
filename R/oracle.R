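# Independent brute-force re-evaluation of the three-step model, used as a
# validation oracle. Deliberately written as straight-line, per-placement
# loops over character vectors, sharing nothing with the production kernels
# in affinity.R beyond the loaded parameter tables. Placement values are
# collected in the model's documented order (plus-strand offsets 0..11,
# then minus-strand offsets 0..11) and means are computed as sum()/n.

.oracle_complement <- c(A = "T", C = "G", G = "C", T = "A")

.oracle_revcomp <- function(chars) unname(rev(.oracle_complement[chars]))

# the 24 candidate 15-mer placements of a 26-bp window, as character vectors
.oracle_placements <- function(chars, width) {
  n_off <- length(chars) - width + 1L
  rc <- .oracle_revcomp(chars)
  plc <- vector("list", 2L * n_off)
  for (off in seq_len(n_off)) {
    plc[[off]] <- chars[off:(off + width - 1L)]
  }
  for (off in seq_len(n_off)) {
    plc[[n_off + off]] <- rc[off:(off + width - 1L)]
  }
  plc
}

.oracle_pwm_score <- function(site, params) {
  weights <- params$pwm$weights
  sum(weights[cbind(match(site, rownames(weights)), seq_along(site))])
}

.oracle_slide_value <- function(site, params) {
  co <- params$coefficients
  rg <- params$regions
  r <- rg$three_prime_half
  ta <- sum(site[r] == "T" & site[r + 1L] == "A")
  sc <- rg$slide_center
  widths <- params$mgw$widths[paste0(site[sc], site[sc + 1L])]
  co$slide_ta * ta + co$slide_mgw * (sum(widths) / length(widths)) +
    co$slide_const
}

.oracle_bend_value <- function(site, params) {
  co <- params$coefficients
  rg <- params$regions
  f <- rg$bend_flank
  wr <- sum(paste0(site[f], site[f + 1L]) %in% rg$wr_set)
  cc <- rg$bend_center
  tv <- sum(paste0(site[cc], site[cc + 1L]) %in% rg$tv_set)
  co$bend_wr * wr + co$bend_tv * tv + co$bend_const
}

# best placement by exhaustive enumeration, tie-break offset-major with
# plus strand before minus (enumerated explicitly here, independent of the
# production search)
.oracle_best_site <- function(chars, params) {
  width <- params$pwm$width
  n_off <- length(chars) - width + 1L
  plc <- .oracle_placements(chars, width)
  best_site <- NULL
  best_score <- -Inf
  for (off in seq_len(n_off)) {
    for (strand_first in c(TRUE, FALSE)) {
      site <- if (strand_first) plc[[off]] else plc[[n_off + off]]
      sc <- .oracle_pwm_score(site, params)
      if (sc > best_score) {
        best_score <- sc
        best_site <- site
      }
    }
  }
  list(site = best_site, score = best_score)
}

.oracle_window <- function(window, params) {
  chars <- if (is.character(window) && length(window) == 1L) {
    strsplit(.normalize_dna(window), "", fixed = TRUE)[[1]]
  } else window
  co <- params$coefficients
  plc <- .oracle_placements(chars, params$pwm$width)
  slide_vals <- numeric(length(plc))
  for (i in seq_along(plc)) {
    slide_vals[i] <- .oracle_slide_value(plc[[i]], params)
  }
  ln_k_slide <- -(sum(slide_vals) / length(slide_vals))
  best <- .oracle_best_site(chars, params)
  ln_k_stop <- -best$score
  bend_vals <- c(.oracle_bend_value(best$site, params),
                 .oracle_bend_value(.oracle_revcomp(best$site), params))
  ln_k_bend <- -((bend_vals[1] + bend_vals[2]) / 2)
  minus_ln_kd <- co$c0 - co$stoich * (ln_k_slide + ln_k_stop + ln_k_bend)
  list(ln_k_slide = ln_k_slide, ln_k_stop = ln_k_stop,
       ln_k_bend = ln_k_bend, minus_ln_kd = minus_ln_kd)
}

.oracle_delta <- function(window, params) {
  chars <- strsplit(.normalize_dna(window), "", fixed = TRUE)[[1]]
  vals <- numeric(3L * length(chars))
  k <- 0L
  for (pos in seq_along(chars)) {
    orig <- chars[pos]
    for (b in c("A", "C", "G", "T")) {
      if (b == orig) next
      v <- chars
      v[pos] <- b
      k <- k + 1L
      vals[k] <- .oracle_window(v, params)$minus_ln_kd
    }
  }
  method <- params$options$delta_method
  if (method == "around_base") {
    base_val <- .oracle_window(chars, params)$minus_ln_kd
    sqrt(sum((vals - base_val)^2) / length(vals))
  } else {
    m <- sum(vals) / length(vals)
    div <- if (method == "sample") length(vals) - 1L else length(vals)
    sqrt(sum((vals - m)^2) / div)
  }
}

#' Brute-force promoter scan (validation oracle)
#'
#' A straight-line, unoptimized re-evaluation of the full scan: all 51
#' window centers, all 24 site placements per window, the two-strand
#' bending mean, and the 78-variant uncertainty at the winning center,
#' implemented independently of the production kernels. Intended for
#' validating [scan_promoter()]; it returns the same `affinity_estimate`
#' structure.
#'
#' @inheritParams scan_promoter
#' @return an `affinity_estimate`
#' @export
brute_force_scan <- function(seq, params = load_default_parameters()) {
  seq <- promoter_sequence(seq)
  n <- promoter_length(seq)
  chars <- strsplit(seq$bases, "", fixed = TRUE)[[1]]
  best <- NULL
  best_center <- NA_integer_
  for (center in -70:-20) {
    lo <- n + (center - 13L) + 1L
    ev <- .oracle_window(chars[lo:(lo + 25L)], params)
    if (is.null(best) || ev$minus_ln_kd > best$minus_ln_kd) {
      best <- ev
      best_center <- center
    }
  }
  win <- substr(seq$bases, n + best_center - 12L, n + best_center + 13L)
  delta <- .oracle_delta(win, params)
  structure(
    list(minus_ln_kd = best$minus_ln_kd, delta = delta,
         kd_molar = exp(-best$minus_ln_kd),
         best = structure(list(center = best_center, strand = NA_character_,
                               offset = NA_integer_,
                               ln_k_slide = best$ln_k_slide,
                               ln_k_stop = best$ln_k_stop,
                               ln_k_bend = best$ln_k_bend,
                               minus_ln_kd = best$minus_ln_kd),
                          class = "window_eval"),
         label = seq$label),
    class = "affinity_estimate")
}
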