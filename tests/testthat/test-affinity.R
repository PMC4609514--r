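# Three-step affinity model: sliding/bending terms, window combination,
# promoter scan and the 78-substitution uncertainty.

test_that("sliding term collapses on homopolymers and is orientation-symmetric", {
  co <- PARAMS$coefficients
  # poly-A: every placement on either strand is A15/T15; no TA steps; all
  # central steps have the AA (= TT) groove width
  w_aa <- PARAMS$mgw$widths[["AA"]]
  expect_equal(slide_term(strrep("A", 26L), PARAMS),
               -(co$slide_mgw * w_aa + co$slide_const), tolerance = 1e-12)
  # poly-G likewise with the GG (= CC) width
  w_gg <- PARAMS$mgw$widths[["GG"]]
  expect_equal(slide_term(strrep("G", 26L), PARAMS),
               -(co$slide_mgw * w_gg + co$slide_const), tolerance = 1e-12)
  set.seed(303)
  for (i in 1:100) {
    win <- rand_window()
    expect_equal(slide_term(win, PARAMS), slide_term(revcomp_chr(win), PARAMS),
                 tolerance = 1e-12)
  }
})

test_that("bending term reduces to the intercept without WR/TV steps and matches hand counts", {
  co <- PARAMS$coefficients
  # G/C-only window: no placement on either strand contains a TA, AA, TG,
  # AG, TC dinucleotide, so both strand values are the bare intercept
  expect_equal(bend_term(strrep("GC", 13L), PARAMS), -co$bend_const,
               tolerance = 1e-12)
  expect_equal(bend_term(strrep("C", 26L), PARAMS), -co$bend_const,
               tolerance = 1e-12)

  # canonical TATAAAAG-cored placement: count WR/TV dinucleotides by hand
  hand_bend <- function(site) {
    rg <- PARAMS$regions
    step <- function(s, i) substr(s, i, i + 1L)
    wr <- sum(vapply(rg$bend_flank, function(i) {
      step(site, i) %in% rg$wr_set
    }, NA))
    tv <- sum(vapply(rg$bend_center, function(i) {
      step(site, i) %in% rg$tv_set
    }, NA))
    co$bend_wr * wr + co$bend_tv * tv + co$bend_const
  }
  win <- paste0("CCCCC", "GTATAAAAGGCGGGG", "CCCCCC")
  site <- best_placement(PARAMS$pwm, win)$site
  expect_identical(site, "GTATAAAAGGCGGGG")
  expect_equal(bend_term(win, PARAMS),
               -(hand_bend(site) + hand_bend(revcomp_chr(site))) / 2,
               tolerance = 1e-12)
  # the same hand oracle on seeded windows
  set.seed(304)
  for (i in 1:50) {
    w <- rand_window()
    s <- best_placement(PARAMS$pwm, w)$site
    expect_equal(bend_term(w, PARAMS),
                 -(hand_bend(s) + hand_bend(revcomp_chr(s))) / 2,
                 tolerance = 1e-12)
  }
})

test_that("window affinity combines the three terms and matches the straight-line oracle", {
  co <- PARAMS$coefficients
  set.seed(305)
  for (i in 1:100) {
    win <- rand_window()
    ev <- window_affinity(win, PARAMS, center = -45L)
    # decomposition identity
    expect_equal(ev$minus_ln_kd,
                 co$c0 - co$stoich * (ev$ln_k_slide + ev$ln_k_stop +
                                      ev$ln_k_bend),
                 tolerance = 1e-9)
    # exported terms are the recorded components
    expect_equal(ev$ln_k_slide, slide_term(win, PARAMS), tolerance = 1e-12)
    expect_equal(ev$ln_k_bend, bend_term(win, PARAMS), tolerance = 1e-12)
    expect_equal(ev$ln_k_stop, -best_placement(PARAMS$pwm, win)$score,
                 tolerance = 1e-12)
    # independent straight-line re-implementation
    orc <- tbpaffinity:::.oracle_window(win, PARAMS)
    expect_equal(ev$ln_k_slide, orc$ln_k_slide, tolerance = 1e-12)
    expect_equal(ev$ln_k_stop, orc$ln_k_stop, tolerance = 1e-12)
    expect_equal(ev$ln_k_bend, orc$ln_k_bend, tolerance = 1e-12)
    expect_equal(ev$minus_ln_kd, orc$minus_ln_kd, tolerance = 1e-12)
    # orientation symmetry of the full evaluation
    expect_equal(window_affinity(revcomp_chr(win), PARAMS)$minus_ln_kd,
                 ev$minus_ln_kd, tolerance = 1e-12)
  }
  expect_error(window_affinity("ACGT", PARAMS), "26")
})

test_that("turning a noncanonical core into a canonical TATA box raises the affinity", {
  # identical embedding of gaaagCATAAAAcag vs gaaagTATAAAAcag at
  # positions [-45, -31], inside the scanned region, in neutral padding
  anc <- promoter_sequence(paste0(strrep("C", 45L), "GAAAGCATAAAACAG",
                                  strrep("C", 30L)))
  min_ <- promoter_sequence(paste0(strrep("C", 45L), "GAAAGTATAAAACAG",
                                  strrep("C", 30L)))
  expect_identical(promoter_length(anc), 90L)
  a <- scan_promoter(anc, PARAMS)
  b <- scan_promoter(min_, PARAMS)
  expect_true(b$minus_ln_kd > a$minus_ln_kd)
  # and at single-window resolution with the contexts centered identically
  wa <- paste0("CGCGC", "GAAAGCATAAAACAG", "GCGCGC")
  wb <- paste0("CGCGC", "GAAAGTATAAAACAG", "GCGCGC")
  expect_true(window_affinity(wb, PARAMS)$minus_ln_kd >
              window_affinity(wa, PARAMS)$minus_ln_kd)
})

test_that("the promoter scan maximizes over the 51 centers with an upstream tie-break", {
  # homopolymer: all 51 windows tie; the most-upstream center is reported
  est <- scan_promoter(strrep("A", 90L), PARAMS)
  expect_identical(est$best$center, -70L)
  expect_equal(est$minus_ln_kd, window_affinity(strrep("A", 26L),
                                                PARAMS)$minus_ln_kd,
               tolerance = 1e-12)
  expect_equal(est$kd_molar * exp(est$minus_ln_kd), 1, tolerance = 1e-12)

  set.seed(306)
  for (i in 1:10) {
    prom <- generate_promoter(fixture_spec(seed = 5000 + i))
    got <- scan_promoter(prom, PARAMS)
    # the reported maximum dominates every window evaluation
    per_window <- vapply(-70:-20, function(ctr) {
      window_affinity(window_at(prom, ctr), PARAMS)$minus_ln_kd
    }, 0)
    expect_equal(got$minus_ln_kd, max(per_window), tolerance = 1e-12)
    expect_identical(got$best$center, (-70:-20)[which.max(per_window)])
    expect_equal(got$kd_molar, exp(-got$minus_ln_kd), tolerance = 1e-12)
    # full independent oracle, including delta
    want <- brute_force_scan(prom, PARAMS)
    expect_equal(got$minus_ln_kd, want$minus_ln_kd, tolerance = 1e-12)
    expect_identical(got$best$center, want$best$center)
    expect_equal(got$delta, want$delta, tolerance = 1e-12)
  }
  expect_error(scan_promoter(strrep("A", 50L), PARAMS), "-84")
})

test_that("bases outside every scan window cannot change the estimate", {
  prom <- generate_promoter(fixture_spec(seed = 777))
  est <- scan_promoter(prom, PARAMS)
  # positions -90..-84 are upstream of the most upstream window base (-83)
  for (pos in c(-90L, -87L, -84L)) {
    b <- base_at(prom, pos)
    alt <- setdiff(c("A", "C", "G", "T"), b)[1]
    edited <- apply_variant(prom, variant_spec(pos, b, alt))
    est2 <- scan_promoter(edited, PARAMS)
    expect_identical(est2$best$center, est$best$center)
    expect_equal(est2$minus_ln_kd, est$minus_ln_kd, tolerance = 1e-12)
    expect_equal(est2$delta, est$delta, tolerance = 1e-12)
  }
})

test_that("delta enumerates 78 substitutions and matches its brute-force oracle", {
  prom <- generate_promoter(fixture_spec(seed = 888))
  ctr <- -40L
  win <- window_at(prom, ctr)
  subs <- enumerate_substitutions(win)
  expect_length(subs, 78L)

  d_pop <- delta_estimate(prom, ctr, PARAMS)
  expect_true(d_pop >= 0)
  expect_identical(delta_estimate(prom, ctr, PARAMS), d_pop)  # deterministic
  expect_equal(d_pop, tbpaffinity:::.oracle_delta(win, PARAMS),
               tolerance = 1e-12)

  # estimator variants relate as their formulas dictate
  p_sample <- load_parameters(list(options = list(delta_method = "sample")))
  expect_equal(delta_estimate(prom, ctr, p_sample),
               d_pop * sqrt(78 / 77), tolerance = 1e-12)
  p_ab <- load_parameters(list(options = list(delta_method = "around_base")))
  d_ab <- delta_estimate(prom, ctr, p_ab)
  # RMS deviation about any point is >= the SD about the mean
  expect_true(d_ab >= d_pop - 1e-12)
  expect_equal(d_ab, tbpaffinity:::.oracle_delta(win, p_ab),
               tolerance = 1e-12)

  # delta sits on the same value the enumerated windows imply
  vals <- vapply(subs, function(w) window_affinity(w, PARAMS)$minus_ln_kd, 0)
  expect_equal(d_pop, sqrt(sum((vals - mean(vals))^2) / 78),
               tolerance = 1e-12)
})
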