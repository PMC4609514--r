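# Parameter tables: fitted constants, PWM scoring, best placement,
# overrides and validation.

test_that("default coefficients, region sets and tables carry the fitted constants", {
  co <- PARAMS$coefficients
  expect_identical(co$c0, 10.9)
  expect_identical(co$stoich, 0.2)
  expect_identical(co$slide_ta, 0.8)
  expect_identical(co$slide_mgw, -3.4)
  expect_identical(co$slide_const, -35.1)
  expect_identical(co$bend_wr, 0.9)
  expect_identical(co$bend_tv, 2.5)
  expect_identical(co$bend_const, 14.4)

  expect_identical(PARAMS$regions$wr_set, c("TA", "AA", "TG", "AG"))
  expect_identical(PARAMS$regions$tv_set, c("TA", "TC", "TG"))
  expect_identical(PARAMS$pwm$width, 15L)
  expect_true(all(is.finite(PARAMS$pwm$weights)))
  expect_identical(dim(PARAMS$pwm$weights), c(4L, 15L))
  expect_match(PARAMS$pwm$source_tag, "Bucher")

  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  expect_true(all(dinucs %in% names(PARAMS$mgw$widths)))
  expect_true(all(PARAMS$mgw$widths > 0))
  # strand symmetry: a step and its reverse complement have one width
  for (d in dinucs) {
    expect_identical(PARAMS$mgw$widths[[d]],
                     PARAMS$mgw$widths[[revcomp_chr(d)]])
  }
})

test_that("repeated loads are deterministic with a stable checksum", {
  p2 <- load_default_parameters()
  expect_identical(p2$coefficients, PARAMS$coefficients)
  expect_identical(p2$pwm$weights, PARAMS$pwm$weights)
  expect_identical(p2$mgw$widths, PARAMS$mgw$widths)
  expect_identical(p2$regions, PARAMS$regions)
  cs <- parameter_checksum(PARAMS)
  expect_match(cs, "^[0-9a-f]{8}$")
  expect_identical(parameter_checksum(p2), cs)
  # the checksum reacts to a coefficient change
  p3 <- load_parameters(list(coefficients = list(c0 = 11)))
  expect_false(parameter_checksum(p3) == cs)
})

test_that("site scoring equals a hand summation and peaks at the consensus", {
  w <- PARAMS$pwm$weights
  consensus <- paste(rownames(w)[apply(w, 2, which.max)], collapse = "")
  expect_identical(consensus, "GTATAAAAGGCGGGG")
  cons_score <- score_site(PARAMS$pwm, consensus)

  set.seed(101)
  for (i in 1:100) {
    site <- rand_dna(15L)
    chars <- strsplit(site, "", fixed = TRUE)[[1]]
    hand <- 0
    for (j in 1:15) hand <- hand + w[chars[j], j]
    expect_equal(score_site(PARAMS$pwm, site), hand, tolerance = 1e-12)
    expect_true(score_site(PARAMS$pwm, site) <= cons_score)
  }
  # determinism and case/whitespace normalization
  expect_identical(score_site(PARAMS$pwm, consensus),
                   score_site(PARAMS$pwm, tolower(consensus)))
  expect_error(score_site(PARAMS$pwm, "ACGT"), "15")
  expect_error(score_site(PARAMS$pwm, paste0(strrep("A", 14), "N")))
})

test_that("best placement equals exhaustive enumeration with documented tie-breaks", {
  enum_best <- function(window) {
    rc <- revcomp_chr(window)
    best <- list(score = -Inf)
    for (off in 0:11) {
      for (strand in c("+", "-")) {
        src <- if (strand == "+") window else rc
        site <- substr(src, off + 1L, off + 15L)
        sc <- score_site(PARAMS$pwm, site)
        if (sc > best$score) {
          best <- list(offset = off, strand = strand, score = sc, site = site)
        }
      }
    }
    best
  }
  set.seed(202)
  for (i in 1:200) {
    win <- rand_window()
    got <- best_placement(PARAMS$pwm, win)
    want <- enum_best(win)
    expect_identical(got$offset, want$offset)
    expect_identical(got$strand, want$strand)
    expect_identical(got$site, want$site)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    # the placement set is orientation-closed
    expect_equal(best_placement(PARAMS$pwm, revcomp_chr(win))$score,
                 got$score, tolerance = 1e-12)
  }
  # consensus embedded at a known offset is found there
  win <- paste0("CCCCC", "GTATAAAAGGCGGGG", "CCCCCC")
  got <- best_placement(PARAMS$pwm, win)
  expect_identical(got$offset, 5L)
  expect_identical(got$strand, "+")
  expect_identical(got$site, "GTATAAAAGGCGGGG")
  # homopolymer: all 24 placements tie; smallest offset, plus strand win
  hp <- best_placement(PARAMS$pwm, strrep("A", 26L))
  expect_identical(hp$offset, 0L)
  expect_identical(hp$strand, "+")
  expect_equal(hp$score, score_site(PARAMS$pwm, strrep("A", 15L)),
               tolerance = 1e-12)
})

test_that("parameter overrides round-trip through YAML and JSON config files", {
  cfg <- list(
    coefficients = list(c0 = 11.5, slide_ta = 1.25),
    regions = list(three_prime_half = 9:14, tv_set = c("TA", "TC")),
    options = list(delta_method = "sample"))
  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    if (ext == "json") {
      jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
    } else {
      yaml::write_yaml(cfg, path)
    }
    p <- load_parameters(path)
    expect_identical(p$coefficients$c0, 11.5)
    expect_identical(p$coefficients$slide_ta, 1.25)
    expect_identical(p$coefficients$stoich, 0.2)  # untouched entries stay
    expect_identical(p$regions$three_prime_half, 9:14)
    expect_identical(p$regions$tv_set, c("TA", "TC"))
    expect_identical(p$options$delta_method, "sample")
  }
  # a written config reloads to an identical parameter set
  out <- tempfile(fileext = ".yaml")
  write_parameters_config(PARAMS, out)
  p2 <- load_parameters(out)
  expect_identical(p2$coefficients, PARAMS$coefficients)
  expect_identical(p2$regions, PARAMS$regions)
  expect_identical(parameter_checksum(p2), parameter_checksum(PARAMS))

  expect_error(load_parameters(list(coefficients = list(nope = 1))),
               "unknown coefficient")
  expect_error(load_parameters(list(regions = list(nope = 1:2))),
               "unknown region")
  expect_error(load_parameters(list(options = list(delta_method = "bogus"))),
               "delta_method")
  expect_error(load_parameters("/no/such/config.yaml"), "not found")
})

test_that("validation rejects malformed parameter sets", {
  p <- PARAMS
  p$coefficients$c0 <- NA_real_
  expect_error(validate_parameters(p), "finite")

  p <- PARAMS
  p$mgw$widths[["AA"]] <- -1
  expect_error(validate_parameters(p), "positive")

  p <- PARAMS
  p$mgw$widths <- p$mgw$widths[names(p$mgw$widths) != "CG"]
  expect_error(validate_parameters(p), "CG")

  p <- PARAMS
  p$regions$bend_flank <- c(2L, 9:14)  # overlaps bend_center
  expect_error(validate_parameters(p), "disjoint")

  p <- PARAMS
  p$regions$slide_center <- 10:15  # step 15 is out of bounds for a 15-mer
  expect_error(validate_parameters(p), "outside")
})
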