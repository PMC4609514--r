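# Fitted constants and lookup tables of the three-step TBP-affinity model:
# regression coefficients, the TATA-box position-weight matrix, the
# dinucleotide minor-groove-width table, and the region scheme used by the
# sliding and bending terms.

.default_coefficients <- function() {
  list(
    c0          = 10.9,   # nonspecific TBP-DNA affinity, ln units (~1e-5 M)
    stoich      = 0.2,    # stoichiometric coefficient of the three ln K terms
    slide_ta    = 0.8,    # weight of the TA count in the 3'-half
    slide_mgw   = -3.4,   # weight of the mean minor-groove width (1/Angstrom)
    slide_const = -35.1,  # sliding intercept
    bend_wr     = 0.9,    # weight of the WR count in the site flanks
    bend_tv     = 2.5,    # weight of the TV count in the site core
    bend_const  = 14.4    # bending intercept
  )
}

.default_regions <- function() {
  list(
    # dinucleotide step start indices within the placed 15-mer
    three_prime_half = 8:14,  # steps inside the 3'-half (bases 8-15)
    slide_center     = 5:10,  # steps inside the central 7 bases (5-11)
    bend_center      = 2:8,   # steps inside the 8-bp TATA core (bases 2-9)
    bend_flank       = c(1L, 9:14),  # remaining steps of the placed site
    wr_set = c("TA", "AA", "TG", "AG"),
    tv_set = c("TA", "TC", "TG")
  )
}

.read_pwm_file <- function(path, pseudocount = 0.25, background = 0.25) {
  if (!file.exists(path)) {
    stop("PWM data file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pos", "A", "C", "G", "T")
  if (!all(need %in% names(tab))) {
    stop("PWM file ", path, " must have columns pos, A, C, G, T",
         call. = FALSE)
  }
  tab <- tab[order(tab$pos), ]
  counts <- t(as.matrix(tab[, .BASES]))  # 4 x width, rows A C G T
  totals <- colSums(counts)
  weights <- log((counts + pseudocount) /
                 rep(totals + 4 * pseudocount, each = 4L) / background)
  rownames(weights) <- .BASES
  structure(
    list(width = ncol(weights), weights = weights,
         source_tag = paste("TATA-box count matrix (389 sites) from Bucher's",
                            "1990 EPD promoter compilation; natural-log odds,",
                            "background 0.25, pseudocount", pseudocount)),
    class = "tbp_pwm")
}

.read_mgw_file <- function(path) {
  if (!file.exists(path)) {
    stop("minor-groove-width data file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("dinucleotide", "width_angstrom") %in% names(tab))) {
    stop("groove-width file ", path,
         " must have columns dinucleotide, width_angstrom", call. = FALSE)
  }
  widths <- stats::setNames(tab$width_angstrom, toupper(tab$dinucleotide))
  structure(
    list(widths = widths,
         source_tag = paste("Synthetic representative B-DNA minor-groove",
                            "widths per dinucleotide step (Angstrom),",
                            "constructed for this package; see",
                            "minor_groove_width_synthetic.tsv header")),
    class = "tbp_mgw")
}

# 4x4 numeric matrix m[b1, b2] = width of step b1b2, from the named vector
.mgw_matrix <- function(mgw) {
  m <- matrix(NA_real_, 4L, 4L, dimnames = list(.BASES, .BASES))
  for (d in names(mgw$widths)) {
    m[substr(d, 1L, 1L), substr(d, 2L, 2L)] <- mgw$widths[[d]]
  }
  m
}

.dinuc_set_matrix <- function(set) {
  m <- matrix(FALSE, 4L, 4L, dimnames = list(.BASES, .BASES))
  for (d in set) m[substr(d, 1L, 1L), substr(d, 2L, 2L)] <- TRUE
  m
}

#' Load the default parameter set of the TBP-affinity model
#'
#' Reads the packaged TATA-box position-weight matrix and
#' minor-groove-width table, combines them with the fitted regression
#' coefficients and the region scheme of the sliding/bending terms, and
#' returns a validated parameter set.
#'
#' @return An object of class `tbp_parameters`: a list with elements
#'   `coefficients`, `pwm`, `mgw`, `regions` and `options`, plus
#'   precomputed lookup matrices used by the numeric kernels.
#' @examples
#' p <- load_default_parameters()
#' p$coefficients$c0      # 10.9, the nonspecific-binding baseline
#' p$regions$wr_set       # "TA" "AA" "TG" "AG"
#' @seealso [load_parameters()] for overriding coefficients, tables or
#'   region definitions via a config file.
#' @export
load_default_parameters <- function() {
  pwm_path <- system.file("extdata", "tata_pwm_counts.tsv",
                          package = "tbpaffinity", mustWork = TRUE)
  mgw_path <- system.file("extdata", "minor_groove_width_synthetic.tsv",
                          package = "tbpaffinity", mustWork = TRUE)
  params <- structure(
    list(coefficients = .default_coefficients(),
         pwm = .read_pwm_file(pwm_path),
         mgw = .read_mgw_file(mgw_path),
         regions = .default_regions(),
         options = list(delta_method = "population")),
    class = "tbp_parameters")
  validate_parameters(params)
}

#' Load a parameter set with optional overrides
#'
#' @param config `NULL` (defaults), a named list, or the path of a YAML/JSON
#'   file. Recognized entries: `coefficients` (any of the eight regression
#'   constants), `regions` (index sets and the `wr_set`/`tv_set`
#'   dinucleotide sets), `options` (`delta_method`: `"population"`,
#'   `"sample"` or `"around_base"`), `pwm_file` and `mgw_file` (paths of
#'   replacement tables in the packaged TSV layouts).
#' @return A validated `tbp_parameters` object.
#' @export
load_parameters <- function(config = NULL) {
  params <- load_default_parameters()
  if (is.null(config)) return(params)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("parameter config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  if (!is.null(config$pwm_file)) params$pwm <- .read_pwm_file(config$pwm_file)
  if (!is.null(config$mgw_file)) params$mgw <- .read_mgw_file(config$mgw_file)
  for (nm in names(config$coefficients)) {
    if (!nm %in% names(params$coefficients)) {
      stop("unknown coefficient in config: ", nm, call. = FALSE)
    }
    params$coefficients[[nm]] <- as.numeric(config$coefficients[[nm]])
  }
  for (nm in names(config$regions)) {
    if (!nm %in% names(params$regions)) {
      stop("unknown region entry in config: ", nm, call. = FALSE)
    }
    val <- config$regions[[nm]]
    params$regions[[nm]] <-
      if (nm %in% c("wr_set", "tv_set")) toupper(val) else as.integer(val)
  }
  for (nm in names(config$options)) {
    params$options[[nm]] <- config$options[[nm]]
  }
  validate_parameters(params)
}

#' Write a parameter config file that round-trips the overridable entries
#'
#' @param params a `tbp_parameters` object
#' @param path output path; format chosen by extension (`.json` or `.yaml`)
#' @return `path`, invisibly.
#' @export
write_parameters_config <- function(params, path) {
  stopifnot(inherits(params, "tbp_parameters"))
  cfg <- list(coefficients = params$coefficients,
              regions = params$regions,
              options = params$options)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter tables (coefficient finiteness,
#' PWM shape, completeness and positivity of the groove-width table,
#' bounds and disjointness of the region index sets) and attaches the
#' precomputed lookup matrices used by the numeric kernels.
#'
#' @param params a `tbp_parameters` object
#' @return the validated object (with refreshed lookup matrices)
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "tbp_parameters")) {
    stop("params must be a tbp_parameters object", call. = FALSE)
  }
  co <- params$coefficients
  need <- names(.default_coefficients())
  if (!all(need %in% names(co))) {
    stop("missing coefficient(s): ",
         paste(setdiff(need, names(co)), collapse = ", "), call. = FALSE)
  }
  for (nm in need) {
    if (!is.numeric(co[[nm]]) || length(co[[nm]]) != 1L ||
        !is.finite(co[[nm]])) {
      stop("coefficient ", nm, " must be a single finite number",
           call. = FALSE)
    }
  }
  pwm <- params$pwm
  if (!inherits(pwm, "tbp_pwm") || !is.matrix(pwm$weights) ||
      nrow(pwm$weights) != 4L || ncol(pwm$weights) != pwm$width) {
    stop("pwm must carry a 4 x width weight matrix", call. = FALSE)
  }
  if (pwm$width != 15L) {
    stop("pwm width must be 15 (TBP-binding site length), got ", pwm$width,
         call. = FALSE)
  }
  if (!all(is.finite(pwm$weights))) {
    stop("pwm weights must all be finite", call. = FALSE)
  }
  mgw <- params$mgw
  dinucs <- as.vector(outer(.BASES, .BASES, paste0))
  if (!inherits(mgw, "tbp_mgw") || !all(dinucs %in% names(mgw$widths))) {
    stop("mgw table must cover all 16 dinucleotides; missing: ",
         paste(setdiff(dinucs, names(mgw$widths)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(mgw$widths > 0)) {
    stop("mgw widths must be strictly positive", call. = FALSE)
  }
  rg <- params$regions
  steps <- seq_len(pwm$width - 1L)
  for (nm in c("three_prime_half", "slide_center", "bend_center",
               "bend_flank")) {
    if (!all(rg[[nm]] %in% steps)) {
      stop("region ", nm, " has step indices outside 1..", max(steps),
           call. = FALSE)
    }
  }
  if (length(intersect(rg$bend_center, rg$bend_flank)) > 0L) {
    stop("bend_center and bend_flank must be disjoint", call. = FALSE)
  }
  if (!all(nchar(c(rg$wr_set, rg$tv_set)) == 2L)) {
    stop("wr_set and tv_set must contain dinucleotides", call. = FALSE)
  }
  if (!params$options$delta_method %in%
      c("population", "sample", "around_base")) {
    stop("options$delta_method must be one of population, sample, around_base",
         call. = FALSE)
  }
  # precomputed kernels
  params$.mgw_mat <- .mgw_matrix(mgw)
  if (anyNA(params$.mgw_mat)) stop("mgw table has undefined entries",
                                   call. = FALSE)
  params$.wr_mat <- .dinuc_set_matrix(rg$wr_set)
  params$.tv_mat <- .dinuc_set_matrix(rg$tv_set)
  # base indices of every 15-mer placement inside a 26-bp window (12 offsets)
  params$.site_idx <- outer(seq_len(pwm$width), 0:(26L - pwm$width), `+`)
  params
}

#' Stable checksum of a parameter set
#'
#' A deterministic hex digest over the coefficients, PWM weights,
#' groove-width table and region scheme; identical loads give identical
#' checksums. Logged by the batch driver so that reports are traceable to
#' the parameter tables that produced them.
#'
#' @param params a `tbp_parameters` object
#' @return a character scalar (8 hex digits)
#' @export
parameter_checksum <- function(params) {
  stopifnot(inherits(params, "tbp_parameters"))
  canon <- paste(
    paste(names(params$coefficients),
          vapply(params$coefficients, format, "", digits = 17),
          collapse = ";"),
    paste(format(params$pwm$weights, digits = 17), collapse = ","),
    paste(names(params$mgw$widths),
          format(params$mgw$widths, digits = 17), collapse = ";"),
    paste(vapply(params$regions, paste, "", collapse = ","), collapse = "|"),
    params$options$delta_method,
    sep = "#")
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1
  h <- 0
  for (b in utf8ToInt(canon)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.tbp_parameters <- function(x, ...) {
  cat("TBP-affinity model parameters\n")
  cat("  coefficients:",
      paste(names(x$coefficients), unlist(x$coefficients), sep = "=",
            collapse = ", "), "\n")
  cat("  pwm: ", x$pwm$width, " positions; ", x$pwm$source_tag, "\n",
      sep = "")
  cat("  mgw: ", length(x$mgw$widths), " dinucleotides; ",
      x$mgw$source_tag, "\n", sep = "")
  cat("  delta method:", x$options$delta_method, "\n")
  cat("  checksum:", parameter_checksum(x), "\n")
  invisible(x)
}

#' Score a 15-bp site with the TATA-box weight matrix
#'
#' Additive PWM score of a single placement in the given orientation, in ln
#' units. Under the model's conventions the score of the best placement is
#' read as \eqn{-\ln K_{STOP}}, the stopping term of the three-step model.
#'
#' @param pwm a `tbp_pwm` object (e.g. `load_default_parameters()$pwm`)
#' @param site a 15-character DNA string over A/C/G/T
#' @return the score (ln units)
#' @export
score_site <- function(pwm, site) {
  stopifnot(inherits(pwm, "tbp_pwm"))
  s <- .normalize_dna(site)
  if (nchar(s) != pwm$width) {
    stop("site must be ", pwm$width, " bp, got ", nchar(s), call. = FALSE)
  }
  codes <- .encode_dna(s)
  .score_codes(pwm$weights, codes)
}

.score_codes <- function(weights, codes) {
  sum(weights[cbind(codes, seq_along(codes))])
}

#' Best placement of the TATA-box matrix inside a 26-bp window
#'
#' Maximizes the PWM score over all 12 offsets of a 15-mer and both
#' orientations (24 placements). Ties are broken deterministically:
#' smallest offset first; at equal offset, plus strand before minus.
#'
#' @param pwm a `tbp_pwm` object
#' @param window a 26-character DNA string
#' @return a list with `offset` (0-based, within the scanned strand),
#'   `strand` (`"+"` or `"-"`), `score` (ln units) and `site` (the placed
#'   15-mer as written on the scanned strand)
#' @export
best_placement <- function(pwm, window) {
  stopifnot(inherits(pwm, "tbp_pwm"))
  w <- .check_window26(window)
  codes <- .encode_dna(w)
  bp <- .best_placement_codes(pwm$weights, codes)
  bp$site <- .decode_dna(bp$site_codes)
  bp$site_codes <- NULL
  bp
}

# shared kernel; minus-strand offsets are taken within the reverse
# complement of the window. Tie-break: smallest offset first; at equal
# offset, plus strand before minus.
.best_placement_codes <- function(weights, codes) {
  width <- ncol(weights)
  n_off <- length(codes) - width + 1L
  rc <- .revcomp_codes(codes)
  best <- list(offset = 0L, strand = "+", score = -Inf, site_codes = NULL)
  for (off in seq_len(n_off) - 1L) {
    for (strand in c("+", "-")) {
      str_codes <- if (strand == "+") codes else rc
      site <- str_codes[(off + 1L):(off + width)]
      sc <- .score_codes(weights, site)
      if (sc > best$score) {
        best <- list(offset = off, strand = strand, score = sc,
                     site_codes = site)
      }
    }
  }
  best
}
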