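# Synthetic promoter fixtures and the bundled SNP benchmark, so the whole
# pipeline is testable without any download.

#' Specify a synthetic promoter fixture
#'
#' @param seed integer random seed; fixtures are deterministic functions of
#'   their spec
#' @param length sequence length in bp (default 90, covering \eqn{[-90, -1]})
#' @param gc_content target G+C fraction in \eqn{[0, 1]}; the generated
#'   sequence carries exactly `round(gc_content * length)` G/C bases
#'   (before any motif is written over it)
#' @param embedded_motif optional DNA text written verbatim into the
#'   sequence
#' @param motif_position TSS-relative position of the motif's first base
#' @return an object of class `fixture_spec`
#' @export
fixture_spec <- function(seed, length = 90L, gc_content = 0.5,
                         embedded_motif = NULL, motif_position = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  length <- as.integer(length)
  if (gc_content < 0 || gc_content > 1) {
    stop("gc_content must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(embedded_motif)) {
    embedded_motif <- .normalize_dna(embedded_motif)
    .encode_dna(embedded_motif)
    if (is.null(motif_position)) {
      stop("motif_position is required with embedded_motif", call. = FALSE)
    }
    motif_position <- as.integer(motif_position)
    if (motif_position < -length ||
        motif_position + nchar(embedded_motif) - 1L > -1L) {
      stop("embedded motif at ", motif_position, " does not fit within [-",
           length, ", -1]", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), length = length,
                 gc_content = gc_content, embedded_motif = embedded_motif,
                 motif_position = motif_position),
            class = "fixture_spec")
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, fn) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  fn()
}

#' Derive a per-fixture seed from a master seed
#'
#' One top-level seed fans out to independent per-fixture seeds by a fixed
#' affine congruential step modulo the Mersenne prime \eqn{2^{31}-1}.
#'
#' @param master integer master seed
#' @param index fixture index (1, 2, ...)
#' @return an integer seed in \eqn{[0, 2^{31}-2]}
#' @export
derive_seed <- function(master, index) {
  as.integer((abs(as.numeric(master)) * 48271 + as.numeric(index) * 16807) %%
             2147483647)
}

#' Generate a synthetic promoter sequence
#'
#' Seeded and reproducible: the same spec always yields the same sequence.
#' G/C bases are placed at exactly `round(gc_content * length)` randomly
#' chosen positions; any embedded motif is then written verbatim at its
#' position.
#'
#' @param spec a `fixture_spec` (or an integer seed, taken as
#'   `fixture_spec(seed)`)
#' @return a `promoter_seq`
#' @examples
#' generate_promoter(fixture_spec(seed = 42, gc_content = 0.4))
#' @export
generate_promoter <- function(spec) {
  if (is.numeric(spec)) spec <- fixture_spec(spec)
  stopifnot(inherits(spec, "fixture_spec"))
  bases <- .with_seed(spec$seed, function() {
    n <- spec$length
    n_gc <- round(spec$gc_content * n)
    out <- sample(c("A", "T"), n, replace = TRUE)
    if (n_gc > 0L) {
      gc_pos <- sample.int(n, n_gc)
      out[gc_pos] <- sample(c("G", "C"), n_gc, replace = TRUE)
    }
    out
  })
  if (!is.null(spec$embedded_motif)) {
    idx <- spec$length + spec$motif_position + 1L
    bases[idx:(idx + nchar(spec$embedded_motif) - 1L)] <-
      strsplit(spec$embedded_motif, "", fixed = TRUE)[[1]]
  }
  promoter_sequence(paste(bases, collapse = ""),
                    label = sprintf("fixture_seed%d", spec$seed))
}

#' All 78 single-base substitution variants of a 26-bp window
#'
#' Enumerates, for each of the 26 positions, the 3 alternative bases
#' (alphabetical order, skipping the current base): exactly 78 windows at
#' Hamming distance 1 from the input, no duplicates. The order matches the
#' enumeration used by [delta_estimate()].
#'
#' @param window a 26-character DNA string
#' @return a character vector of 78 windows
#' @export
enumerate_substitutions <- function(window) {
  w <- .check_window26(window)
  chars <- strsplit(w, "", fixed = TRUE)[[1]]
  out <- character(3L * length(chars))
  k <- 0L
  for (pos in seq_along(chars)) {
    orig <- chars[pos]
    for (b in .BASES) {
      if (b == orig) next
      v <- chars
      v[pos] <- b
      k <- k + 1L
      out[k] <- paste(v, collapse = "")
    }
  }
  out
}

# Fixed neutral 90-bp scaffold for embedding benchmark contexts: G/C only,
# so it contains no TA/WR/TV dinucleotides and no TATA-like PWM placement
# that could confound the direction of an embedded variant's effect.
.NEUTRAL_SCAFFOLD <- strrep("GCGGC", 18L)

#' Embed a reported 21-bp promoter context in a neutral scaffold
#'
#' Reconstructs an ancestral/minor allele pair from a benchmark row: the
#' printed context (5'-flank, ancestral allele, 3'-flank) is written at its
#' reported TSS-relative position into a fixed neutral G/C-only 90-bp
#' scaffold, and the minor allele is produced with [apply_variant()]. Only
#' the *direction* of the affinity change on such a pair is meaningful; the
#' magnitude depends on the true genomic flanks.
#'
#' @param row optionally a list or one-row data.frame with fields
#'   `position`, `flank5`, `ref`, `alt`, `flank3`, `kind`, `label` (e.g. a
#'   row of [tbp_snp_benchmark()]); otherwise pass the fields directly
#' @param position TSS-relative position of the variant (for insertions,
#'   the first base of the 3'-flank)
#' @param flank5,flank3 printed flanking sequence (any length; 10 bp in the
#'   bundled benchmark)
#' @param ref,alt ancestral / minor base(s); `""` or `"."` when empty
#' @param kind variant kind; inferred from ref/alt when `NULL`
#' @param label identifier
#' @return a list with `ancestral` and `minor` (`promoter_seq`) and
#'   `variant` (`variant_spec`)
#' @export
table_context_fixture <- function(row = NULL, position = NULL,
                                  flank5 = NULL, ref = NULL, alt = NULL,
                                  flank3 = NULL, kind = NULL, label = NULL) {
  if (!is.null(row)) {
    row <- as.list(row)
    position <- row$position
    flank5 <- row$flank5
    ref <- row$ref
    alt <- row$alt
    flank3 <- row$flank3
    kind <- row$kind %||% NULL
    label <- label %||% row$label
  }
  if (!is.null(kind)) {
    kind <- c(sub = "substitution", del = "deletion", ins = "insertion",
              substitution = "substitution", deletion = "deletion",
              insertion = "insertion")[[kind]]
  }
  v <- variant_spec(position, ref, alt, kind, label)
  flank5 <- .normalize_dna(flank5)
  flank3 <- .normalize_dna(flank3)
  context <- paste0(flank5, v$ref, flank3)
  start_pos <- v$position - nchar(flank5)
  end_pos <- start_pos + nchar(context) - 1L
  n <- nchar(.NEUTRAL_SCAFFOLD)
  if (start_pos < -n || end_pos > -1L) {
    stop("context for '", v$label %||% "?", "' spans [", start_pos, ", ",
         end_pos, "], outside the scaffold span [-", n, ", -1]",
         call. = FALSE)
  }
  idx <- n + start_pos + 1L
  bases <- paste0(substr(.NEUTRAL_SCAFFOLD, 1L, idx - 1L), context,
                  substring(.NEUTRAL_SCAFFOLD, idx + nchar(context)))
  ancestral <- promoter_sequence(bases, label = paste0(v$label %||% "context",
                                                       "_ancestral"))
  minor <- apply_variant(ancestral, v)
  list(ancestral = ancestral, minor = minor, variant = v)
}

#' Bundled benchmark of published promoter SNPs in TBP-binding sites
#'
#' Loads the packaged table of literature-reported promoter variants: 21-bp
#' contexts (10-bp flanks around the variant), reported dissociation
#' constants of both alleles (nM), the reported direction of the expression
#' change (`up`/`down`/`eq`), and the reported Z-score and significance
#' level. See the TSV header in `inst/extdata` for provenance notes.
#'
#' @return a data.frame, one row per variant
#' @export
tbp_snp_benchmark <- function() {
  path <- system.file("extdata", "tbp_snp_benchmark.tsv",
                      package = "tbpaffinity", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  tab$ref[tab$ref == "."] <- ""
  tab$alt[tab$alt == "."] <- ""
  tab
}
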