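# Core-promoter sequences anchored at the transcription start site (TSS).
# Positions are 1-based negative offsets: the last base of the sequence is
# position -1, the base 5' of it -2, and so on; the TSS itself (position 0)
# is not part of the sequence.

.PROMOTER_MIN <- 84L   # the window centered at -70 must fit (reaches -83)
.PROMOTER_MAX <- 120L

#' Construct a TSS-anchored core-promoter sequence
#'
#' @param bases DNA text over A/C/G/T (case-insensitive; whitespace
#'   stripped). The default design length is 90 bp, covering positions
#'   \eqn{[-90, -1]}; lengths 84-120 bp are accepted so that indel alleles
#'   remain analyzable. Ambiguity codes are rejected: the affinity model has
#'   no semantics for them.
#' @param label optional free-text identifier
#' @return an object of class `promoter_seq` with elements `bases` (the
#'   normalized sequence) and `label`. The 3' end is anchored at position
#'   -1 regardless of length.
#' @examples
#' p <- promoter_sequence(strrep("ACGT", 22), "example88")
#' promoter_length(p)
#' base_at(p, -1)
#' @export
promoter_sequence <- function(bases, label = NULL) {
  if (inherits(bases, "promoter_seq")) return(bases)
  if (!is.character(bases) || length(bases) != 1L) {
    stop("bases must be a single character string", call. = FALSE)
  }
  b <- .normalize_dna(bases)
  n <- nchar(b)
  if (n < .PROMOTER_MIN || n > .PROMOTER_MAX) {
    stop("promoter sequence must cover at least [-", .PROMOTER_MIN,
         ", -1] and at most [-", .PROMOTER_MAX, ", -1]; got ", n,
         " bp (the scan window centered at -70 spans down to -83)",
         call. = FALSE)
  }
  .encode_dna(b)  # errors on ambiguity codes
  structure(list(bases = b, label = label), class = "promoter_seq")
}

#' @rdname promoter_sequence
#' @param x a `promoter_seq`
#' @export
promoter_length <- function(x) nchar(promoter_sequence(x)$bases)

# string index of TSS-relative position p (p in -L..-1)
.pos_index <- function(n, p) {
  idx <- n + p + 1L
  if (any(p >= 0L) || any(idx < 1L)) {
    stop("position ", paste(p[p >= 0L | idx < 1L], collapse = ","),
         " outside the sequence span [-", n, ", -1]", call. = FALSE)
  }
  idx
}

#' @rdname promoter_sequence
#' @param position TSS-relative position (negative; -1 is the last base)
#' @export
base_at <- function(x, position) {
  x <- promoter_sequence(x)
  idx <- .pos_index(promoter_length(x), as.integer(position))
  substr(x$bases, idx, idx)
}

#' Extract the 26-bp scan window centered at a TSS-relative position
#'
#' The window at center \eqn{i} spans positions \eqn{[i-13, i+12]}.
#'
#' @param x a `promoter_seq` (or DNA text)
#' @param center TSS-relative center position
#' @return a 26-character DNA string
#' @export
window_at <- function(x, center) {
  x <- promoter_sequence(x)
  n <- promoter_length(x)
  center <- as.integer(center)
  lo <- center - 13L
  hi <- center + 12L
  if (lo < -n || hi > -1L) {
    stop("window centered at ", center, " spans [", lo, ", ", hi,
         "], outside the sequence span [-", n, ", -1]", call. = FALSE)
  }
  substr(x$bases, .pos_index(n, lo), .pos_index(n, hi))
}

#' @export
print.promoter_seq <- function(x, ...) {
  n <- promoter_length(x)
  cat("promoter_seq", if (!is.null(x$label)) paste0("'", x$label, "'"),
      paste0("[", -n, ", -1]"), "\n")
  cat(" ", x$bases, "\n")
  invisible(x)
}

#' @export
as.character.promoter_seq <- function(x, ...) x$bases
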