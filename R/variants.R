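# Variant specifications (substitution, deletion, insertion) at
# TSS-relative promoter positions, and their application to a reference
# promoter to construct the minor allele.

#' Specify a promoter variant
#'
#' @param position TSS-relative coordinate (negative) of the affected base:
#'   for substitutions and deletions the 5'-most base of `ref`; for
#'   insertions the base in front of which `alt` is inserted (the first
#'   inserted base takes the place of the base currently at `position`,
#'   which moves 3' of the insert).
#' @param ref ancestral base(s); empty (`""` or `"."`) for insertions
#' @param alt minor base(s); empty for deletions
#' @param kind `"substitution"`, `"deletion"` or `"insertion"`; inferred
#'   from `ref`/`alt` when missing
#' @param label free-text identifier (e.g. an rsID)
#' @return an object of class `variant_spec`
#' @examples
#' variant_spec(-31, "C", "T", label = "rs1143627")
#' parse_variant("-31c>t")
#' parse_variant("del-29t")
#' parse_variant("ins-55at")
#' @export
variant_spec <- function(position, ref, alt, kind = NULL, label = NULL) {
  clean <- function(x) {
    x <- toupper(x)
    if (x %in% c(".", "-")) "" else x
  }
  ref <- clean(ref)
  alt <- clean(alt)
  for (x in c(ref, alt)) {
    if (nchar(x) > 0L) .encode_dna(x)
  }
  position <- as.integer(position)
  if (is.na(position) || position >= 0L) {
    stop("variant position must be a negative TSS-relative coordinate",
         call. = FALSE)
  }
  if (is.null(kind)) {
    kind <- if (nchar(ref) == 0L) "insertion"
            else if (nchar(alt) == 0L) "deletion"
            else "substitution"
  }
  kind <- match.arg(kind, c("substitution", "deletion", "insertion"))
  ok <- switch(kind,
    substitution = nchar(ref) == nchar(alt) && nchar(ref) >= 1L,
    deletion     = nchar(ref) >= 1L && nchar(alt) == 0L,
    insertion    = nchar(ref) == 0L && nchar(alt) >= 1L)
  if (!ok) {
    stop("kind '", kind, "' inconsistent with ref='", ref, "', alt='", alt,
         "'", call. = FALSE)
  }
  structure(list(position = position, ref = ref, alt = alt, kind = kind,
                 label = label),
            class = "variant_spec")
}

#' @rdname variant_spec
#' @param notation inline variant notation: `"-31c>t"` (also accepted with
#'   a Unicode minus and arrow, `"−31c→t"`), `"del-29t"`,
#'   `"ins-55at"`. Multi-allelic substitutions such as `"-29t>a,g,c"` are
#'   resolved to their first listed alternative.
#' @export
parse_variant <- function(notation, label = NULL) {
  x <- tolower(gsub("−", "-", trimws(notation)))
  x <- gsub("→|->", ">", x)
  if (is.null(label)) label <- notation
  m <- regmatches(x, regexec("^del(-[0-9]+)([acgt]+)$", x))[[1]]
  if (length(m)) {
    return(variant_spec(as.integer(m[2]), m[3], "", "deletion", label))
  }
  m <- regmatches(x, regexec("^ins(-[0-9]+)([acgt]+)$", x))[[1]]
  if (length(m)) {
    return(variant_spec(as.integer(m[2]), "", m[3], "insertion", label))
  }
  m <- regmatches(x,
                  regexec("^(-[0-9]+)([acgt]+)>([acgt]+(,[acgt]+)*)$", x))[[1]]
  if (length(m)) {
    alt <- strsplit(m[4], ",", fixed = TRUE)[[1]][1]
    return(variant_spec(as.integer(m[2]), m[3], alt, "substitution", label))
  }
  stop("cannot parse variant notation: '", notation, "'", call. = FALSE)
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("variant_spec%s: %s at %d, '%s' -> '%s'\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$kind, x$position, x$ref, x$alt))
  invisible(x)
}

#' Apply a variant to a promoter, constructing the minor allele
#'
#' The edited sequence is re-anchored so its last base is again position
#' -1; deletions shorten and insertions lengthen the sequence within the
#' accepted 84-120 bp span.
#'
#' @param seq a `promoter_seq` (or DNA text)
#' @param variant a `variant_spec` or inline notation string
#' @return the edited `promoter_seq`
#' @examples
#' prom <- generate_promoter(fixture_spec(seed = 1))
#' v <- variant_spec(-31, base_at(prom, -31),
#'                   setdiff(c("A", "C", "G", "T"), base_at(prom, -31))[1])
#' apply_variant(prom, v)
#' @export
apply_variant <- function(seq, variant) {
  seq <- promoter_sequence(seq)
  if (is.character(variant)) variant <- parse_variant(variant)
  stopifnot(inherits(variant, "variant_spec"))
  n <- promoter_length(seq)
  idx <- .pos_index(n, variant$position)
  bases <- seq$bases
  if (variant$kind %in% c("substitution", "deletion")) {
    span <- idx + nchar(variant$ref) - 1L
    if (span > n) {
      stop("variant ref runs past the 3' end of the sequence", call. = FALSE)
    }
    observed <- substr(bases, idx, span)
    if (observed != variant$ref) {
      stop("ref mismatch at position ", variant$position, ": expected '",
           variant$ref, "' but sequence has '", observed, "'", call. = FALSE)
    }
    edited <- paste0(substr(bases, 1L, idx - 1L), variant$alt,
                     substring(bases, span + 1L))
  } else {
    edited <- paste0(substr(bases, 1L, idx - 1L), variant$alt,
                     substring(bases, idx))
  }
  if (variant$kind == "substitution" && variant$ref == variant$alt) {
    warning("variant '", variant$label,
            "' has alt identical to ref; the alleles are the same sequence",
            call. = FALSE)
  }
  n_new <- nchar(edited)
  if (n_new < .PROMOTER_MIN || n_new > .PROMOTER_MAX) {
    stop("edit yields a ", n_new, " bp sequence, outside the accepted [",
         .PROMOTER_MIN, ", ", .PROMOTER_MAX, "] bp span", call. = FALSE)
  }
  promoter_sequence(edited,
                    label = if (is.null(variant$label)) seq$label
                            else paste0(seq$label %||% "", "|",
                                        variant$label))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
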