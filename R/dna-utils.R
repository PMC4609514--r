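# Internal DNA helpers shared by the model code. Sequences are handled as
# uppercase character strings at the interface and as integer codes
# (A=1, C=2, G=3, T=4) inside the numeric kernels.

.BASES <- c("A", "C", "G", "T")

.encode_dna <- function(x) {
  codes <- match(strsplit(x, "", fixed = TRUE)[[1]], .BASES)
  if (anyNA(codes)) {
    stop("sequence contains characters outside {A, C, G, T}: ",
         substr(x, 1L, 40L), call. = FALSE)
  }
  codes
}

.decode_dna <- function(codes) paste(.BASES[codes], collapse = "")

# reverse complement of an integer-coded sequence (A<->T, C<->G)
.revcomp_codes <- function(codes) rev(5L - codes)

.revcomp_string <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

.normalize_dna <- function(x) toupper(gsub("[ \t\r\n]", "", x))

.check_window26 <- function(window) {
  if (!is.character(window) || length(window) != 1L) {
    stop("window must be a single character string", call. = FALSE)
  }
  w <- .normalize_dna(window)
  if (nchar(w) != 26L) {
    stop("window must be exactly 26 bp, got ", nchar(w), " bp", call. = FALSE)
  }
  w
}
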