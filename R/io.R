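# Sequence and variant-table input, single-pair and batch drivers, and
# table-style report output.

#' Read promoter sequences from FASTA, plain text, or strings
#'
#' @param input a file path (FASTA if the file starts with `>`, otherwise
#'   one raw sequence per line) or a character vector of sequences (an
#'   element containing `>` is parsed as inline FASTA)
#' @return a list of `promoter_seq`, uppercase-normalized and anchored at
#'   position -1
#' @export
read_promoter_sequences <- function(input) {
  if (length(input) == 1L && file.exists(input)) {
    first <- readLines(input, n = 1L, warn = FALSE)
    if (length(first) == 0L) stop("empty sequence file: ", input,
                                  call. = FALSE)
    if (startsWith(trimws(first), ">")) {
      set <- Biostrings::readDNAStringSet(input)
      if (length(set) == 0L) stop("no records in FASTA file: ", input,
                                  call. = FALSE)
      return(mapply(function(s, nm) promoter_sequence(s, label = nm),
                    as.character(set), names(set),
                    SIMPLIFY = FALSE, USE.NAMES = FALSE))
    }
    lines <- readLines(input, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty sequence file: ", input,
                                  call. = FALSE)
    return(lapply(seq_along(lines), function(i) {
      promoter_sequence(lines[i], label = sprintf("seq%d", i))
    }))
  }
  if (any(grepl(">", input, fixed = TRUE))) {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE))
    heads <- grep("^>", lines)
    if (length(heads) == 0L) stop("malformed inline FASTA", call. = FALSE)
    return(lapply(seq_along(heads), function(i) {
      from <- heads[i] + 1L
      to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
      promoter_sequence(paste(lines[from:to], collapse = ""),
                        label = sub("^>\\s*", "", lines[heads[i]]))
    }))
  }
  lapply(seq_along(input), function(i) {
    promoter_sequence(input[i], label = sprintf("seq%d", i))
  })
}

#' Write promoter sequences as FASTA
#'
#' @param seqs a `promoter_seq` or list of them
#' @param path output path
#' @return `path`, invisibly
#' @export
write_promoter_fasta <- function(seqs, path) {
  if (inherits(seqs, "promoter_seq")) seqs <- list(seqs)
  set <- Biostrings::DNAStringSet(vapply(seqs, function(s) s$bases, ""))
  names(set) <- vapply(seq_along(seqs), function(i) {
    seqs[[i]]$label %||% sprintf("seq%d", i)
  }, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# longest common prefix/suffix split used for the display slices
.diff_region <- function(a, b) {
  na <- nchar(a)
  nb <- nchar(b)
  nmin <- min(na, nb)
  cp <- 0L
  while (cp < nmin &&
         substr(a, cp + 1L, cp + 1L) == substr(b, cp + 1L, cp + 1L)) {
    cp <- cp + 1L
  }
  cs <- 0L
  while (cs < nmin - cp &&
         substr(a, na - cs, na - cs) == substr(b, nb - cs, nb - cs)) {
    cs <- cs + 1L
  }
  list(flank5 = substr(a, max(1L, cp - 9L), cp),
       allele_a = substr(a, cp + 1L, na - cs),
       allele_b = substr(b, cp + 1L, nb - cs),
       flank3 = substr(a, na - cs + 1L, min(na, na - cs + 10L)))
}

.pair_record <- function(anc_est, min_est, anc_seq, min_seq, alpha = 0.05,
                         label = NA_character_, gene = NA_character_,
                         notation = NA_character_) {
  cmp <- compare_alleles(anc_est, min_est, alpha = alpha)
  d <- .diff_region(anc_seq$bases, min_seq$bases)
  data.frame(
    label = label, gene = gene, notation = notation,
    flank5 = d$flank5, allele_ancestral = d$allele_a,
    allele_minor = d$allele_b, flank3 = d$flank3,
    kd_ancestral_nM = signif(1e9 * anc_est$kd_molar, 3),
    kd_minor_nM = signif(1e9 * min_est$kd_molar, 3),
    arrow = cmp$direction_arrow,
    z = round(cmp$z, 2),
    alpha_bucket = cmp$alpha_bucket,
    p = cmp$p,
    decision = cmp$decision,
    minus_ln_kd_ancestral = anc_est$minus_ln_kd,
    delta_ancestral = anc_est$delta,
    minus_ln_kd_minor = min_est$minus_ln_kd,
    delta_minor = min_est$delta,
    error = NA_character_,
    stringsAsFactors = FALSE)
}

.empty_record <- function(label = NA_character_, gene = NA_character_,
                          notation = NA_character_, error = NA_character_) {
  data.frame(
    label = label, gene = gene, notation = notation,
    flank5 = NA_character_, allele_ancestral = NA_character_,
    allele_minor = NA_character_, flank3 = NA_character_,
    kd_ancestral_nM = NA_real_, kd_minor_nM = NA_real_,
    arrow = NA_character_, z = NA_real_, alpha_bucket = NA_character_,
    p = NA_real_, decision = NA_character_,
    minus_ln_kd_ancestral = NA_real_, delta_ancestral = NA_real_,
    minus_ln_kd_minor = NA_real_, delta_minor = NA_real_,
    error = error, stringsAsFactors = FALSE)
}

#' Analyze one ancestral/minor promoter pair
#'
#' Runs the full pipeline on two explicit sequences: scans both alleles,
#' compares them, and returns a one-row report record with display slices
#' of the differing region, dissociation constants in nM (3 significant
#' digits), the direction arrow, Z (2 decimals), the significance bucket
#' and the decision, alongside full-precision columns.
#'
#' @param base_seq,edited_seq ancestral and minor promoter sequences
#'   (`promoter_seq` or DNA text)
#' @param params a `tbp_parameters` object
#' @param alpha significance threshold
#' @param label record identifier
#' @return a one-row data.frame
#' @export
run_pair <- function(base_seq, edited_seq,
                     params = load_default_parameters(), alpha = 0.05,
                     label = NA_character_) {
  base_seq <- promoter_sequence(base_seq)
  edited_seq <- promoter_sequence(edited_seq)
  .pair_record(scan_promoter(base_seq, params),
               scan_promoter(edited_seq, params),
               base_seq, edited_seq, alpha = alpha, label = label)
}

#' Analyze a batch of variants against a reference promoter
#'
#' Each variant row is applied to the reference sequence independently and
#' analyzed as in [run_pair()]. Row order is preserved; per-row failures
#' are reported in the `error` column without aborting the batch.
#'
#' @param reference a `promoter_seq` (or DNA text): the ancestral promoter
#' @param variants a data.frame or TSV path with columns `label`,
#'   `position`, `ref`, `alt` and optionally `kind` and `gene`; or with a
#'   `notation` column of inline variant notations
#' @param params a `tbp_parameters` object
#' @param alpha significance threshold
#' @return a list with `records` (one row per variant) and `summary`
#'   (counts per decision class and error count)
#' @export
run_batch <- function(reference, variants,
                      params = load_default_parameters(), alpha = 0.05) {
  reference <- promoter_sequence(reference)
  if (is.character(variants) && length(variants) == 1L) {
    variants <- utils::read.delim(variants, comment.char = "#",
                                  stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(variants))
  anc_est <- if (nrow(variants) > 0L) scan_promoter(reference, params)
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    rw <- variants[i, , drop = FALSE]
    gene <- if ("gene" %in% names(variants)) rw$gene else NA_character_
    rows[[i]] <- tryCatch({
      v <- if ("notation" %in% names(variants) &&
               !("position" %in% names(variants))) {
        parse_variant(rw$notation,
                      label = if ("label" %in% names(variants)) rw$label
                              else rw$notation)
      } else {
        variant_spec(rw$position, rw$ref, rw$alt,
                     kind = if ("kind" %in% names(variants)) rw$kind,
                     label = if ("label" %in% names(variants)) rw$label)
      }
      minor <- withCallingHandlers(
        apply_variant(reference, v),
        warning = function(w) invokeRestart("muffleWarning"))
      .pair_record(anc_est, scan_promoter(minor, params),
                   reference, minor, alpha = alpha,
                   label = v$label %||% NA_character_, gene = gene,
                   notation = if ("notation" %in% names(variants))
                                rw$notation else NA_character_)
    }, error = function(e) {
      .empty_record(label = if ("label" %in% names(variants)) rw$label
                            else NA_character_,
                    gene = gene,
                    notation = if ("notation" %in% names(variants))
                                 rw$notation else NA_character_,
                    error = conditionMessage(e))
    })
  }
  records <- if (length(rows)) do.call(rbind, rows) else .empty_record()[0, ]
  decisions <- factor(records$decision,
                      levels = c("excess", "deficiency", "norm"))
  summary <- c(as.list(table(decisions)),
               list(n = nrow(records), n_errors = sum(!is.na(records$error))))
  list(records = records, summary = summary)
}

#' Write a batch report as TSV with a full-precision JSON sidecar
#'
#' @param records a record data.frame (from [run_pair()]/[run_batch()])
#' @param path TSV output path; the JSON sidecar is written next to it with
#'   extension `.json`
#' @param params the parameter set used (its checksum is logged into the
#'   sidecar for traceability)
#' @return `path`, invisibly
#' @export
write_report <- function(records, path, params = NULL) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(parameter_checksum = if (!is.null(params)) parameter_checksum(params)
                              else NA,
         records = records),
    sidecar, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Fetch a promoter sequence from the UCSC genome API (network helper)
#'
#' Downloads the `length` bp immediately upstream of a TSS given explicit
#' genomic coordinates, strand-corrected so the returned sequence reads
#' toward the TSS. Purely optional: every analysis path in the package
#' accepts local sequences, and this helper fails softly without network
#' access. Transcript-identifier resolution is not provided; look up the
#' TSS coordinate in a genome browser and pass it here.
#'
#' @param chrom chromosome name (e.g. `"chr2"`)
#' @param tss 1-based genomic coordinate of the TSS base
#' @param strand `"+"` or `"-"`
#' @param genome UCSC genome tag (default `"hg19"`)
#' @param length promoter length in bp (default 90)
#' @param cache_dir optional directory; responses are cached as FASTA and
#'   reused on identical queries
#' @return a `promoter_seq`
#' @export
fetch_promoter <- function(chrom, tss, strand = c("+", "-"),
                           genome = "hg19", length = 90L,
                           cache_dir = NULL) {
  strand <- match.arg(strand)
  tss <- as.numeric(tss)
  stopifnot(is.character(chrom), base::length(chrom) == 1L, is.finite(tss))
  length <- as.integer(length)
  key <- sprintf("%s_%s_%.0f_%s_%d", genome, chrom, tss, strand, length)
  if (!is.null(cache_dir)) {
    cached <- file.path(cache_dir, paste0(key, ".fa"))
    if (file.exists(cached)) {
      return(read_promoter_sequences(cached)[[1]])
    }
  }
  # UCSC API uses 0-based half-open coordinates
  if (strand == "+") {
    start0 <- tss - 1 - length
    end0 <- tss - 1
  } else {
    start0 <- tss
    end0 <- tss + length
  }
  url <- sprintf(
    "https://api.genome.ucsc.edu/getData/sequence?genome=%s;chrom=%s;start=%.0f;end=%.0f",
    genome, chrom, start0, end0)
  resp <- tryCatch(jsonlite::fromJSON(url), error = function(e) {
    stop("promoter fetch failed (network or lookup error): ",
         conditionMessage(e), call. = FALSE)
  })
  bases <- toupper(resp$dna)
  if (is.null(bases) || !nzchar(bases)) {
    stop("promoter fetch returned no sequence for ", key, call. = FALSE)
  }
  if (strand == "-") bases <- .revcomp_string(bases)
  out <- promoter_sequence(bases, label = key)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    write_promoter_fasta(out, file.path(cache_dir, paste0(key, ".fa")))
  }
  out
}
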