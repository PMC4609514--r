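# Shared test helpers: one cached parameter load, seeded random DNA, an
# independent reverse complement, and a tiny fake affinity estimate for
# comparator arithmetic tests.

PARAMS <- tbpaffinity::load_default_parameters()

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_window <- function() rand_dna(26L)

# deliberately different mechanics from the package's .revcomp_string
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

fake_estimate <- function(minus_ln_kd, delta) {
  structure(list(minus_ln_kd = minus_ln_kd, delta = delta,
                 kd_molar = exp(-minus_ln_kd), best = NULL, label = NULL),
            class = "affinity_estimate")
}
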