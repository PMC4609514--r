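# tbpaffinity

Predicts the binding affinity of the TATA-binding protein (TBP) for
core-promoter DNA and scores regulatory promoter variants by comparing the
affinity of two alleles.

## The model

TBP binding is approximated as a three-step process — nonspecific
**sliding** along the double helix, **stopping** at a TATA box, and
**bending** the DNA — combined into a single affinity estimate for a
26-bp window:

    -ln KD = 10.9 - 0.2 * (ln K_SLIDE + ln K_STOP + ln K_BEND)

- *Sliding*: mean, over all 24 placements of a 15-bp site in the window
  (12 offsets x 2 orientations), of
  `0.8*[TA count, 3' half] - 3.4*[mean minor-groove width, center] - 35.1`.
- *Stopping*: the maximal score of the Bucher (1990) TATA-box
  position-weight matrix over the same placements, read as `-ln K_STOP`.
- *Bending*: mean over both strands of the best-placed site of
  `0.9*[WR count, flanks] + 2.5*[TV count, core] + 14.4`,
  with WR = {TA, AA, TG, AG} and TV = {TA, TC, TG}.

A promoter (positions −90…−1 relative to the transcription start site) is
scanned at window centers −70…−20 and the maximum −ln KD is reported with
an uncertainty δ: the standard deviation of −ln KD over all 78 single-base
substitutions of the winning window. Two alleles are compared with
`Z = |Δ(-ln KD)| / sqrt(δ_a² + δ_b²)`; a significant affinity gain for the
minor allele is called **excess** (predicted overexpression, ↑), a
significant loss **deficiency** (↓), anything else **norm** (=).

See the vignette (`vignettes/tbp-affinity-model.Rmd`) for the exact
conventions, parameter provenance, and limitations — in particular, with
the packaged parameter tables only *directions* and *Z comparisons* are
meaningful, not absolute nanomolar KD values.

## Worked example

The promoter variant rs1143627 (IL1B, −31c>t) converts a noncanonical
CATAAAA core into a canonical TATAAAA box. Embedding its published 21-bp
context into a neutral scaffold:

```r
library(tbpaffinity)
params <- load_default_parameters()
bench  <- tbp_snp_benchmark()
fx  <- table_context_fixture(bench[bench$label == "rs1143627", ])
anc <- scan_promoter(fx$ancestral, params)
min_ <- scan_promoter(fx$minor, params)
anc
#> affinity_estimate 'rs1143627_ancestral': -ln(KD) = 6.2715 +/- 0.4656 (KD = 0.00189 M), best window center -28 (+)
min_
#> affinity_estimate 'rs1143627_ancestral|rs1143627': -ln(KD) = 7.0989 +/- 0.4780 (KD = 0.000826 M), best window center -29 (+)
compare_alleles(anc, min_)
#> tbp_comparison: ancestral -ln(KD) 6.2715 +/- 0.4656 vs minor 7.0989 +/- 0.4780
#>   Z = 1.24, alpha >0.05 (p = 0.78498) -> norm (=)
```

The affinity rises (+0.83 ln units, the reported ↑ direction); in the
bare 21-bp context the change is not significant against δ — significance
magnitudes need the true genomic flanks.

Batch analysis against one reference promoter:

```r
prom <- generate_promoter(fixture_spec(seed = 7, embedded_motif = "TATAAAAG",
                                       motif_position = -31))
out <- run_batch(prom, data.frame(notation = c("-31t>c", "-28a>c", "del-29t")))
out$records[, c("label", "arrow", "z", "alpha_bucket", "decision")]
#>     label arrow    z alpha_bucket   decision
#> 1  -31t>c     = 1.06        >0.05       norm
#> 2  -28a>c     ↓ 2.74        <0.01 deficiency
#> 3 del-29t     ↓ 2.61        <0.01 deficiency
```

`write_report()` writes such records as TSV with a full-precision JSON
sidecar carrying the `parameter_checksum()` of the tables used. A thin
command-line front end with `pair`, `batch` and `fixture` subcommands is
installed at `system.file("cli", "tbpaffinity.R", package = "tbpaffinity")`.

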