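# SYNTHETIC representative B-DNA minor-groove widths (Angstrom) per
# dinucleotide step. Constructed for this package following the trend of
# crystallographic and DNA-shape surveys: A-tract steps narrow the minor
# groove (~3.4-4.0 A), TpA and G/C-rich steps widen it (~5.0-6.0 A),
# genome-average ~5 A. Strand-symmetric by construction (width of a step
# equals the width of its reverse complement). Not a transcription of any
# single published table; replace via the parameter config to use one.
dinucleotide	width_angstrom
AA	3.8
AC	4.3
AG	4.6
AT	3.4
CA	5.5
CC	5.0
CG	5.6
CT	4.6
GA	4.8
GC	5.2
GG	5.0
GT	4.3
TA	5.3
TC	4.8
TG	5.5
TT	3.8
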