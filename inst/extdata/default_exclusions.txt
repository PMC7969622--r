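# Default false-acronym exclusion list: laboratory/measurement acronyms that
# collide with (or are easily mistaken for) HGNC-style tokens in abstracts.
# One token per line; '#' starts a comment.
CBF
TEER
LDH
AOP
COPD
PCR
ELISA
ANOVA
RIN
ISO
MS
QC
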