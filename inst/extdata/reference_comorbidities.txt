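# Curated reference list of major well-established diabetic complications
# (cardiovascular, cerebrovascular, peripheral-vascular, renal and bone
# infection codes agreed on by multiple hand-curated literature sources).
# One 3-character ICD-10 code per line; '#' starts a comment.
G45
I10
I20
I21
I24
I47
I50
I60
I61
I62
I65
I66
I67
I70
I71
I72
I73
I74
M86
N17
N18
N19
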