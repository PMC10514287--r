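# Seven physicochemical groups: one group of concatenated residue letters
# per line. The groups must partition the 20 standard amino acids.
AVIL
STNQ
RHK
DE
FYW
CGP
M
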