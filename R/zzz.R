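.datatable.aware <- TRUE

# The 20 standard amino-acid letters, alphabetical.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

SEQ_TYPES <- c("cTP", "mTP", "SP", "AMP")

utils::globalVariables(c(".", ".I", ".N", "row", "value"))
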