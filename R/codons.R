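# Standard genetic code, cached from Biostrings at package build time.
# Codon -> single-letter amino acid; stops are "*".
GENCODE <- Biostrings::GENETIC_CODE
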