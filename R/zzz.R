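#' @importFrom data.table := .N
NULL

utils::globalVariables(c(".N", "i", "d", "pos", "cluster", "kmer"))
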