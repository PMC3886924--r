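# Shared small-scale fixture builders (all generated in code at test time).

# A read set with uniform coverage from a plain genome string.
uniform_reads <- function(seq, depth = 30, error_rate = 0, seed = 1,
                          sample_id = "S1") {
  simulate_paired_reads(seq, depth, error_rate = error_rate, seed = seed,
                        sample_id = sample_id)
}

# A pair of read sets from two genomes (the minimal bubble-calling input).
two_sample_reads <- function(seq1, seq2, depth = 30, seed = 1,
                             error_rate = 0) {
  list(A = uniform_reads(seq1, depth, error_rate, seed, "A"),
       B = uniform_reads(seq2, depth, error_rate, seed + 1, "B"))
}

# Plant a single SNP at a (1-based) position of a sequence.
plant_snp <- function(seq, pos, alt = NULL) {
  refb <- substring(seq, pos, pos)
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  paste0(substring(seq, 1, pos - 1), alt, substring(seq, pos + 1))
}

# Delete `len` bases starting at 1-based position `pos`.
plant_del <- function(seq, pos, len) {
  paste0(substring(seq, 1, pos - 1), substring(seq, pos + len))
}
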