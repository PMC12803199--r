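# Small in-code fixtures shared across test files.

fixture_heads <- function() {
  heads_from_rows(
    name = c("glycine", "ornithine", "glutamic acid"),
    smiles = c("NCC(=O)O", "NCCCC(N)C(=O)O", "NC(CCC(=O)O)C(=O)O"),
    diagnostic_fragments = c(NA, "70.0651;115.0866", "84.04;102.06;130.05")
  )
}

fixture_tails <- function() {
  tails_from_rows(
    name = tail_name(c(4, 12, 14), c(0, 0, 0)),
    smiles = vapply(c(4, 12, 14), hydroxy_tail_smiles, character(1))
  )
}

# a deterministic toy spectrum whose peaks are explicit
toy_spectrum <- function(mz, intensity, precursor = 300) {
  new_spectrum(mz, intensity, precursor_mz = precursor)
}
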