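# Formula values below were cross-checked against an independent
# cheminformatics toolkit before being frozen.
test_that("SMILES parsing recovers elemental formulas", {
  frozen <- c(
    "NCC(=O)O" = "C2H5NO2",                     # glycine
    "NCCCC(N)C(=O)O" = "C5H12N2O2",             # ornithine
    "NC(Cc1c[nH]c2ccccc12)C(=O)O" = "C11H12N2O2",  # tryptophan
    "NCCc1c[nH]cn1" = "C5H9N3",                 # histamine
    "NCCS(=O)(=O)O" = "C2H7NO3S",               # taurine
    "NC(CCCNC(=N)N)C(=O)O" = "C6H14N4O2",       # arginine
    "NC(CCCNC(N)=O)C(=O)O" = "C6H13N3O3",       # citrulline
    "NCCc1ccc(O)c(O)c1" = "C8H11NO2",           # dopamine
    "CCCCCCCCCC(O)CC(=O)O" = "C12H24O3"         # 3-hydroxylauric acid
  )
  for (smi in names(frozen)) {
    expect_identical(format_formula(mol_formula(smi)), unname(frozen[smi]),
                     info = smi)
  }
})

test_that("primary-amine detection follows the conjugation-site rule", {
  expect_length(find_primary_amines("NCC(=O)O"), 1)          # glycine
  expect_length(find_primary_amines("NCCCC(N)C(=O)O"), 2)    # ornithine: alpha + delta
  expect_length(find_primary_amines("NCCCCC(N)C(=O)O"), 2)   # lysine
  # amide NH2 (glutamine side chain) is not a site
  expect_length(find_primary_amines("NC(CCC(N)=O)C(=O)O"), 1)
  # guanidino NH2 (arginine) is not a site
  expect_length(find_primary_amines("NC(CCCNC(=N)N)C(=O)O"), 1)
  # aromatic ring NH (histamine imidazole) is not a site
  expect_length(find_primary_amines("NCCc1c[nH]cn1"), 1)
  # secondary amines only (proline) -> no site
  expect_length(find_primary_amines("OC(=O)C1CCCN1"), 0)
})

test_that("head-table parsing validates rows and preserves order", {
  heads <- fixture_heads()
  expect_identical(heads$name, c("glycine", "ornithine", "glutamic acid"))
  expect_identical(heads$n_primary_amines, c(1L, 2L, 1L))
  expect_identical(heads$diagnostic_fragments[[1]], numeric(0))
  expect_equal(heads$diagnostic_fragments[[3]], c(84.04, 102.06, 130.05))
  expect_error(heads_from_rows("bad", "C1CC"), "row 1")
  expect_error(heads_from_rows("proline", "OC(=O)C1CCCN1"), "no primary amine")
  # TSV round trip through the file reader
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    name = c("glycine", "ornithine"),
    smiles = c("NCC(=O)O", "NCCCC(N)C(=O)O"),
    diagnostic_fragments = c(NA, "70.065;115.087")), tf)
  h2 <- parse_head_table(tf)
  expect_identical(h2$n_primary_amines, c(1L, 2L))
  expect_equal(h2$diagnostic_fragments[[2]], c(70.065, 115.087))
})

test_that("tail names round-trip and structures are validated", {
  tails <- fixture_tails()
  expect_identical(tails$carbons, c(4L, 12L, 14L))
  expect_identical(tails$formula_str, c("C4H8O3", "C12H24O3", "C14H28O3"))
  pn <- parse_tail_name(tail_name(c(3, 18, 10), c(0, 0, 1)))
  expect_identical(pn$carbons, c(3L, 18L, 10L))
  expect_identical(pn$unsaturations, c(0L, 0L, 1L))
  expect_error(parse_tail_name("C12:0"), "unparseable")
  # unsaturated tail formula CnH(2n-2)O3
  expect_identical(format_formula(mol_formula(hydroxy_tail_smiles(10, 1))),
                   "C10H18O3")
  # name/structure mismatch is rejected
  expect_error(tails_from_rows("3OH-C12:0", hydroxy_tail_smiles(10, 0)),
               "inconsistent")
})

test_that("graph-to-SMILES writing preserves composition from any root", {
  for (smi in c("NCC(=O)O", "NC(Cc1c[nH]c2ccccc12)C(=O)O",
                "NCCc1ccc(O)c(O)c1", "NCCS(=O)(=O)O", "NCCCCNC(=N)N")) {
    mol <- parse_smiles(smi)
    for (root in seq_len(nrow(mol$atoms))) {
      out <- write_smiles(mol, root)
      expect_identical(format_formula(mol_formula(out)),
                       format_formula(mol_formula(smi)),
                       info = paste(smi, "root", root))
    }
  }
})
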