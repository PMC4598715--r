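test_that("peptide extension does amide mass bookkeeping exactly", {
  x <- extend_peptide(NULL, "gly", table = MONOMERS)
  x <- extend_peptide(x, "gly", table = MONOMERS)
  expect_equal(structure_mass(x), 132.0535, tolerance = 1e-4)

  y <- extend_peptide(extend_peptide(NULL, "gly", table = MONOMERS),
                      "gly", n_methylated = TRUE, table = MONOMERS)
  expect_equal(structure_mass(y), 146.0691, tolerance = 1e-4)

  z <- extend_peptide(NULL, "ser", table = MONOMERS)
  expect_equal(structure_mass(z), MONOMERS$mass[MONOMERS$name == "ser"])
  expect_error(extend_peptide(z, "mal", table = MONOMERS), "amino_acid")
})

test_that("ketide extension simulates the reductive loop states", {
  start <- napminer:::chain_start_acyl("acetyl", MONOMERS)
  keto <- extend_ketide(start, "mal", character(), MONOMERS)
  # acetoacetic acid C4H6O3
  expect_equal(structure_mass(keto), formula_mass("C4H6O3"), tolerance = 1e-6)
  expect_match(structure_smiles(keto), "CC\\(=O\\)CC\\(=O\\)O")

  kr <- extend_ketide(start, "mmal", "KR", MONOMERS)
  expect_equal(structure_mass(kr), formula_mass("C5H10O3"), tolerance = 1e-6)
  expect_match(structure_smiles(kr), "C\\(O\\)")   # beta-hydroxyl present
  expect_match(structure_smiles(kr), "C\\(C\\)")   # alpha-methyl present

  full <- extend_ketide(start, "mal", c("KR", "DH", "ER"), MONOMERS)
  expect_equal(structure_mass(full), formula_mass("C4H8O2"), tolerance = 1e-6)

  expect_error(extend_ketide(start, "mal", "DH", MONOMERS), "unreachable")
  expect_error(extend_ketide(start, "mal", "ER", MONOMERS), "requires")
})

test_that("starters attach as N-acyl amides or open R-sites", {
  pep <- build_from_tokens(c("ser", "gly"), MONOMERS)
  dec <- attach_starter(pep, "c10", MONOMERS)
  expect_equal(structure_mass(dec),
               structure_mass(pep) + formula_mass("C10H20O2") - MASS_H2O,
               tolerance = 1e-6)
  expect_match(structure_smiles(dec), "^CCCCCCCCCC\\(=O\\)N")

  bhm <- attach_starter(pep, "c14_oh", MONOMERS)
  expect_match(structure_smiles(bhm), "C\\(O\\)CC\\(=O\\)N")

  open <- attach_starter(pep, NULL, MONOMERS)
  expect_true(is.na(structure_mass(open)))
  expect_match(structure_smiles(open), "\\[\\*\\]", fixed = FALSE)
  expect_error(attach_starter(dec, "c10", MONOMERS), "already")
})

test_that("build_scaffold applies modules co-linearly and excludes trans", {
  mods <- data.frame(
    index = c(1, 2, 3, NA), kind = c("NRPS", "PKS", "NRPS", "NRPS"),
    substrate = c("ser", "mmal", "gly", "asn"),
    reductive_state = c("", "KR", "", ""),
    n_methylated = FALSE, is_starter = FALSE,
    trans_acting = c(FALSE, FALSE, FALSE, TRUE), orf_ids = "g",
    stringsAsFactors = FALSE)
  expect_message(x <- build_scaffold(mods, MONOMERS), "trans-acting")
  # Ser + (2-methyl-3-hydroxy ketide) + Gly; asn NOT included
  expect_equal(structure_mass(x),
               sum(MONOMERS$mass[match(c("ser", "mmal", "gly"), MONOMERS$name)]) +
                 napminer:::.KR_DELTA - 2 * MASS_H2O,
               tolerance = 1e-6)
  smi <- structure_smiles(x)
  expect_match(smi, "C\\(O\\)C\\(C\\)C\\(=O\\)N")  # hydroxy-methyl ketide into amide
  expect_false(grepl("CC\\(N\\)=O", smi))          # no asn side chain
})

test_that("structure masses agree with an independent SMILES mass oracle", {
  cases <- list(
    c("ser", "val", "thr"),
    c("c12_oh", "thr", "orn", "gly"),
    c("acetyl", "mmal(KR)", "mal", "mmal(KR,DH)"),
    c("prop", "mmal(KR)", "mmal", "mal(KR,DH,ER)", "gly"))
  for (tok in cases) {
    x <- build_from_tokens(tok, MONOMERS)
    expect_equal(structure_mass(x), smiles_exact_mass(structure_smiles(x)),
                 tolerance = 1e-3)
  }
  # macrocycle and glycoside too
  m <- build_from_tokens(c("c12_oh", "ser", "dab", "clthr"), MONOMERS)
  m <- close_macrocycle(m, "lactone", 2)
  expect_equal(structure_mass(m), smiles_exact_mass(structure_smiles(m)),
               tolerance = 1e-3)
  g <- attach_sugar(build_from_tokens(c("thr", "ser"), MONOMERS),
                    SUGARS[SUGARS$name == "mycaminose", ])
  expect_equal(structure_mass(g), smiles_exact_mass(structure_smiles(g)),
               tolerance = 1e-3)
})

test_that("mass additivity holds with exact modification deltas", {
  base <- build_from_tokens(c("ser", "gly", "thr"), MONOMERS)
  nme <- extend_peptide(build_from_tokens(c("ser", "gly"), MONOMERS), "thr",
                        n_methylated = TRUE, table = MONOMERS)
  expect_equal(structure_mass(nme) - structure_mass(base), 14.01565,
               tolerance = 1e-5)
  st <- napminer:::chain_start_acyl("acetyl", MONOMERS)
  keto <- extend_ketide(st, "mal", character(), MONOMERS)
  kr <- extend_ketide(st, "mal", "KR", MONOMERS)
  dh <- extend_ketide(st, "mal", c("KR", "DH"), MONOMERS)
  er <- extend_ketide(st, "mal", c("KR", "DH", "ER"), MONOMERS)
  expect_equal(structure_mass(kr) - structure_mass(keto), 2.01565,
               tolerance = 1e-5)
  expect_equal(structure_mass(dh) - structure_mass(kr), -18.010565,
               tolerance = 1e-5)
  expect_equal(structure_mass(er) - structure_mass(dh), 2.01565,
               tolerance = 1e-5)
})

test_that("emission is deterministic and round-trips through canonical SMILES", {
  x1 <- build_from_tokens(c("ser", "val", "phe"), MONOMERS)
  x2 <- build_from_tokens(c("ser", "val", "phe"), MONOMERS)
  e1 <- emit_structure(x1); e2 <- emit_structure(x2)
  expect_identical(e1$smiles, e2$smiles)
  expect_match(e1$molfile, "V2000")
  # canonical SMILES is a fixed point of canonicalization
  expect_identical(smiles_canonical(e1$smiles), e1$smiles)
  expect_identical(smiles_canonical("NCC(=O)NCC(O)=O"),
                   smiles_canonical("OC(=O)CNC(=O)CN"))
})

test_that("monomer table masses match their formulas and SMILES templates", {
  # spot-check template chemistry against OpenBabel for marker-bearing rows
  spots <- c("ser", "thr", "tyr", "orn", "bohasp", "clthr", "dhb", "pro",
             "c12_oh", "c16_ohoh", "orn_noh_ac")
  for (nm in spots) {
    x <- build_from_tokens(nm, MONOMERS)
    expect_equal(structure_mass(x), smiles_exact_mass(structure_smiles(x)),
                 tolerance = 1e-3, label = nm)
  }
})
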