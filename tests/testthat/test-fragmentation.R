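test_that("diglycine amide cleavage yields the ketene/free pair", {
  x <- build_from_tokens(c("gly", "gly"), MONOMERS)
  fr <- enumerate_fragments(x, cleavage_settings(amide = c(1, 1)))
  expect_equal(sort(round(fr$neutral_mass, 4)), c(57.0215, 75.0320))
  expect_equal(sum(fr$neutral_mass), structure_mass(x), tolerance = 1e-6)
  # fragment substructure SMILES carry the same masses
  ok <- !is.na(fr$substructure_smiles)
  expect_true(all(ok))
  expect_equal(sort(smiles_exact_mass(fr$substructure_smiles)),
               sort(fr$neutral_mass), tolerance = 1e-3)
})

test_that("single-cleavage mass conservation holds on random structures", {
  set.seed(21)
  aa <- MONOMERS$name[MONOMERS$class == "amino_acid"]
  for (trial in 1:12) {
    toks <- sample(aa, sample(3:7, 1), replace = TRUE)
    x <- build_from_tokens(toks, MONOMERS)
    parent <- structure_mass(x)
    fr <- enumerate_fragments(x, cleavage_settings(amide = c(1, 1)))
    fr <- fr[fr$side %in% c("n_terminal_like", "c_terminal_like"), ]
    # each cleavage produced exactly one n- and one c-side fragment; pair
    # them by shared provenance and check the sums
    for (bond in unique(fr$cleaved_bonds)) {
      pair <- fr[vapply(strsplit(fr$cleaved_bonds, " | ", fixed = TRUE),
                        function(p) bond %in% p, logical(1)), ]
      # dedup may merge several bonds into one mass; conservation checked
      # via complement instead
      for (i in seq_len(nrow(pair))) {
        comp <- parent - pair$neutral_mass[i]
        expect_true(any(abs(fr$neutral_mass - comp) < 1e-6),
                    label = paste(toks, collapse = "-"))
      }
    }
  }
})

test_that("linear-peptide amide fragments equal the classical b/y series", {
  set.seed(5)
  aa <- setdiff(MONOMERS$name[MONOMERS$class == "amino_acid"], "X")
  for (trial in 1:10) {
    toks <- sample(aa, sample(2:6, 1), replace = TRUE)
    x <- build_from_tokens(toks, MONOMERS)
    fr <- enumerate_fragments(x, cleavage_settings(amide = c(1, 1)))
    expect_equal(sort(unique(round(fr$neutral_mass, 5))),
                 sort(unique(round(oracle_by_series(toks), 5))),
                 label = paste(toks, collapse = "-"))
  }
})

test_that("ring opening of a macrocycle conserves the parent mass", {
  p <- build_from_tokens(c("ser", "gly", "ala", "val", "leu"), MONOMERS)
  cyc <- apply_cyclization(p, "lactam@1")
  fr <- enumerate_fragments(cyc, cleavage_settings(amide = c(1, 1)))
  expect_equal(unique(fr$side), "ring_opened_full")
  expect_true(all(abs(fr$neutral_mass - structure_mass(cyc)) < 1e-9))
  # two cleavages of the ring give complementary pairs again
  fr2 <- enumerate_fragments(cyc, cleavage_settings(amide = c(2, 2)))
  sums <- outer(fr2$neutral_mass, fr2$neutral_mass, "+")
  expect_true(any(abs(sums - structure_mass(cyc)) < 1e-6))
})

test_that("neutral losses are applied within budgets", {
  x <- build_from_tokens(c("ser", "gly"), MONOMERS)
  fr <- enumerate_fragments(x, cleavage_settings(water_loss = c(0, 1)))
  m <- structure_mass(x)
  expect_true(any(abs(fr$neutral_mass - m) < 1e-9))
  expect_true(any(abs(fr$neutral_mass - (m - 18.010565)) < 1e-6))
  fr2 <- enumerate_fragments(x, cleavage_settings(water_loss = c(0, 1),
                                                  ammonia_loss = c(0, 1)))
  expect_true(any(abs(fr2$neutral_mass - (m - 18.010565 - 17.026549)) < 1e-5))
})

test_that("widening any budget never removes fragment masses", {
  x <- build_from_tokens(c("thr", "ser", "val", "gly"), MONOMERS)
  narrow <- enumerate_fragments(x, cleavage_settings(amide = c(0, 1)))
  wide <- enumerate_fragments(x, cleavage_settings(amide = c(0, 2),
                                                   water_loss = c(0, 1)))
  for (m in narrow$neutral_mass) {
    expect_true(any(abs(wide$neutral_mass - m) < 1e-9))
  }
})

test_that("cleavable bond detection types amides, esters and glycosides", {
  x <- build_from_tokens(c("gly", "gly"), MONOMERS)
  b <- detect_cleavable_bonds(x)
  expect_equal(nrow(b), 1)
  expect_equal(b$type, "amide")

  # macrolactone with one sugar: 1 ester + 1 glycosidic (+ backbone amides)
  m <- build_from_tokens(c("c10", "ser", "thr", "gly"), MONOMERS)
  m <- close_macrocycle(m, "lactone", 2)
  m <- attach_sugar(m, SUGARS[SUGARS$name == "olivose", ])
  bm <- detect_cleavable_bonds(m)
  expect_equal(sum(bm$type == "ester"), 1)
  expect_equal(sum(bm$type == "glycosidic"), 1)
  expect_true(bm$in_ring[bm$type == "ester"])

  # a pure polyketide chain has no cleavable heteroatom backbone bonds
  pk <- build_from_tokens(c("acetyl", "mal", "mal"), MONOMERS)
  expect_equal(nrow(detect_cleavable_bonds(pk)), 0)
  fr <- enumerate_fragments(pk, cleavage_settings(water_loss = c(0, 1)))
  expect_equal(nrow(fr), 2)  # parent and its water loss only
})

test_that("glycosidic cleavage is gated on the oxan-2-ol ring", {
  g <- attach_sugar(build_from_tokens(c("thr", "gly"), MONOMERS),
                    SUGARS[SUGARS$name == "mycaminose", ])
  b <- detect_cleavable_bonds(g)
  expect_true("glycosidic" %in% b$type)
  fr <- enumerate_fragments(g, cleavage_settings(glycosidic = c(1, 1)))
  # aglycone keeps its hydroxyl; sugar leaves as the anhydro species
  agly <- structure_mass(build_from_tokens(c("thr", "gly"), MONOMERS))
  expect_true(any(abs(fr$neutral_mass - agly) < 1e-6))
  expect_true(any(abs(fr$neutral_mass -
                        (SUGARS$mass[SUGARS$name == "mycaminose"] - MASS_H2O)) < 1e-6))
})

test_that("ionization arithmetic matches the proton-mass convention", {
  fr <- data.frame(neutral_mass = c(999.0, 132.0535), side = "parent",
                   n_cleavages = 0L, cleaved_bonds = "none", losses = "",
                   substructure_smiles = NA, stringsAsFactors = FALSE)
  ions <- ionize(fr, charges = c(1, 2))
  z1 <- ions[ions$charge == 1, ]
  expect_equal(z1$mz[abs(z1$neutral_mass - 999) < 1e-6], 1000.00728,
               tolerance = 1e-5)
  expect_equal(z1$mz[abs(z1$neutral_mass - 132.0535) < 1e-4], 133.0608,
               tolerance = 1e-4)
  z2 <- ions[ions$charge == 2, ]
  expect_equal(nrow(z2), 1)  # only the species above the 2+ mass floor
  expect_equal(z2$mz, 500.50364, tolerance = 1e-5)
})

test_that("unsatisfiable channel minima yield no fragments", {
  x <- build_from_tokens(c("gly", "gly"), MONOMERS)
  fr <- enumerate_fragments(x, cleavage_settings(ester = c(1, 1)))
  expect_equal(nrow(fr), 0)
  expect_error(cleavage_settings(amide = c(2, 1)), "min")
  expect_error(cleavage_settings(amide = c(0, 4), ester = c(0, 4)), "bound")
})
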