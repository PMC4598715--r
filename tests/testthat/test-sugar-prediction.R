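gt_call <- function(class = "DEOXYSUGAR", hex = NA_character_) {
  data.frame(orf_id = "gt", substrate_class = class, hexose_identity = hex,
             top_hit = "x", top_score = 50, stringsAsFactors = FALSE)
}

test_that("sugar slot counting subtracts hexose glycosyltransferases", {
  expect_equal(count_sugar_slots(rbind(gt_call(), gt_call())), 2)
  expect_equal(count_sugar_slots(rbind(gt_call(), gt_call(),
                                       gt_call("HEXOSE", "mannose"))), 2)
  expect_equal(count_sugar_slots(gt_call()[0, ]), 0)
})

test_that("combination scoring uses set semantics over family names", {
  toy <- data.frame(name = c("S1", "S2", "S3"), sugar_class = "deoxyhexose",
                    formula = "C6H12O4", attach_smiles = "C1OC(C)C(O)C(O)C1",
                    mass = 148, stringsAsFactors = FALSE)
  toy$gene_families <- list(c("g1", "g2"), c("g2", "g3"), "g4")
  cl <- c("g1", "g2", "g3")
  expect_equal(unname(score_combination(c("S1", "S3"), cl, toy)), c(1, 1))
  expect_equal(unname(score_combination(c("S1", "S2"), cl, toy)), c(0, 0))
  expect_equal(unname(score_combination(c("S1", "S1"), c("g1", "g2"), toy)),
               c(0, 0))
  # permutation invariance
  expect_equal(score_combination(c("S2", "S1"), cl, toy),
               score_combination(c("S1", "S2"), cl, toy))
})

test_that("prediction matches the exhaustive oracle and handles n = 0", {
  toy <- data.frame(name = c("S1", "S2", "S3"), sugar_class = "deoxyhexose",
                    formula = "C6H12O4", attach_smiles = "C1OC(C)C(O)C(O)C1",
                    mass = 148, stringsAsFactors = FALSE)
  toy$gene_families <- list(c("g1", "g2"), c("g2", "g3"), "g4")
  got <- predict_sugars(c("g1", "g2", "g3"), rbind(gt_call(), gt_call()), toy)
  expect_equal(sort(got$sugars), c("S1", "S2"))
  expect_equal(got$missing_genes + got$extra_genes, 0)

  none <- predict_sugars(c("g1"), gt_call()[0, ], toy)
  expect_equal(none$n_slots, 0)
  expect_equal(none$sugars, character())

  expect_error(predict_sugars(c("g1"), do.call(rbind, replicate(6, gt_call(),
                                                                simplify = FALSE)),
                              toy, max_slots = 4),
               "bounded")
})

test_that("prediction equals brute force over 100 random toy codes", {
  trials <- 0
  for (seed in 1:100) {
    code <- toy_sugar_code(n_sugars = sample(3:10, 1), n_fams = sample(4:8, 1),
                           seed = seed)
    set.seed(seed + 1000)
    n <- sample(1:3, 1)
    fams <- sprintf("g%02d", sample(1:8, sample(2:6, 1)))
    gt <- do.call(rbind, replicate(n, gt_call(), simplify = FALSE))
    got <- predict_sugars(fams, gt, code)
    want <- oracle_predict_sugars(fams, n, code)
    expect_equal(got$missing_genes + got$extra_genes, want$obj[1],
                 label = paste("seed", seed))
    expect_equal(got$missing_genes, want$obj[2], label = paste("seed", seed))
    expect_equal(sort(got$sugars), sort(want$best),
                 label = paste("seed", seed))
    # objective monotonicity: adding a gene from the chosen pathways never
    # worsens the chosen combination's objective
    chosen_fams <- unique(unlist(code$gene_families[match(got$sugars,
                                                          code$name)]))
    extra_gene <- setdiff(chosen_fams, fams)
    if (length(extra_gene)) {
      before <- sum(score_combination(got$sugars, fams, code))
      after <- sum(score_combination(got$sugars, c(fams, extra_gene[1]), code))
      expect_lte(after, before)
    }
    trials <- trials + 1
  }
  expect_equal(trials, 100)
})

test_that("the packaged code recovers angolosamine + mycaminose/ravidosamine", {
  fams <- unique(unlist(SUGARS$gene_families[
    SUGARS$name %in% c("mycaminose", "angolosamine")]))
  gt <- rbind(gt_call(), gt_call())
  got <- predict_sugars(fams, gt, SUGARS)
  expect_equal(got$missing_genes + got$extra_genes, 0)
  in_co <- vapply(got$co_optimal, function(s) {
    "angolosamine" %in% s && any(c("mycaminose", "ravidosamine") %in% s)
  }, logical(1))
  expect_true(any(in_co))
  # every co-optimal contains angolosamine; the partner is one of the
  # genomically indistinguishable diastereomers
  expect_true(all(vapply(got$co_optimal, function(s) "angolosamine" %in% s,
                         logical(1))))
})

test_that("glycosylation site draws are seeded and exhaustive mode enumerates", {
  x <- build_from_tokens(c("ser", "thr", "tyr"), MONOMERS)  # 3 free hydroxyls
  g1 <- glycosylate(x, "mycaminose", seed = 7)
  g2 <- glycosylate(x, "mycaminose", seed = 7)
  expect_identical(compose_smiles(g1), compose_smiles(g2))

  one <- build_from_tokens(c("ser", "gly"), MONOMERS)
  d <- glycosylate(one, "rhamnose", seed = 3)
  expect_equal(structure_mass(d),
               structure_mass(one) + SUGARS$mass[SUGARS$name == "rhamnose"] -
                 MASS_H2O, tolerance = 1e-6)

  two <- build_from_tokens(c("ser", "thr"), MONOMERS)
  all_p <- glycosylate(two, c("rhamnose", "olivose"), enumerate_all = TRUE)
  expect_equal(length(all_p), 2)
  expect_false(identical(compose_smiles(all_p[[1]]), compose_smiles(all_p[[2]])))

  expect_error(glycosylate(one, c("rhamnose", "olivose")), "1")
})
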