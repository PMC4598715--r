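mk_orfs <- function(starts, ends, contig = "c1") {
  data.frame(orf_id = sprintf("g%02d", seq_along(starts)), contig_id = contig,
             start = starts, end = ends, stringsAsFactors = FALSE)
}
mk_hits <- function(orf_ids, families) {
  do.call(rbind, Map(function(o, f) hit_row(orf = o, family = f), orf_ids,
                     families))
}

test_that("greedy gap clustering splits exactly at gaps above the window", {
  orfs <- mk_orfs(c(0, 5000, 25000), c(3000, 9000, 30000))
  hits <- mk_hits(orfs$orf_id, rep("ADENYLATION", 3))
  cl <- group_into_clusters(orfs, hits, cluster_settings(10000))
  expect_equal(length(cl), 2)
  expect_equal(cl[[1]]$orf_ids, c("g01", "g02"))
  expect_equal(cl[[2]]$orf_ids, "g03")

  one <- group_into_clusters(mk_orfs(c(0, 2000, 6000), c(1500, 5000, 8000)),
                             mk_hits(sprintf("g%02d", 1:3),
                                     rep("CONDENSATION", 3)))
  expect_equal(length(one), 1)
})

test_that("protein-mode genes without coordinates form a single cluster", {
  orfs <- mk_orfs(rep(NA_integer_, 3), rep(NA_integer_, 3))
  hits <- mk_hits(orfs$orf_id, c("ADENYLATION", "CONDENSATION", "THIOLATION"))
  cl <- group_into_clusters(orfs, hits)
  expect_equal(length(cl), 1)
  expect_equal(cl[[1]]$orf_ids, orfs$orf_id)
})

test_that("clustering equals the gap-scan oracle on random gene layouts", {
  set.seed(99)
  for (trial in 1:50) {
    n <- sample(3:15, 1)
    starts <- sort(sample(0:100000, n))
    ends <- starts + sample(500:2500, n, replace = TRUE)
    gap <- sample(c(2000, 5000, 10000), 1)
    orfs <- mk_orfs(starts, ends)
    hits <- mk_hits(orfs$orf_id, rep("ADENYLATION", n))
    got <- group_into_clusters(orfs, hits, cluster_settings(gap))
    want <- oracle_partition(starts, ends, gap)
    expect_equal(length(got), length(want))
    expect_equal(lapply(got, function(c) sort(c$orf_ids)),
                 unname(lapply(want, function(ix) sort(orfs$orf_id[ix]))))
    # partition property: every gene in exactly one cluster
    all_ids <- unlist(lapply(got, `[[`, "orf_ids"))
    expect_equal(sort(all_ids), sort(orfs$orf_id))
    # refinement monotonicity: shrinking the window never merges clusters
    finer <- group_into_clusters(orfs, hits, cluster_settings(gap / 2))
    expect_gte(length(finer), length(got))
  }
})

test_that("cluster filter requires both an A/AT and a C/KS domain", {
  orfs <- mk_orfs(c(0, 2000), c(1500, 3500))
  keep_ac <- group_into_clusters(orfs, mk_hits(orfs$orf_id,
                                               c("ADENYLATION", "CONDENSATION")))
  expect_equal(length(filter_clusters(keep_ac)), 1)
  only_a <- group_into_clusters(orfs, mk_hits(orfs$orf_id,
                                              c("ADENYLATION", "ADENYLATION")))
  expect_equal(length(filter_clusters(only_a)), 0)
  pks <- group_into_clusters(orfs, mk_hits(orfs$orf_id,
                                           c("ACYLTRANSFERASE", "KETOSYNTHASE")))
  expect_equal(length(filter_clusters(pks)), 1)
})

cluster_from_recipe <- function(recipe, seed = 1) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  p <- make_cluster_fixture(recipe, td, seed = seed)
  hits <- ingest_domain_hits(p$domtbl)
  hom <- read_homology_tsv(p$homology)
  hits <- napminer:::attach_substrate_calls(hits, hom)
  coords <- utils::read.delim(p$genes)
  orfs <- data.frame(orf_id = coords$orf_id, contig_id = coords$contig_id,
                     start = coords$start, end = coords$end,
                     stringsAsFactors = FALSE)
  filter_clusters(group_into_clusters(orfs, hits))[[1]]
}

test_that("module grammar parses NRPS, PKS and N-methylation spans", {
  cl <- cluster_from_recipe("C-A(ser)-T | C-A(val)-nMT-T | TE")
  mods <- define_modules(cl)
  expect_equal(nrow(mods), 2)
  expect_equal(mods$kind, c("NRPS", "NRPS"))
  expect_equal(mods$substrate, c("ser", "val"))
  expect_equal(mods$n_methylated, c(FALSE, TRUE))

  cl <- cluster_from_recipe("KS-AT(mal)-KR-T")
  mods <- define_modules(cl)
  expect_equal(mods$kind, "PKS")
  expect_equal(mods$reductive_state, "KR")
})

test_that("starter acylation is flagged and trans A-T didomains surfaced", {
  cl <- cluster_from_recipe("C-A(ser)-T | C-A(thr)-T-TE | A(asn)-T | A(thr)-T")
  mods <- define_modules(cl)
  chain <- mods[!mods$trans_acting, ]
  trans <- mods[mods$trans_acting, ]
  expect_equal(nrow(chain), 2)
  expect_true(chain$is_starter[1])
  expect_false(any(chain$is_starter[-1]))
  expect_equal(nrow(trans), 2)
  expect_setequal(trans$substrate, c("asn", "thr"))
  expect_true(all(is.na(trans$index)))

  # an A-T initiation span without a leading C (same gene as the rest of the
  # assembly line, so not a standalone didomain) is not starter-acylated
  cl2 <- cluster_from_recipe("A(ser)-T-C-A(gly)-T-TE")
  mods2 <- define_modules(cl2)
  expect_false(any(mods2$is_starter))
  expect_equal(mods2$substrate, c("ser", "gly"))
})

test_that("module count never exceeds the thiolation count", {
  recipes <- c("C-A(ser)-T | C-A(val)-T | C-A(gly)-T",
               "C-A(ser)-T-C-A(val)-T",
               "KS-AT(mal)-T | KS-AT(mmal)-DH-KR-T",
               "C-A(ser)-T | A(asn)-T | TE")
  for (r in recipes) {
    cl <- cluster_from_recipe(r)
    mods <- define_modules(cl)
    n_t <- sum(cl$hits$family == "THIOLATION")
    expect_lte(nrow(mods), n_t)
  }
})

test_that("domain strings render genes and substrates readably", {
  cl <- cluster_from_recipe("C-A(ser)-T | C-A(val)-nMT-T | TE")
  expect_equal(domain_string(cl), "C-A(ser)-T | C-A(val)-nMT-T | TE")
})
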