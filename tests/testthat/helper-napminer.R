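# Shared fixtures and independent oracles for the test suite.

MONOMERS <- load_monomer_table()
SUGARS <- load_sugar_code()

# Independent brute-force ORF oracle: walk every position of all six frames.
oracle_orfs <- function(seq, min_aa) {
  seq <- toupper(seq)
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  starts <- c("ATG", "GTG", "TTG"); stops <- c("TAA", "TAG", "TGA")
  found <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (pos0 in 0:(L - 3)) {
      if (!substring(s, pos0 + 1, pos0 + 3) %in% starts) next
      p <- pos0
      repeat {
        if (p + 3 > L) break
        codon <- substring(s, p + 1, p + 3)
        if (codon %in% stops && p > pos0) {
          aa_len <- (p - pos0) / 3
          if (aa_len >= min_aa) {
            found[[length(found) + 1L]] <- c(strand = strand, s0 = pos0,
                                             e0 = p + 3)
          }
          break
        }
        p <- p + 3
      }
    }
  }
  found
}

# Independent greedy gap-partition oracle.
oracle_partition <- function(starts, ends, gap) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  grp <- integer(length(starts)); g <- 1L; grp[1] <- 1L
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - ends[i - 1] > gap) g <- g + 1L
    grp[i] <- g
  }
  split(ord, grp)
}

# Independent exhaustive sugar-prediction oracle (pure set arithmetic).
oracle_predict_sugars <- function(cluster_families, n, code) {
  cand <- code[code$sugar_class %in% c("deoxyhexose", "pentose"), ]
  cand <- cand[order(cand$name), ]
  if (n == 0) return(list(best = character(), obj = c(0, length(unique(cluster_families)))))
  idx_cmb <- function(k, n) {
    if (n == 1) return(matrix(seq_len(k), ncol = 1))
    out <- NULL
    for (i in seq_len(k)) {
      sub <- idx_cmb(k, n - 1)
      sub <- sub[sub[, 1] >= i, , drop = FALSE]
      out <- rbind(out, cbind(i, sub))
    }
    out
  }
  cmb <- idx_cmb(nrow(cand), n)
  best <- NULL; best_obj <- c(Inf, Inf)
  for (r in seq_len(nrow(cmb))) {
    fams <- unique(unlist(cand$gene_families[cmb[r, ]]))
    missing <- length(setdiff(fams, cluster_families))
    extra <- length(setdiff(unique(cluster_families), fams))
    obj <- c(missing + extra, missing)
    if (obj[1] < best_obj[1] ||
        (obj[1] == best_obj[1] && obj[2] < best_obj[2])) {
      best_obj <- obj
      best <- cand$name[cmb[r, ]]
    }
  }
  list(best = best, obj = best_obj)
}

# Random toy sugar code generator.
toy_sugar_code <- function(n_sugars, n_fams, seed) {
  set.seed(seed)
  fams <- sprintf("g%02d", seq_len(n_fams))
  data.frame(
    name = sprintf("S%02d", seq_len(n_sugars)),
    sugar_class = "deoxyhexose",
    formula = "C6H12O4",
    attach_smiles = "C1OC(C)C(O)C(O)C1",
    mass = formula_mass("C6H12O4"),
    stringsAsFactors = FALSE
  ) -> df
  df$gene_families <- lapply(seq_len(n_sugars), function(i) {
    sample(fams, sample(1:min(4, n_fams), 1))
  })
  df
}

# Classical b/y neutral fragment series from residue masses.
oracle_by_series <- function(residue_names, table = MONOMERS) {
  rm_ <- vapply(residue_names, function(r) table$mass[table$name == r],
                numeric(1)) - MASS_H2O
  n <- length(rm_)
  b <- cumsum(rm_)[seq_len(n - 1)]
  y <- rev(cumsum(rev(rm_)))[2:n] + MASS_H2O
  sort(c(b, y))
}

# One-row domain hit for unit tests.
hit_row <- function(orf = "orfA", family = "ADENYLATION", model = "AMP-binding",
                    score = 80, a1 = 10, a2 = 109) {
  data.frame(orf_id = orf, model_name = model, bitscore = score,
             ali_start = a1, ali_end = a2, family = family,
             sugar_family = NA_character_, substrate = NA_character_,
             substrate_calls = I(list(NULL)), stringsAsFactors = FALSE)
}
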