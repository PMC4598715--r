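#' Number of deoxysugar slots in a cluster
#'
#' Total glycosyltransferases minus those with hexose substrates.
#'
#' @param gt_calls data.frame of [assign_gt_substrate()] rows (zero rows OK).
#' @return non-negative integer count.
#' @export
count_sugar_slots <- function(gt_calls) {
  if (is.null(gt_calls) || nrow(gt_calls) == 0) return(0L)
  total <- nrow(gt_calls)
  hex <- sum(gt_calls$substrate_class == "HEXOSE")
  if (hex > total) stop("internal error: hexose count exceeds GT count")
  total - hex
}

#' Score one sugar combination against a cluster's sugar-gene families
#'
#' `missing` counts family names required by the combined pathways of the
#' combination but absent from the cluster; `extra` counts sugar-gene
#' families present in the cluster but unused by the combination. Set
#' semantics over family names (pathways share enzymes; copy number is not
#' compared).
#'
#' @param combo character vector of sugar names (multiset).
#' @param cluster_families character vector of family names in the cluster.
#' @param code sugar code from [load_sugar_code()].
#' @return named numeric `c(missing = , extra = )`.
#' @export
score_combination <- function(combo, cluster_families, code) {
  idx <- match(combo, code$name)
  if (anyNA(idx)) stop("unknown sugar(s): ", paste(combo[is.na(idx)], collapse = ", "))
  needed <- unique(unlist(code$gene_families[idx]))
  cl <- unique(cluster_families)
  c(missing = length(setdiff(needed, cl)), extra = length(setdiff(cl, needed)))
}

#' @keywords internal
#' All multisets of size n from 1..k as a matrix of nondecreasing index rows.
multisets_of_size <- function(k, n) {
  if (n == 0) return(matrix(integer(), nrow = 1, ncol = 0))
  rec <- function(lo, left) {
    if (left == 0) return(matrix(integer(), nrow = 1, ncol = 0))
    out <- list()
    for (i in lo:k) {
      sub <- rec(i, left - 1)
      out[[length(out) + 1L]] <- cbind(rep(i, nrow(sub)), sub)
    }
    do.call(rbind, out)
  }
  rec(1L, n)
}

#' @keywords internal
popcount32 <- function(x) {
  n <- integer(length(x))
  for (b in 0:30) n <- n + bitwAnd(bitwShiftR(x, b), 1L)
  n
}

#' Predict the deoxysugar multiset encoded by a cluster
#'
#' Exhaustively evaluates every multiset of `n` sugars from the code
#' (deoxyhexose and pentose entries; repetition allowed) where `n` comes from
#' [count_sugar_slots()], simultaneously minimizing the genes missing from
#' the cluster and the cluster's unexplained sugar genes (collapsed to the
#' sum, ties broken by smaller `missing`, then lexicographic sugar-name
#' order). All co-optimal multisets are retained. Hexose identities from the
#' glycosyltransferase calls are appended after optimization.
#'
#' @param cluster_families character vector of sugar-gene family names found
#'   in the cluster.
#' @param gt_calls data.frame of [assign_gt_substrate()] rows.
#' @param code sugar code from [load_sugar_code()].
#' @param max_slots refuse combinatorial explosion beyond this many slots
#'   (default 4).
#' @return a `sugar_assignment` list: `n_slots`, `sugars` (character multiset,
#'   length `n_slots`), `missing_genes`, `extra_genes`, `co_optimal` (list of
#'   equally good multisets, including `sugars`), `hexoses`.
#' @export
predict_sugars <- function(cluster_families, gt_calls, code = load_sugar_code(),
                           max_slots = 4) {
  n <- count_sugar_slots(gt_calls)
  hexoses <- gt_calls$hexose_identity[!is.na(gt_calls$hexose_identity)]
  if (n > max_slots) {
    stop("cluster implies ", n, " deoxysugar slots; exhaustive search is ",
         "bounded at ", max_slots, ". Raise max_slots deliberately or split ",
         "the cluster.")
  }
  cand <- code[code$sugar_class %in% c("deoxyhexose", "pentose"), , drop = FALSE]
  if (nrow(cand) == 0) stop("sugar code has no deoxysugar/pentose entries")
  cand <- cand[order(cand$name), , drop = FALSE]
  out <- list(n_slots = n, sugars = character(), missing_genes = NA_real_,
              extra_genes = NA_real_, co_optimal = list(), hexoses = hexoses)
  class(out) <- "sugar_assignment"
  if (n == 0) {
    out$missing_genes <- 0; out$extra_genes <- length(unique(cluster_families))
    return(out)
  }
  fams <- sort(unique(c(unlist(cand$gene_families), cluster_families)))
  if (length(fams) <= 31) {
    bit <- stats::setNames(bitwShiftL(1L, seq_along(fams) - 1L), fams)
    sugar_mask <- vapply(cand$gene_families,
                         function(f) Reduce(bitwOr, bit[f], 0L), integer(1))
    cl_mask <- Reduce(bitwOr, bit[unique(cluster_families)], 0L)
    combos <- multisets_of_size(nrow(cand), n)
    union_mask <- rep(0L, nrow(combos))
    for (j in seq_len(ncol(combos))) {
      union_mask <- bitwOr(union_mask, sugar_mask[combos[, j]])
    }
    missing <- popcount32(bitwAnd(union_mask, bitwNot(cl_mask)))
    extra <- popcount32(bitwAnd(cl_mask, bitwNot(union_mask)))
  } else {
    combos <- multisets_of_size(nrow(cand), n)
    sc <- t(apply(combos, 1, function(ix) {
      score_combination(cand$name[ix], cluster_families, code)
    }))
    missing <- sc[, 1]; extra <- sc[, 2]
  }
  total <- missing + extra
  best_total <- min(total)
  sel <- total == best_total
  best_missing <- min(missing[sel])
  sel <- sel & missing == best_missing
  rows <- which(sel)  # combos are in lexicographic name order already
  out$sugars <- cand$name[combos[rows[1], ]]
  out$missing_genes <- missing[rows[1]]
  out$extra_genes <- extra[rows[1]]
  out$co_optimal <- lapply(rows, function(r) cand$name[combos[r, ]])
  out
}

#' @export
print.sugar_assignment <- function(x, ...) {
  cat("<sugar_assignment> ", x$n_slots, " slot(s): ",
      paste(x$sugars, collapse = " + "),
      "  (missing ", x$missing_genes, ", extra ", x$extra_genes, "; ",
      length(x$co_optimal), " co-optimal)", sep = "")
  if (length(x$hexoses)) cat("  + hexoses:", paste(x$hexoses, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Glycosylate a scaffold with a multiset of sugars
#'
#' Attaches each sugar O-glycosidically at a free hydroxyl chosen by a
#' seeded pseudo-random draw without replacement (identical seed, identical
#' product). With `enumerate_all = TRUE`, returns every distinct placement of
#' the sugars on the free hydroxyls as a list of structures instead.
#'
#' @param scaffold an `np_structure` with at least as many free hydroxyls as
#'   sugars.
#' @param sugars character vector of sugar names (multiset).
#' @param seed integer seed for the site draw.
#' @param code sugar code.
#' @param enumerate_all emit all placements instead of one random draw.
#' @return glycosylated `np_structure`, or a list of them.
#' @export
glycosylate <- function(scaffold, sugars, seed = 1, code = load_sugar_code(),
                        enumerate_all = FALSE) {
  if (!length(sugars)) return(scaffold)
  free <- free_hydroxyl_sites(scaffold)
  if (nrow(free) < length(sugars)) {
    stop("need ", length(sugars), " free hydroxyl(s), structure has ",
         nrow(free))
  }
  rows <- lapply(sugars, function(s) {
    r <- code[code$name == s, , drop = FALSE]
    if (nrow(r) == 0) stop("sugar not in code: ", s)
    r
  })
  if (!enumerate_all) {
    sites <- with_seed(seed, sample(free$site_id, length(sugars)))
    for (i in seq_along(rows)) {
      scaffold <- attach_sugar(scaffold, rows[[i]], sites[i])
    }
    return(scaffold)
  }
  # all distinct assignments sugar -> site (injective; duplicate sugars
  # produce set-identical placements, deduplicated)
  placements <- list()
  assign_rec <- function(i, used, acc) {
    if (i > length(sugars)) {
      key <- paste(sort(paste(sugars, acc)), collapse = "|")
      if (is.null(placements[[key]])) placements[[key]] <<- acc
      return(invisible())
    }
    for (s in setdiff(free$site_id, used)) {
      assign_rec(i + 1L, c(used, s), c(acc, s))
    }
  }
  assign_rec(1L, integer(), integer())
  lapply(unname(placements), function(sites) {
    x <- scaffold
    for (i in seq_along(rows)) x <- attach_sugar(x, rows[[i]], sites[i])
    x
  })
}
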