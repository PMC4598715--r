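#' Matching settings for the LC-MS/MS database-dependent search
#'
#' @param precursor_window precursor mass window W in Da (candidates are kept
#'   when the charge-deconvoluted neutral mass lies within +/- W of the
#'   candidate mass).
#' @param fragment_tolerance fragment m/z tolerance in Da (0.5 suits
#'   ion-trap CID data).
#' @param p1_cutoff,p2_cutoff minimum report scores.
#' @param charges precursor/fragment charge states considered.
#' @return a `match_settings` list.
#' @export
match_settings <- function(precursor_window = 18, fragment_tolerance = 0.5,
                           p1_cutoff = 10, p2_cutoff = 10, charges = 1) {
  if (precursor_window <= 0 || fragment_tolerance <= 0) {
    stop("precursor_window and fragment_tolerance must be > 0")
  }
  if (p1_cutoff < 0 || p2_cutoff < 0) stop("P cutoffs must be >= 0")
  structure(list(precursor_window = precursor_window,
                 fragment_tolerance = fragment_tolerance,
                 p1_cutoff = p1_cutoff, p2_cutoff = p2_cutoff,
                 charges = charges), class = "match_settings")
}

#' Filter scans by precursor mass around a candidate
#'
#' The observed neutral mass is computed from the precursor m/z at the
#' scan's charge when known, otherwise at every allowed charge; the scan is
#' kept if any deconvolution lands within the window.
#'
#' @param spectra list of spectra from [read_spectra()].
#' @param candidate_mass neutral monoisotopic candidate mass (Da).
#' @param settings a [match_settings()].
#' @return the retained subset of `spectra`.
#' @export
precursor_filter <- function(spectra, candidate_mass, settings = match_settings()) {
  Filter(function(s) {
    zs <- if (!is.na(s$precursor_z)) s$precursor_z else settings$charges
    neutral <- s$precursor_mz * zs - zs * MASS_PROTON
    any(abs(neutral - candidate_mass) <= settings$precursor_window)
  }, spectra)
}

#' Match theoretical fragment ions to observed peaks
#'
#' Greedy nearest-m/z pairing within the fragment tolerance; each observed
#' peak and each theoretical fragment is used at most once.
#'
#' @param spectrum one spectrum.
#' @param fragments ionized fragment table from [ionize()] (needs `mz`).
#' @param settings a [match_settings()].
#' @return data.frame of matched pairs: `theo_mz`, `obs_mz`, `intensity`,
#'   `delta`, `frag_row`, `peak_row`.
#' @export
match_fragments <- function(spectrum, fragments, settings = match_settings()) {
  empty <- data.frame(theo_mz = numeric(), obs_mz = numeric(),
                      intensity = numeric(), delta = numeric(),
                      frag_row = integer(), peak_row = integer())
  pk <- spectrum$peaks
  if (!nrow(pk) || !nrow(fragments)) return(empty)
  tol <- settings$fragment_tolerance
  cand <- list()
  for (i in seq_len(nrow(fragments))) {
    d <- abs(pk[, 1] - fragments$mz[i])
    js <- which(d <= tol)
    for (j in js) {
      cand[[length(cand) + 1L]] <- c(i, j, d[j])
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, 3]), , drop = FALSE]
  used_f <- logical(nrow(fragments)); used_p <- logical(nrow(pk))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used_f[i] && !used_p[j]) {
      keep[r] <- TRUE; used_f[i] <- TRUE; used_p[j] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(theo_mz = fragments$mz[cand[, 1]], obs_mz = pk[cand[, 2], 1],
             intensity = pk[cand[, 2], 2], delta = cand[, 3],
             frag_row = cand[, 1], peak_row = cand[, 2])
}

#' Score a compound-to-scan match (P1, P2)
#'
#' P1 is `-10 log10` of the upper-tail probability of observing at least the
#' matched number of fragments under a null in which each theoretical
#' fragment independently matches a random peak with probability
#' `q = min(1, n_peaks * 2 * tol / observed m/z range)`. P2 is the same tail
#' statistic restricted to the intensity-rank top half of the peaks (the
#' matched ion-current-carrying peaks), guarding against matches built on
#' noise-level peaks. Both scores are clamped to [0, 200]; an empty spectrum
#' scores (0, 0).
#'
#' @param matched data.frame from [match_fragments()].
#' @param n_theoretical number of theoretical fragment ions offered.
#' @param spectrum the spectrum that was matched.
#' @param settings a [match_settings()].
#' @return named numeric `c(p1 = , p2 = )`.
#' @export
score_match <- function(matched, n_theoretical, spectrum,
                        settings = match_settings()) {
  stopifnot(n_theoretical >= 1)
  pk <- spectrum$peaks
  if (!nrow(pk)) return(c(p1 = 0, p2 = 0))
  tol <- settings$fragment_tolerance
  rng <- max(diff(range(pk[, 1])), 1)
  tail_score <- function(k, q) {
    if (k <= 0) return(0)
    p <- stats::pbinom(k - 1, n_theoretical, min(q, 1), lower.tail = FALSE)
    min(max(-10 * log10(max(p, 1e-300)), 0), 200)
  }
  q1 <- nrow(pk) * 2 * tol / rng
  p1 <- tail_score(nrow(matched), q1)
  m <- ceiling(nrow(pk) / 2)
  top_rows <- order(pk[, 2], decreasing = TRUE)[seq_len(m)]
  k2 <- if (nrow(matched)) sum(matched$peak_row %in% top_rows) else 0
  q2 <- m * 2 * tol / rng
  p2 <- tail_score(k2, q2)
  c(p1 = p1, p2 = p2)
}

#' Precompute ionized fragment tables for a structure library
#'
#' @param lib library data.frame from [enumerate_library()] /
#'   [load_structure_library()].
#' @param cleavage a [cleavage_settings()].
#' @param charges fragment charge states.
#' @return named list (by `compound_id`) of ionized fragment tables;
#'   graph-less entries fall back to the parent mass plus neutral losses.
#' @export
fragment_library <- function(lib, cleavage = cleavage_settings(amide = c(1, 2),
                                                               water_loss = c(0, 1)),
                             charges = 1) {
  out <- vector("list", nrow(lib))
  names(out) <- lib$compound_id
  for (i in seq_len(nrow(lib))) {
    s <- lib$structure[[i]]
    fr <- if (!is.null(s)) {
      enumerate_fragments(s, cleavage)
    } else {
      # no residue graph: parent species and neutral losses only
      wl <- cleavage$water_loss; al <- cleavage$ammonia_loss
      grid <- expand.grid(w = wl[1]:wl[2], a = al[1]:al[2])
      data.frame(
        neutral_mass = lib$neutral_monoisotopic_mass[i] -
          grid$w * MASS_H2O - grid$a * MASS_NH3,
        side = "parent", n_cleavages = 0L, cleaved_bonds = "none",
        losses = paste0(ifelse(grid$w > 0, paste0(grid$w, "xH2O"), ""),
                        ifelse(grid$w > 0 & grid$a > 0, "+", ""),
                        ifelse(grid$a > 0, paste0(grid$a, "xNH3"), "")),
        substructure_smiles = NA_character_, stringsAsFactors = FALSE)
    }
    out[[i]] <- ionize(fr, charges)
  }
  out
}

#' Score every candidate against every retained scan
#'
#' The core database-dependent search: precursor filtering per candidate,
#' greedy fragment matching, P1/P2 scoring.
#'
#' @param spectra list of spectra.
#' @param lib candidate library data.frame.
#' @param frag_lib precomputed [fragment_library()] (recomputed if `NULL`).
#' @param settings a [match_settings()].
#' @param cleavage a [cleavage_settings()] (used when `frag_lib` is `NULL`).
#' @return data.frame of scan matches: `scan_id`, `rt_min`, `compound_id`,
#'   `n_matched`, `n_theoretical`, `p1`, `p2`.
#' @export
score_library <- function(spectra, lib, frag_lib = NULL,
                          settings = match_settings(),
                          cleavage = cleavage_settings(amide = c(1, 2),
                                                       water_loss = c(0, 1))) {
  if (is.null(frag_lib)) {
    frag_lib <- fragment_library(lib, cleavage, settings$charges)
  }
  rows <- list()
  for (i in seq_len(nrow(lib))) {
    cid <- lib$compound_id[i]
    frags <- frag_lib[[cid]]
    if (is.null(frags) || !nrow(frags)) next
    keep <- precursor_filter(spectra, lib$neutral_monoisotopic_mass[i],
                             settings)
    for (s in keep) {
      matched <- match_fragments(s, frags, settings)
      sc <- score_match(matched, nrow(frags), s, settings)
      rows[[length(rows) + 1L]] <- data.frame(
        scan_id = s$scan_id, rt_min = s$rt_min, compound_id = cid,
        n_matched = nrow(matched), n_theoretical = nrow(frags),
        p1 = sc["p1"], p2 = sc["p2"], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(scan_id = character(), rt_min = numeric(),
                      compound_id = character(), n_matched = integer(),
                      n_theoretical = integer(), p1 = numeric(),
                      p2 = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank matches per scan and build the report table
#'
#' Ranks the union of prediction and decoy matches within each scan by P1
#' (ties: higher P2, then compound id). Scans whose top-ranked hit is a
#' prediction-library compound and passes both score cutoffs become report
#' rows, carrying the scan's decoy mean P1 and the decoy-normalized P1
#' (denominator floored at 1).
#'
#' @param matches data.frame from [score_library()] over the union library.
#' @param prediction_ids compound ids of the prediction library.
#' @param decoy_ids compound ids of the decoy ("dummy") library.
#' @param settings a [match_settings()].
#' @return data.frame: `scan_id`, `rt_min`, `compound_id`, `p1`, `p2`,
#'   `n_matched`, `decoy_mean_p1`, `normalized_p1`.
#' @export
rank_and_report <- function(matches, prediction_ids, decoy_ids,
                            settings = match_settings()) {
  if (!length(decoy_ids)) {
    warning("decoy library empty: discovery chart normalization disabled")
  }
  empty <- data.frame(scan_id = character(), rt_min = numeric(),
                      compound_id = character(), p1 = numeric(),
                      p2 = numeric(), n_matched = integer(),
                      decoy_mean_p1 = numeric(), normalized_p1 = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(matches)) return(empty)
  rows <- list()
  for (sid in unique(matches$scan_id)) {
    m <- matches[matches$scan_id == sid, , drop = FALSE]
    m <- m[order(-m$p1, -m$p2, m$compound_id), , drop = FALSE]
    top <- m[1, ]
    if (!top$compound_id %in% prediction_ids) next
    if (top$p1 < settings$p1_cutoff || top$p2 < settings$p2_cutoff) next
    dec <- m[m$compound_id %in% decoy_ids, , drop = FALSE]
    dmean <- if (nrow(dec)) mean(dec$p1) else 0
    rows[[length(rows) + 1L]] <- data.frame(
      scan_id = top$scan_id, rt_min = top$rt_min,
      compound_id = top$compound_id, p1 = top$p1, p2 = top$p2,
      n_matched = top$n_matched, decoy_mean_p1 = dmean,
      normalized_p1 = top$p1 / max(dmean, 1), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the prediction-guided discovery chart
#'
#' Sums decoy-normalized top-hit P1 values in half-open 0.25-minute
#' retention-time buckets.
#'
#' @param report data.frame from [rank_and_report()].
#' @return data.frame: `bucket_start` (min, multiple of 0.25),
#'   `summed_normalized_p1`, `n_scans`, `contributing_scans`.
#' @export
build_discovery_chart <- function(report) {
  if (!nrow(report)) {
    return(data.frame(bucket_start = numeric(), summed_normalized_p1 = numeric(),
                      n_scans = integer(), contributing_scans = character(),
                      stringsAsFactors = FALSE))
  }
  bucket <- floor(report$rt_min / 0.25) * 0.25
  agg <- split(seq_len(nrow(report)), bucket)
  out <- data.frame(
    bucket_start = as.numeric(names(agg)),
    summed_normalized_p1 = vapply(agg, function(ix) {
      sum(report$normalized_p1[ix])
    }, numeric(1)),
    n_scans = vapply(agg, length, integer(1)),
    contributing_scans = vapply(agg, function(ix) {
      paste(report$scan_id[ix], collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$bucket_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
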