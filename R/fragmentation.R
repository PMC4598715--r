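#' Cleavage and neutral-loss budgets for in-silico fragmentation
#'
#' Each channel takes a `c(min, max)` count of cleavages (or losses) per
#' fragment species. The total enumerated cleavage budget is bounded
#' (default sum of maxima <= 6).
#'
#' @param amide,ester,inverse_ester,thioether,glycosidic cleavage count
#'   ranges.
#' @param water_loss,ammonia_loss neutral-loss count ranges.
#' @param max_total_cleavages global bound on `sum(max)` over cleavage
#'   channels.
#' @return a `cleavage_settings` list.
#' @export
cleavage_settings <- function(amide = c(0, 0), ester = c(0, 0),
                              inverse_ester = c(0, 0), thioether = c(0, 0),
                              glycosidic = c(0, 0), water_loss = c(0, 0),
                              ammonia_loss = c(0, 0),
                              max_total_cleavages = 6) {
  s <- list(amide = amide, ester = ester, inverse_ester = inverse_ester,
            thioether = thioether, glycosidic = glycosidic,
            water_loss = water_loss, ammonia_loss = ammonia_loss)
  for (nm in names(s)) {
    v <- s[[nm]]
    if (length(v) != 2 || v[1] < 0 || v[1] > v[2]) {
      stop("channel ", nm, " needs c(min, max) with 0 <= min <= max")
    }
  }
  cleave <- c("amide", "ester", "inverse_ester", "thioether", "glycosidic")
  if (sum(vapply(s[cleave], `[`, 0, 2)) > max_total_cleavages) {
    stop("total cleavage budget exceeds the global bound of ",
         max_total_cleavages)
  }
  structure(c(s, list(max_total_cleavages = max_total_cleavages)),
            class = "cleavage_settings")
}

#' @keywords internal
.OXANOL_SMARTS <- "[#6;R1]1([OX2])[#8;R1][#6;R1][#6;R1][#6;R1][#6;R1]1"

#' @keywords internal
#' Memoized oxan-2-ol gate for a sugar piece (free reducing form).
sugar_is_oxanol <- local({
  cache <- new.env(parent = emptyenv())
  function(piece) {
    key <- piece
    if (!is.null(cache[[key]])) return(cache[[key]])
    hit <- tryCatch({
      sdf <- suppressWarnings(ChemmineR::smiles2sdf(paste0("O", piece)))
      sum(ChemmineR::smartsSearchOB(sdf, .OXANOL_SMARTS)) > 0
    }, error = function(e) FALSE)
    cache[[key]] <- hit
    hit
  }
})

#' @keywords internal
#' Bond ids belonging to the macrocycle ring, if any.
ring_bond_ids <- function(x) {
  if (is.null(x$closure)) return(integer())
  term <- x$chain[length(x$chain)]
  k <- which(x$chain == x$closure$residue)
  ring_res <- x$chain[k:length(x$chain)]
  which((x$bonds$from %in% ring_res & x$bonds$to %in% ring_res))
}

#' Detect cleavable bonds in a structure
#'
#' Typed bond table over the residue graph: backbone and side amides,
#' esters (lactones), and glycosidic bonds gated on the sugar ring matching
#' an oxan-2-ol substructure (six-membered oxygen ring with an exocyclic
#' oxygen at the anomeric carbon). Ketide Claisen C-C bonds are not
#' cleavable. Hydroxyl and amine inventories for neutral losses are implicit
#' in the residue templates.
#'
#' @param x an `np_structure`.
#' @return data.frame: `bond_id`, `from`, `to`, `type`, `in_ring`.
#' @export
detect_cleavable_bonds <- function(x) {
  b <- x$bonds
  if (nrow(b) == 0) {
    return(data.frame(bond_id = integer(), from = integer(), to = integer(),
                      type = character(), in_ring = logical()))
  }
  ring <- ring_bond_ids(x)
  out <- data.frame(bond_id = seq_len(nrow(b)), from = b$from, to = b$to,
                    type = b$type, in_ring = seq_len(nrow(b)) %in% ring,
                    stringsAsFactors = FALSE)
  keep <- out$type %in% c("amide", "ester", "thioether")
  gly <- which(out$type == "glycosidic")
  keep[gly] <- vapply(out$to[gly], function(r) sugar_is_oxanol(x$pieces[r]),
                      logical(1))
  out[keep, , drop = FALSE]
}

#' @keywords internal
subsets_of_sizes <- function(ids, min_n, max_n) {
  max_n <- min(max_n, length(ids))
  out <- list()
  for (k in max(min_n, 0):max_n) {
    if (k == 0) { out[[length(out) + 1L]] <- integer(); next }
    if (k > length(ids)) break
    cmb <- utils::combn(ids, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  if (min_n > length(ids)) list() else out
}

#' Enumerate theoretical neutral fragments under cleavage budgets
#'
#' Applies every combination of cleavage counts within the per-channel
#' budgets. Hydrogen transfer follows the convention that the amine/alkoxy
#' side fragment is emitted as the free (hydrolysis-equivalent) species and
#' the acyl side as the ketene equivalent, so the two neutral fragments of
#' one acyclic cleavage sum exactly to the parent neutral mass; for
#' glycosidic bonds the aglycone keeps its hydroxyl and the sugar leaves as
#' the anhydro (oxocarbenium-equivalent) species. The first cleavage of a
#' macrocycle yields a ring-opened species of unchanged mass. Internal
#' fragments (two or more cut ends on an acyclic chain) are emitted only
#' when the summed cleavage budget is at least 3. Water/ammonia losses are
#' applied combinatorially within their budgets; duplicate masses are
#' collapsed with provenance union.
#'
#' @param x an `np_structure` (e.g. from [enumerate_library()]'s
#'   `structure` column).
#' @param settings a [cleavage_settings()].
#' @return data.frame: `neutral_mass`, `side`, `n_cleavages`,
#'   `cleaved_bonds`, `losses`, `substructure_smiles`.
#' @export
enumerate_fragments <- function(x, settings = cleavage_settings()) {
  bonds <- detect_cleavable_bonds(x)
  chan_bonds <- list(
    amide = bonds$bond_id[bonds$type == "amide"],
    ester = bonds$bond_id[bonds$type == "ester"],
    inverse_ester = bonds$bond_id[bonds$type == "ester"],
    thioether = bonds$bond_id[bonds$type == "thioether"],
    glycosidic = bonds$bond_id[bonds$type == "glycosidic"])
  per_chan <- lapply(names(chan_bonds), function(ch) {
    subsets_of_sizes(chan_bonds[[ch]], settings[[ch]][1], settings[[ch]][2])
  })
  names(per_chan) <- names(chan_bonds)
  if (any(vapply(per_chan, length, 0L) == 0)) {
    # some channel's minimum cannot be satisfied: no fragments
    return(empty_fragments())
  }
  allow_internal <- sum(vapply(
    c("amide", "ester", "inverse_ester", "thioether", "glycosidic"),
    function(ch) settings[[ch]][2], numeric(1))) >= 3

  combos <- expand.grid(lapply(per_chan, seq_along))
  frags <- list()
  for (ci in seq_len(nrow(combos))) {
    picks <- lapply(names(per_chan), function(ch) {
      per_chan[[ch]][[combos[ci, ch]]]
    })
    names(picks) <- names(per_chan)
    cut_ids <- unlist(picks, use.names = FALSE)
    if (anyDuplicated(cut_ids)) next  # same ester bond in both channels
    inv_ids <- picks$inverse_ester
    frags <- c(frags, fragment_components(x, bonds, cut_ids, inv_ids,
                                          allow_internal))
  }
  if (!length(frags)) return(empty_fragments())
  base <- do.call(rbind, frags)
  # neutral losses
  wl <- settings$water_loss; al <- settings$ammonia_loss
  out <- list()
  for (w in wl[1]:wl[2]) for (a in al[1]:al[2]) {
    v <- base
    v$neutral_mass <- v$neutral_mass - w * MASS_H2O - a * MASS_NH3
    v$losses <- paste0(if (w) paste0(w, "xH2O") else "",
                       if (w && a) "+" else "",
                       if (a) paste0(a, "xNH3") else "")
    if (w + a > 0) v$substructure_smiles <- NA_character_
    out[[length(out) + 1L]] <- v
  }
  res <- do.call(rbind, out)
  res <- res[res$neutral_mass > 0, , drop = FALSE]
  # collapse duplicate masses, union provenance
  key <- sprintf("%.6f", res$neutral_mass)
  keep <- !duplicated(key)
  prov <- tapply(paste0(res$cleaved_bonds, ifelse(nzchar(res$losses),
                                                  paste0(";", res$losses), "")),
                 key, function(p) paste(unique(p), collapse = " | "))
  res <- res[keep, , drop = FALSE]
  res$cleaved_bonds <- unname(prov[sprintf("%.6f", res$neutral_mass)])
  res <- res[order(res$neutral_mass), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @keywords internal
empty_fragments <- function() {
  data.frame(neutral_mass = numeric(), side = character(),
             n_cleavages = integer(), cleaved_bonds = character(),
             losses = character(), substructure_smiles = character(),
             stringsAsFactors = FALSE)
}

#' @keywords internal
#' Split the residue graph at `cut_ids` and emit one row per component.
fragment_components <- function(x, bonds, cut_ids, inv_ids, allow_internal) {
  n <- nrow(x$residues)
  keep_bonds <- x$bonds[setdiff(seq_len(nrow(x$bonds)), cut_ids), ,
                        drop = FALSE]
  comp <- seq_len(n)
  for (i in seq_len(nrow(keep_bonds))) {
    a <- comp[keep_bonds$from[i]]; b2 <- comp[keep_bonds$to[i]]
    if (a != b2) comp[comp == b2] <- a
  }
  cutb <- bonds[match(cut_ids, bonds$bond_id), , drop = FALSE]
  # deduct side: acyl side for amide/ester/thioether, sugar side for
  # glycosidic; inverse-ester cleavage deducts on the alkoxy side instead
  deduct_res <- ifelse(cutb$bond_id %in% inv_ids | cutb$type == "glycosidic",
                       cutb$to, cutb$from)
  chain_start <- x$chain[1]; chain_end <- x$chain[length(x$chain)]
  ring_ids <- ring_bond_ids(x)
  rows <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    internal_bonds <- sum(keep_bonds$from %in% members &
                            keep_bonds$to %in% members)
    deduct <- sum(deduct_res %in% members)
    mass <- sum(x$residues$mass[members]) -
      (internal_bonds + deduct) * MASS_H2O
    has_start <- chain_start %in% members
    has_end <- chain_end %in% members
    side <- if (has_start && has_end) {
      if (length(cut_ids) == 0) "parent"
      else if (any(cutb$bond_id %in% ring_ids)) "ring_opened_full"
      else "full_backbone"
    } else if (has_start) "n_terminal_like"
    else if (has_end) "c_terminal_like"
    else if (!length(intersect(members, x$chain))) "sugar"
    else "internal"
    if (side == "internal" && !allow_internal) next
    smi <- fragment_smiles(x, members, cutb, deduct_res, cut_ids)
    rows[[length(rows) + 1L]] <- data.frame(
      neutral_mass = mass, side = side, n_cleavages = length(cut_ids),
      cleaved_bonds = if (length(cut_ids)) {
        paste(paste0(cutb$type, ":", cutb$bond_id), collapse = ",")
      } else "none",
      losses = "", substructure_smiles = smi, stringsAsFactors = FALSE)
  }
  rows
}

#' @keywords internal
#' Best-effort fragment SMILES: free form for amine/alkoxy-side ends, ketene
#' for an acyl-side chain end; NA for sugar-side (anhydro) species and other
#' cases with no clean valence form.
fragment_smiles <- function(x, members, cutb, deduct_res, cut_ids) {
  chain_members <- x$chain[x$chain %in% members]
  if (!length(chain_members)) return(NA_character_)
  # deduct residues in this component other than a trailing chain acyl end
  # have no clean neutral SMILES (inverse-ester / sugar-side species)
  ded_here <- intersect(deduct_res[deduct_res %in% members], members)
  tail_res <- chain_members[length(chain_members)]
  if (length(setdiff(ded_here, tail_res))) return(NA_character_)
  acyl_end <- if (length(ded_here)) tail_res else integer()
  if (length(acyl_end)) {
    # must be a normal acyl-side cut (not inverse ester)
    row <- cutb[match(acyl_end, cutb$from), , drop = FALSE]
    if (nrow(row) == 0 || is.na(row$bond_id[1])) return(NA_character_)
  }
  open_ring <- any(cutb$bond_id %in% ring_bond_ids(x))
  tryCatch(
    compose_smiles(x, members, acyl_cut_end = acyl_end,
                   open_ring = open_ring),
    error = function(e) NA_character_)
}

#' Ionize neutral fragments to m/z values
#'
#' Protonated species; doubly charged entries only above a configurable
#' neutral-mass floor (ion-trap convention).
#'
#' @param fragments data.frame from [enumerate_fragments()] (needs
#'   `neutral_mass`).
#' @param charges subset of `c(1, 2)`.
#' @param z2_min_mass minimum neutral mass for 2+ ions (default 400 Da).
#' @return the fragments replicated per charge with `mz` and `charge`.
#' @export
ionize <- function(fragments, charges = 1, z2_min_mass = 400) {
  stopifnot(all(charges %in% c(1, 2)))
  out <- list()
  for (z in sort(charges)) {
    f <- fragments
    if (z == 2) f <- f[f$neutral_mass >= z2_min_mass, , drop = FALSE]
    if (!nrow(f)) next
    f$charge <- z
    f$mz <- (f$neutral_mass + z * MASS_PROTON) / z
    out[[length(out) + 1L]] <- f
  }
  if (!length(out)) {
    f <- fragments[0, , drop = FALSE]; f$charge <- integer(); f$mz <- numeric()
    return(f)
  }
  do.call(rbind, out)
}
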