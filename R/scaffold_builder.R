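#' @keywords internal
#' Residue-graph representation of a (partially built) natural product.
#'
#' A structure is a set of residues (monomer instances with state-adjusted
#' masses and SMILES piece templates) joined by typed bonds: `amide`
#' (peptide/acyl amide), `cc` (ketide Claisen C-C, not cleavable), `ester`
#' (lactone) and `glycosidic`. Backbone residues are listed in `chain`;
#' sugars hang off hydroxyl sites. Every bond costs one water in mass
#' bookkeeping (ketide units carry acid-equivalent monomer masses so the
#' same rule holds for Claisen extension).
new_structure <- function() {
  structure(list(
    residues = data.frame(name = character(), class = character(),
                          mass = numeric(), stringsAsFactors = FALSE),
    pieces = character(),
    chain = integer(),
    bonds = data.frame(from = integer(), to = integer(), type = character(),
                       stringsAsFactors = FALSE),
    oh_sites = data.frame(site_id = integer(), residue = integer(),
                          status = character(), sugar_residue = integer(),
                          stringsAsFactors = FALSE),
    nh_sites = data.frame(site_id = integer(), residue = integer(),
                          status = character(), stringsAsFactors = FALSE),
    closure = NULL,
    n_rsites = 0L,
    provenance = list()
  ), class = "np_structure")
}

#' @export
print.np_structure <- function(x, ...) {
  m <- structure_mass(x)
  cat("<np_structure> ", nrow(x$residues), " residues [",
      paste(x$residues$name[x$chain], collapse = "-"), "]",
      if (!is.null(x$closure)) paste0(" ", x$closure$type, "-cyclized"),
      "; neutral monoisotopic mass ",
      if (is.na(m)) "undefined (open sites)" else sprintf("%.4f Da", m),
      "\n", sep = "")
  invisible(x)
}

#' @keywords internal
add_residue <- function(x, name, class, mass, piece) {
  x$residues <- rbind(x$residues,
                      data.frame(name = name, class = class, mass = mass,
                                 stringsAsFactors = FALSE))
  idx <- nrow(x$residues)
  # register {OH}/{NH2} site markers with unique ids
  for (marker in c("OH", "NH2")) {
    pat <- paste0("{", marker, "}")
    while (grepl(pat, piece, fixed = TRUE)) {
      sid <- nrow(x$oh_sites) + nrow(x$nh_sites) + 1L
      tag <- paste0("{", marker, sid, "}")
      piece <- sub(pat, tag, piece, fixed = TRUE)
      if (marker == "OH") {
        x$oh_sites <- rbind(x$oh_sites, data.frame(
          site_id = sid, residue = idx, status = "free",
          sugar_residue = NA_integer_, stringsAsFactors = FALSE))
      } else {
        x$nh_sites <- rbind(x$nh_sites, data.frame(
          site_id = sid, residue = idx, status = "free",
          stringsAsFactors = FALSE))
      }
    }
  }
  x$pieces[idx] <- piece
  list(x = x, idx = idx)
}

#' @keywords internal
add_bond <- function(x, from, to, type) {
  x$bonds <- rbind(x$bonds, data.frame(from = from, to = to, type = type,
                                       stringsAsFactors = FALSE))
  x
}

#' @keywords internal
aa_piece <- function(row, n_methylated) {
  if (nzchar(row$piece_override)) {
    if (n_methylated) warning("N-methylation ignored for ", row$name,
                              " (templated residue)")
    return(row$piece_override)
  }
  nme <- if (n_methylated) "(C)" else ""
  side <- row$side_smiles
  alpha <- if (nzchar(side)) paste0("C(", side, ")") else "C"
  paste0("N", nme, alpha, "C(=O)")
}

#' Extend a peptide chain by one amino-acid monomer
#'
#' Forms an amide bond with loss of water in mass bookkeeping; with
#' `n_methylated` the new amide nitrogen carries a methyl (+CH2 in mass).
#' An empty chain is initialized with the monomer.
#'
#' @param chain an `np_structure` (or `NULL`/fresh structure to start).
#' @param monomer monomer name (row of the monomer table, class
#'   `amino_acid`) or `"X"` for the wildcard attachment-site residue.
#' @param n_methylated logical flag from the module's N-methyltransferase.
#' @param table monomer table from [load_monomer_table()].
#' @return extended `np_structure`.
#' @export
extend_peptide <- function(chain = NULL, monomer, n_methylated = FALSE,
                           table = load_monomer_table()) {
  if (is.null(chain)) chain <- new_structure()
  if (!is.null(chain$closure)) stop("chain is macrocyclized; no free carboxyl terminus")
  if (identical(monomer, "X")) {
    piece <- paste0("N", if (n_methylated) "(C)" else "", "C([*])C(=O)")
    res <- add_residue(chain, "X", "amino_acid", NA_real_, piece)
    res$x$n_rsites <- res$x$n_rsites + 1L
  } else {
    row <- monomer_row(monomer, table)
    if (row$class != "amino_acid") {
      stop("extend_peptide needs an amino_acid monomer, got ", row$class,
           " (", monomer, ")")
    }
    mass <- row$mass + if (n_methylated) 14.0156500642 else 0
    res <- add_residue(chain, monomer, "amino_acid", mass,
                       aa_piece(row, n_methylated))
  }
  x <- res$x
  prev <- if (length(x$chain)) x$chain[length(x$chain)] else NA
  x$chain <- c(x$chain, res$idx)
  if (!is.na(prev)) x <- add_bond(x, prev, res$idx, "amide")
  x
}

#' @keywords internal
.KR_DELTA <- 2 * 1.0078250319          # ketone -> alcohol
.DH_DELTA <- -MASS_H2O                 # alcohol -> alkene
.ER_DELTA <- 2 * 1.0078250319          # alkene -> methylene
.CH2 <- 14.0156500638

#' Extend a chain by one ketide unit with a simulated reductive loop
#'
#' Two-carbon (Claisen) extension at the thioester-equivalent carboxyl
#' terminus. The beta position (the previous acyl carbon) is set by the
#' module's reductive state: none = ketone, `KR` = hydroxyl, `KR,DH` =
#' alpha,beta-alkene, `KR,DH,ER` = methylene. Methylmalonate adds an
#' alpha-methyl branch. `DH` without `KR` (or `ER` without both) is
#' chemically unreachable and rejected.
#'
#' @param chain an `np_structure` with at least one residue.
#' @param at_substrate `"mal"` or `"mmal"`.
#' @param reductive_state character subset of `c("KR","DH","ER")` (or a
#'   comma-joined string).
#' @param table monomer table.
#' @return extended `np_structure`.
#' @export
extend_ketide <- function(chain, at_substrate = c("mal", "mmal"),
                          reductive_state = character(),
                          table = load_monomer_table()) {
  at_substrate <- match.arg(at_substrate)
  if (length(reductive_state) == 1 && grepl(",", reductive_state)) {
    reductive_state <- strsplit(reductive_state, ",")[[1]]
  }
  reductive_state <- toupper(trimws(reductive_state[nzchar(reductive_state)]))
  bad <- setdiff(reductive_state, c("KR", "DH", "ER"))
  if (length(bad)) stop("unknown reductive domain(s): ", paste(bad, collapse = ","))
  if ("DH" %in% reductive_state && !"KR" %in% reductive_state) {
    stop("reductive state {DH} without KR is chemically unreachable")
  }
  if ("ER" %in% reductive_state && !all(c("KR", "DH") %in% reductive_state)) {
    stop("reductive state with ER requires KR and DH")
  }
  if (!length(chain$chain)) stop("extend_ketide needs a started chain")
  if (!is.null(chain$closure)) stop("chain is macrocyclized")

  row <- monomer_row(at_substrate, table)
  mass <- row$mass +
    ("KR" %in% reductive_state) * .KR_DELTA +
    ("DH" %in% reductive_state) * .DH_DELTA +
    ("ER" %in% reductive_state) * .ER_DELTA

  prev <- chain$chain[length(chain$chain)]
  prev_piece <- chain$pieces[prev]
  if (!endsWith(prev_piece, "C(=O)")) {
    stop("chain terminus lacks a free acyl carbon for ketide extension")
  }
  stem <- substr(prev_piece, 1, nchar(prev_piece) - 5)
  mm <- if (at_substrate == "mmal") "(C)" else ""
  state_key <- paste(sort(reductive_state), collapse = ",")
  if (state_key == "") {
    beta <- "C(=O)"; alpha <- paste0("C", mm)
  } else if (state_key == "KR") {
    beta <- "C({OH})"; alpha <- paste0("C", mm)
  } else if (state_key == "DH,KR") {
    beta <- "C"; alpha <- paste0("=C", mm)
  } else {
    beta <- "C"; alpha <- paste0("C", mm)
  }
  piece <- paste0(alpha, "C(=O)")
  res <- add_residue(chain, paste0(at_substrate,
                                   if (nzchar(state_key)) paste0("(", state_key, ")") else ""),
                     "ketide_unit", mass, piece)
  x <- res$x
  # rewrite the previous acyl carbon (now the beta carbon); a KR hydroxyl is
  # registered as a site belonging to the new unit but lives in the old piece
  if (grepl("{OH}", beta, fixed = TRUE)) {
    sid <- nrow(x$oh_sites) + nrow(x$nh_sites) + 1L
    beta <- sub("{OH}", paste0("{OH", sid, "}"), beta, fixed = TRUE)
    x$oh_sites <- rbind(x$oh_sites, data.frame(
      site_id = sid, residue = res$idx, status = "free",
      sugar_residue = NA_integer_, stringsAsFactors = FALSE))
  }
  x$pieces[prev] <- paste0(stem, beta)
  x$chain <- c(x$chain, res$idx)
  add_bond(x, prev, res$idx, "cc")
}

#' Attach a fatty-acyl (or unresolved) starter at the N-terminus
#'
#' Prepends an acyl starter amide-linked to the first backbone nitrogen.
#' With `starter = NULL` (fatty acyl-AMP ligase substrate unresolved) an
#' open R-site labelled `R_acyl` is emitted instead and the scaffold mass
#' becomes undefined until the site is filled.
#'
#' @param chain an `np_structure` whose N-terminus is free.
#' @param starter monomer name of class `fatty_acyl`, or `NULL`.
#' @param table monomer table.
#' @return `np_structure` with the starter as the new first chain residue.
#' @export
attach_starter <- function(chain, starter = NULL, table = load_monomer_table()) {
  if (!length(chain$chain)) stop("attach_starter needs a started chain")
  first <- chain$chain[1]
  if (chain$residues$class[first] == "fatty_acyl") {
    stop("N-terminus already acylated")
  }
  if (is.null(starter)) {
    res <- add_residue(chain, "R_acyl", "fatty_acyl", NA_real_, "[*]")
    res$x$n_rsites <- res$x$n_rsites + 1L
  } else {
    row <- monomer_row(starter, table)
    if (row$class != "fatty_acyl") {
      stop("starter must be a fatty_acyl monomer, got ", row$class)
    }
    res <- add_residue(chain, starter, "fatty_acyl", row$mass,
                       row$piece_override)
  }
  x <- res$x
  x$chain <- c(res$idx, x$chain)
  add_bond(x, res$idx, first, "amide")
}

#' Build a predicted scaffold from an ordered module list
#'
#' Applies modules in assembly-line order under the co-linearity assumption:
#' each NRPS module contributes its top-scoring amino-acid substrate (with
#' N-methylation simulated), each PKS module a ketide unit with its
#' reductive-loop state. Release is the linear acid; macrocyclization is a
#' combinatorialization axis, not asserted here. Trans-acting modules are
#' excluded with a message (surfaced for user-directed placement). A starter
#' acylation flag on module 1 attaches an open `R_acyl` site.
#'
#' @param modules data.frame from [define_modules()].
#' @param table monomer table.
#' @return an `np_structure` scaffold.
#' @export
build_scaffold <- function(modules, table = load_monomer_table()) {
  chain_mods <- modules[!modules$trans_acting, , drop = FALSE]
  if (nrow(chain_mods) == 0) stop("no in-chain modules to build from")
  trans <- modules[modules$trans_acting, , drop = FALSE]
  if (nrow(trans)) {
    message(nrow(trans), " trans-acting module(s) excluded from the chain: ",
            paste(trans$substrate, collapse = ", "))
  }
  chain_mods <- chain_mods[order(chain_mods$index), , drop = FALSE]
  if (all(chain_mods$substrate == "X")) {
    warning("all modules lack substrate calls; scaffold is all wildcards")
  }
  x <- NULL
  for (i in seq_len(nrow(chain_mods))) {
    m <- chain_mods[i, ]
    if (m$kind == "NRPS") {
      x <- extend_peptide(x, m$substrate, n_methylated = isTRUE(m$n_methylated),
                          table = table)
    } else {
      sub <- if (m$substrate %in% c("mal", "mmal")) m$substrate else "mal"
      if (is.null(x)) {
        # PKS-initiated chain: acetyl starter unit
        row <- monomer_row("acetyl", table)
        res <- add_residue(new_structure(), "acetyl", "fatty_acyl", row$mass,
                           row$piece_override)
        x <- res$x
        x$chain <- res$idx
      }
      x <- extend_ketide(x, sub, m$reductive_state, table = table)
    }
  }
  if (isTRUE(chain_mods$is_starter[1])) x <- attach_starter(x, NULL, table)
  x$provenance$modules <- chain_mods
  x
}

#' Neutral monoisotopic mass of a structure
#'
#' Sum of monomer masses minus one water per bond (amide, Claisen,
#' ester, glycosidic alike; ketide monomer masses are acid equivalents so
#' the rule is uniform). `NA` while open R-sites or wildcards remain.
#'
#' @param x an `np_structure`.
#' @return mass in Da, or `NA`.
#' @export
structure_mass <- function(x) {
  if (x$n_rsites > 0 || anyNA(x$residues$mass)) return(NA_real_)
  sum(x$residues$mass) - nrow(x$bonds) * MASS_H2O
}

#' Free hydroxyl sites of a structure
#'
#' @param x an `np_structure`.
#' @return data.frame of unconsumed hydroxyl sites.
#' @export
free_hydroxyl_sites <- function(x) {
  x$oh_sites[x$oh_sites$status == "free", , drop = FALSE]
}

#' Close a macrolactone or macrolactam
#'
#' Joins the chain's terminal carboxyl to a free hydroxyl (`lactone`), a free
#' side-chain amine (`lactam`), or the backbone N-terminus
#' (`lactam`, `site_residue` = first residue) with loss of water.
#'
#' @param x an `np_structure` with a free acyl terminus.
#' @param type `"lactone"` or `"lactam"`.
#' @param site_residue chain position (1-based along the backbone) of the
#'   residue providing the hydroxyl/amine.
#' @return cyclized `np_structure`.
#' @export
close_macrocycle <- function(x, type = c("lactone", "lactam"), site_residue) {
  type <- match.arg(type)
  if (!is.null(x$closure)) stop("structure already macrocyclized")
  ridx <- x$chain[site_residue]
  term <- x$chain[length(x$chain)]
  if (type == "lactone") {
    cand <- x$oh_sites[x$oh_sites$residue == ridx & x$oh_sites$status == "free", ]
    if (nrow(cand) == 0) {
      stop("residue ", x$residues$name[ridx], " at chain position ",
           site_residue, " has no free hydroxyl for lactonization")
    }
    sid <- cand$site_id[1]
    x$oh_sites$status[x$oh_sites$site_id == sid] <- "ester"
    x$closure <- list(type = "lactone", site_kind = "oh", site_id = sid,
                      residue = ridx)
    x <- add_bond(x, term, ridx, "ester")
  } else {
    if (site_residue == 1) {
      # head-to-tail: backbone N of the first chain residue
      if (x$residues$class[ridx] != "amino_acid") {
        stop("head-to-tail lactam needs a free backbone amine")
      }
      x$closure <- list(type = "lactam", site_kind = "bbN", site_id = NA,
                        residue = ridx)
    } else {
      cand <- x$nh_sites[x$nh_sites$residue == ridx & x$nh_sites$status == "free", ]
      if (nrow(cand) == 0) {
        stop("residue ", x$residues$name[ridx], " at chain position ",
             site_residue, " has no free side-chain amine for lactamization")
      }
      sid <- cand$site_id[1]
      x$nh_sites$status[x$nh_sites$site_id == sid] <- "amide"
      x$closure <- list(type = "lactam", site_kind = "nh", site_id = sid,
                        residue = ridx)
    }
    x <- add_bond(x, term, ridx, "amide")
  }
  x
}

#' Attach a sugar at a hydroxyl site
#'
#' O-glycosidic attachment of a sugar-code entry at a named free hydroxyl
#' site (see [free_hydroxyl_sites()]), with loss of water.
#'
#' @param x an `np_structure`.
#' @param sugar one row of a [load_sugar_code()] data.frame.
#' @param site_id site to glycosylate (default: first free site).
#' @return glycosylated `np_structure`.
#' @export
attach_sugar <- function(x, sugar, site_id = NULL) {
  free <- free_hydroxyl_sites(x)
  if (nrow(free) == 0) stop("no free hydroxyl available for glycosylation")
  if (is.null(site_id)) site_id <- free$site_id[1]
  if (!site_id %in% free$site_id) stop("hydroxyl site ", site_id, " not free")
  res <- add_residue(x, sugar$name, "sugar", sugar$mass, sugar$attach_smiles)
  x <- res$x
  host <- x$oh_sites$residue[x$oh_sites$site_id == site_id]
  x$oh_sites$status[x$oh_sites$site_id == site_id] <- "glyco"
  x$oh_sites$sugar_residue[x$oh_sites$site_id == site_id] <- res$idx
  add_bond(x, host, res$idx, "glycosidic")
}

#' @keywords internal
#' Expand site markers in a piece for emission. `site_map` maps site ids to
#' replacement strings; unmapped sites expand to their free form.
expand_piece <- function(piece, site_map) {
  m <- gregexpr("\\{(OH|NH2)([0-9]+)\\}", piece)
  toks <- regmatches(piece, m)[[1]]
  for (tok in unique(toks)) {
    sid <- as.integer(sub("\\{(OH|NH2)([0-9]+)\\}", "\\2", tok))
    kind <- sub("\\{(OH|NH2)([0-9]+)\\}", "\\1", tok)
    rep <- if (!is.null(site_map[[as.character(sid)]])) {
      site_map[[as.character(sid)]]
    } else if (kind == "OH") "O" else "N"
    piece <- gsub(tok, rep, piece, fixed = TRUE)
  }
  piece
}

#' @keywords internal
#' Compose raw SMILES for a subset of residues (default: all). `residues`
#' must contain whole chain segments; sugars are embedded at their host
#' hydroxyls. `acyl_cut_end` marks chain residues whose trailing acyl carbon
#' was left as the ketene-equivalent by a cleavage (C(=O) -> =C=O).
compose_smiles <- function(x, residues = NULL, acyl_cut_end = integer(),
                           open_ring = FALSE) {
  if (is.null(residues)) residues <- seq_len(nrow(x$residues))
  chain_res <- x$chain[x$chain %in% residues]
  if (!length(chain_res)) {
    # sugar-only fragment: free reducing sugar
    sug <- residues[x$residues$class[residues] == "sugar"]
    if (length(sug) == 1) return(paste0("O", expand_piece(x$pieces[sug], list())))
    stop("cannot compose SMILES for residue set")
  }
  site_map <- list()
  ring_open <- "%99"
  closed_here <- !is.null(x$closure) && !open_ring &&
    x$closure$residue %in% chain_res &&
    x$chain[length(x$chain)] %in% chain_res
  if (closed_here) {
    if (x$closure$site_kind == "oh") {
      site_map[[as.character(x$closure$site_id)]] <- paste0("O", ring_open)
    } else if (x$closure$site_kind == "nh") {
      site_map[[as.character(x$closure$site_id)]] <- paste0("N", ring_open)
    }
  }
  # glycosylated sites expand to O + sugar fragment (only sugars in subset)
  glyc <- x$oh_sites[x$oh_sites$status == "glyco", , drop = FALSE]
  for (i in seq_len(nrow(glyc))) {
    if (glyc$sugar_residue[i] %in% residues) {
      site_map[[as.character(glyc$site_id[i])]] <-
        paste0("O", expand_piece(x$pieces[glyc$sugar_residue[i]], list()))
    }
    # else: glycosidic bond cut, hydroxyl reverts to its free form
  }
  out <- character()
  for (k in seq_along(chain_res)) {
    r <- chain_res[k]
    piece <- expand_piece(x$pieces[r], site_map)
    if (closed_here && x$closure$site_kind == "bbN" && r == x$closure$residue) {
      piece <- sub("^N", paste0("N", ring_open), piece)
    }
    last <- k == length(chain_res)
    if (last) {
      if (r %in% acyl_cut_end) {
        if (!endsWith(piece, "C(=O)")) stop("no trailing acyl carbon to cut")
        piece <- paste0(substr(piece, 1, nchar(piece) - 5), "=C=O")
      } else if (r == x$chain[length(x$chain)]) {
        if (closed_here) {
          piece <- paste0(substr(piece, 1, nchar(piece) - 5),
                          "C", ring_open, "(=O)")
        } else if (endsWith(piece, "C(=O)")) {
          piece <- paste0(piece, "O")  # free acid release
        }
      }
    } else if (r %in% acyl_cut_end) {
      stop("acyl cut end must terminate a fragment chain")
    }
    out <- c(out, piece)
  }
  paste(out, collapse = "")
}

#' Canonicalize a SMILES string
#'
#' @param smiles SMILES text.
#' @return canonical SMILES (OpenBabel canonical form).
#' @export
smiles_canonical <- function(smiles) {
  out <- ChemmineOB::convertFormat("SMI", "CAN", smiles)
  out <- strsplit(out, "[\t\n]")[[1]][1]
  if (is.na(out) || !nzchar(out)) stop("SMILES canonicalization failed for: ", smiles)
  out
}

#' Monoisotopic mass of a SMILES string
#'
#' Computed with OpenBabel via ChemmineR (independent of the residue-graph
#' bookkeeping).
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector of exact masses (Da).
#' @export
smiles_exact_mass <- function(smiles) {
  vapply(smiles, function(s) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(s))
    unname(ChemmineR::exactMassOB(sdf))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Emit a structure as canonical SMILES and MDL Molfile
#'
#' @param x an `np_structure`.
#' @return list with `smiles` (canonical; R-sites as `[*]` attachment atoms)
#'   and `molfile` (V2000 text).
#' @export
emit_structure <- function(x) {
  raw <- compose_smiles(x)
  can <- smiles_canonical(raw)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))
  molfile <- paste(ChemmineR::sdf2str(sdf[[1]]), collapse = "\n")
  list(smiles = can, molfile = molfile)
}

#' Raw (builder-order) SMILES of a structure
#'
#' @param x an `np_structure`.
#' @return SMILES text in residue order (not canonicalized).
#' @export
structure_smiles <- function(x) compose_smiles(x)
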