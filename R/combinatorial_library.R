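#' @keywords internal
chain_start_acyl <- function(name, table) {
  row <- monomer_row(name, table)
  if (row$class != "fatty_acyl") stop("chain must start with a fatty_acyl, got ", name)
  res <- add_residue(new_structure(), name, "fatty_acyl", row$mass,
                     row$piece_override)
  x <- res$x
  x$chain <- res$idx
  x
}

#' @keywords internal
#' Parse one residue token: "ser", "ser(nMe)", "mmal(KR,DH)".
parse_residue_token <- function(tok) {
  m <- regmatches(tok, regexec("^([A-Za-z0-9_]+)(\\(([^)]*)\\))?$", tok))[[1]]
  if (!length(m)) stop("bad residue token: ", tok)
  name <- m[2]
  ann <- m[4]
  nmeth <- FALSE
  state <- character()
  if (nzchar(ann)) {
    parts <- trimws(strsplit(ann, ",")[[1]])
    if (any(tolower(parts) == "nme")) {
      nmeth <- TRUE
      parts <- parts[tolower(parts) != "nme"]
    }
    state <- toupper(parts[nzchar(parts)])
  }
  list(name = name, nmeth = nmeth, state = state)
}

#' Build a structure from a residue token list
#'
#' Tokens are monomer names, optionally annotated: `ser(nMe)` for an
#' N-methylated residue, `mmal(KR,DH)` for a ketide unit with its reductive
#' state. A fatty-acyl token may only start the chain.
#'
#' @param tokens character vector of residue tokens, or a list from
#'   [parse_residue_token()].
#' @param table monomer table.
#' @return an `np_structure`.
#' @export
build_from_tokens <- function(tokens, table = load_monomer_table()) {
  if (is.character(tokens)) tokens <- lapply(tokens, parse_residue_token)
  x <- NULL
  for (i in seq_along(tokens)) {
    tk <- tokens[[i]]
    cls <- if (tk$name == "X") "amino_acid" else monomer_row(tk$name, table)$class
    if (is.null(x)) {
      x <- switch(cls,
                  amino_acid = extend_peptide(NULL, tk$name, tk$nmeth, table),
                  fatty_acyl = chain_start_acyl(tk$name, table),
                  stop("chain cannot start with a ", cls, " (", tk$name, ")"))
    } else {
      x <- switch(cls,
                  amino_acid = extend_peptide(x, tk$name, tk$nmeth, table),
                  ketide_unit = extend_ketide(x, tk$name, tk$state, table),
                  stop("token ", i, " (", tk$name, "): ", cls,
                       " not allowed mid-chain"))
    }
  }
  x
}

#' Apply a cyclization choice to a structure
#'
#' `"linear"` is the identity; `"lactone@k"` closes an ester to the free
#' hydroxyl of the residue at chain position `k`; `"lactam@k"` closes an
#' amide to a free side-chain amine (or, at position 1, head-to-tail to the
#' backbone nitrogen). Closure loses one water (-18.010565 Da).
#'
#' @param x an `np_structure`.
#' @param choice character, e.g. `"linear"`, `"lactone@2"`.
#' @return the (possibly cyclized) structure.
#' @export
apply_cyclization <- function(x, choice) {
  if (identical(choice, "linear")) return(x)
  m <- regmatches(choice, regexec("^(lactone|lactam)@([0-9]+)$", choice))[[1]]
  if (!length(m)) stop("bad cyclization choice: ", choice)
  close_macrocycle(x, m[2], as.integer(m[3]))
}

#' @keywords internal
#' Parse an axis option: ops joined by "+": "none", "2=ser", "4=mmal(KR)",
#' "glyco:5=angolosamine".
parse_axis_option <- function(opt) {
  opt <- trimws(opt)
  if (opt == "none") return(list(label = "none", ops = list()))
  ops <- lapply(trimws(strsplit(opt, "+", fixed = TRUE)[[1]]), function(op) {
    if (grepl("^glyco:", op)) {
      body <- sub("^glyco:", "", op)
      kv <- strsplit(body, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("bad glycosylation op: ", op)
      list(type = "glyco", pos = as.integer(kv[1]), sugar = kv[2])
    } else {
      kv <- strsplit(op, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("bad substitution op: ", op)
      c(list(type = "sub", pos = as.integer(kv[1])),
        parse_residue_token(kv[2]))
    }
  })
  list(label = opt, ops = ops)
}

#' Read a combinatorialization recipe file
#'
#' Plain-text format, one or more `library` blocks:
#' \preformatted{
#' library thanamycin
#' scaffold thana: c12_oh ser dab asn ser gly phe dhb bohasp clthr
#' axis pos3: 3=dab | 3=orn | 3=arg
#' axis acyl: 1=c12_oh | 1=c12_ohoh | ...
#' cyclization: lactone@2
#' }
#' Axis options are `|`-separated; each option is `none` or `+`-joined ops:
#' `pos=monomer` substitutions (ketide states/N-methyl in parentheses) and
#' `glyco:pos=sugar` glycosylations. `cyclization:` options are `linear`,
#' `lactone@pos`, `lactam@pos` (omitting the line means linear only).
#' `#` starts a comment.
#'
#' @param path recipe file.
#' @return list of library specs (one per `library` block), each with
#'   `name`, `scaffolds` (named list of token vectors), `axes`,
#'   `cyclization`.
#' @export
read_library_recipe <- function(path) {
  if (!file.exists(path)) stop("no such recipe: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  specs <- list()
  cur <- NULL
  flush <- function(cur, specs) {
    if (is.null(cur)) return(specs)
    if (!length(cur$scaffolds)) stop("library block '", cur$name, "' has no scaffold")
    if (!length(cur$cyclization)) cur$cyclization <- "linear"
    c(specs, list(cur))
  }
  for (ln in lines) {
    if (grepl("^library\\b", ln)) {
      specs <- flush(cur, specs)
      cur <- list(name = trimws(sub("^library", "", ln)),
                  scaffolds = list(), axes = list(), cyclization = character())
    } else if (grepl("^scaffold\\b", ln)) {
      if (is.null(cur)) stop("scaffold before any 'library' line")
      body <- sub("^scaffold\\s+", "", ln)
      kv <- strsplit(body, ":", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("bad scaffold line: ", ln)
      cur$scaffolds[[trimws(kv[1])]] <-
        strsplit(trimws(kv[2]), "\\s+")[[1]]
    } else if (grepl("^axis\\b", ln)) {
      body <- sub("^axis\\s+", "", ln)
      if (!grepl(":", body, fixed = TRUE)) stop("bad axis line: ", ln)
      label <- trimws(sub(":.*$", "", body))
      rest <- sub("^[^:]*:", "", body)
      opts <- lapply(strsplit(rest, "|", fixed = TRUE)[[1]], parse_axis_option)
      if (!length(opts)) stop("axis ", label, " has no options")
      if (label %in% vapply(cur$axes, `[[`, "", "label")) {
        stop("duplicate axis label: ", label)
      }
      cur$axes[[length(cur$axes) + 1L]] <- list(label = label, options = opts)
    } else if (grepl("^cyclization\\s*:", ln)) {
      body <- sub("^cyclization\\s*:", "", ln)
      cur$cyclization <- trimws(strsplit(body, "|", fixed = TRUE)[[1]])
    } else {
      stop("unparseable recipe line: ", ln)
    }
  }
  flush(cur, specs)
}

#' Enumerate a combinatorial hypothetical-structure library
#'
#' Full cartesian product over scaffolds x cyclization options x all axis
#' options, in deterministic lexicographic order of provenance, with no
#' canonical-structure deduplication: the library size is exactly
#' `sum over blocks of (#scaffolds x #cyclizations x prod(axis sizes))`.
#'
#' @param spec one library spec or a list of them (from
#'   [read_library_recipe()]).
#' @param table monomer table.
#' @param code sugar code (for `glyco:` ops).
#' @return data.frame with `compound_id`, `smiles`, `neutral_monoisotopic_mass`,
#'   `provenance`, and list-column `structure` (`np_structure` objects).
#' @export
enumerate_library <- function(spec, table = load_monomer_table(),
                              code = load_sugar_code()) {
  if (!is.null(spec$scaffolds)) spec <- list(spec)
  rows <- list()
  for (blk in spec) {
    axis_sizes <- vapply(blk$axes, function(a) length(a$options), integer(1))
    grid_dims <- c(length(blk$scaffolds), length(blk$cyclization), axis_sizes)
    grid <- expand.grid(rev(lapply(grid_dims, seq_len)))
    grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]  # lexicographic
    for (g in seq_len(nrow(grid))) {
      si <- grid[g, 1]; ci <- grid[g, 2]
      opt_idx <- if (length(axis_sizes)) as.integer(grid[g, -(1:2)]) else integer()
      tokens <- lapply(blk$scaffolds[[si]], parse_residue_token)
      glyco_ops <- list()
      for (a in seq_along(blk$axes)) {
        opt <- blk$axes[[a]]$options[[opt_idx[a]]]
        for (op in opt$ops) {
          if (op$type == "sub") {
            if (op$pos > length(tokens)) {
              stop("axis ", blk$axes[[a]]$label, ": position ", op$pos,
                   " beyond scaffold length")
            }
            tokens[[op$pos]] <- op[c("name", "nmeth", "state")]
          } else {
            glyco_ops[[length(glyco_ops) + 1L]] <- op
          }
        }
      }
      x <- build_from_tokens(tokens, table)
      cyc <- blk$cyclization[ci]
      x <- apply_cyclization(x, cyc)
      for (op in glyco_ops) {
        ridx <- x$chain[op$pos]
        free <- free_hydroxyl_sites(x)
        free <- free[free$residue == ridx, , drop = FALSE]
        if (nrow(free) == 0) {
          stop("glycosylation at chain position ", op$pos,
               ": no free hydroxyl on ", x$residues$name[ridx])
        }
        sug <- code[code$name == op$sugar, , drop = FALSE]
        if (nrow(sug) == 0) stop("sugar not in code: ", op$sugar)
        x <- attach_sugar(x, sug, free$site_id[1])
      }
      prov <- paste0(blk$name, "/", names(blk$scaffolds)[si], "/", cyc,
                     if (length(opt_idx)) paste0(
                       "/", paste(vapply(seq_along(blk$axes), function(a) {
                         paste0(blk$axes[[a]]$label, "=",
                                blk$axes[[a]]$options[[opt_idx[a]]]$label)
                       }, character(1)), collapse = "/")) else "")
      x$provenance$recipe <- prov
      rows[[length(rows) + 1L]] <- list(
        compound_id = sprintf("%s_%04d", blk$name, g),
        smiles = compose_smiles(x),
        neutral_monoisotopic_mass = structure_mass(x),
        provenance = prov, structure = x)
    }
  }
  out <- data.frame(
    compound_id = vapply(rows, `[[`, "", "compound_id"),
    smiles = vapply(rows, `[[`, "", "smiles"),
    neutral_monoisotopic_mass = vapply(rows, `[[`, 0, "neutral_monoisotopic_mass"),
    provenance = vapply(rows, `[[`, "", "provenance"),
    stringsAsFactors = FALSE)
  out$structure <- lapply(rows, `[[`, "structure")
  out
}

#' @keywords internal
serialize_structure <- function(x) {
  jsonlite::toJSON(list(
    residues = x$residues, pieces = x$pieces, chain = x$chain,
    bonds = x$bonds, oh_sites = x$oh_sites, nh_sites = x$nh_sites,
    closure = x$closure, n_rsites = x$n_rsites), digits = NA, auto_unbox = TRUE)
}

#' @keywords internal
deserialize_structure <- function(json) {
  l <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  x <- new_structure()
  for (f in c("residues", "bonds", "oh_sites", "nh_sites")) {
    if (length(l[[f]])) x[[f]] <- as.data.frame(l[[f]], stringsAsFactors = FALSE)
  }
  x$pieces <- as.character(l$pieces)
  x$chain <- as.integer(l$chain)
  x$n_rsites <- as.integer(l$n_rsites)
  if (!is.null(l$closure) && length(l$closure)) {
    cl <- l$closure
    cl$residue <- as.integer(cl$residue)
    if (!is.null(cl$site_id) && !all(is.na(cl$site_id))) {
      cl$site_id <- as.integer(cl$site_id)
    }
    x$closure <- cl
  }
  x
}

#' Write a structure library as TSV
#'
#' Columns: `compound_id`, `smiles`, `mass`, and a serialized residue graph
#' (`graph`) that lets [load_structure_library()] restore full fragmentation
#' support.
#'
#' @param lib data.frame from [enumerate_library()] (or with compatible
#'   columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_library <- function(lib, path) {
  graph <- if (!is.null(lib$structure)) {
    vapply(lib$structure, function(s) as.character(serialize_structure(s)), "")
  } else ""
  df <- data.frame(compound_id = lib$compound_id, smiles = lib$smiles,
                   mass = lib$neutral_monoisotopic_mass, graph = graph,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a structure library
#'
#' Accepts either the package's own TSV (with header and serialized residue
#' graphs, restoring full in-silico fragmentation) or a plain headerless
#' `id TAB smiles` list, in which case neutral masses are computed from the
#' SMILES (OpenBabel) and only precursor-level matching plus neutral losses
#' are available for those entries. Unparseable SMILES are skipped with a
#' line-level warning.
#'
#' @param path library file.
#' @return data.frame like [enumerate_library()]'s output (`structure` may
#'   contain `NULL` for graph-less entries).
#' @export
load_structure_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  if (!length(first)) stop("empty structure library: ", path)
  if (grepl("^compound_id\t", first)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
    structures <- lapply(df$graph, function(g) {
      if (is.na(g) || !nzchar(g)) NULL else deserialize_structure(g)
    })
    out <- data.frame(compound_id = df$compound_id, smiles = df$smiles,
                      neutral_monoisotopic_mass = df$mass,
                      provenance = paste0("file:", basename(path)),
                      stringsAsFactors = FALSE)
    out$structure <- structures
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty structure library: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(parts, length, 0L) >= 2
    if (any(!keep)) warning("skipping ", sum(!keep), " malformed line(s)")
    parts <- parts[keep]
    ids <- vapply(parts, `[[`, "", 1)
    smi <- vapply(parts, `[[`, "", 2)
    mass <- rep(NA_real_, length(smi))
    ok <- logical(length(smi))
    for (i in seq_along(smi)) {
      m <- tryCatch(smiles_exact_mass(smi[i]), error = function(e) NA_real_)
      mass[i] <- m
      ok[i] <- !is.na(m)
    }
    if (any(!ok)) {
      warning("unparseable SMILES skipped: ",
              paste(ids[!ok], collapse = ", "))
    }
    out <- data.frame(compound_id = ids[ok], smiles = smi[ok],
                      neutral_monoisotopic_mass = mass[ok],
                      provenance = paste0("file:", basename(path)),
                      stringsAsFactors = FALSE)
    out$structure <- vector("list", nrow(out))
  }
  if (nrow(out) == 0) stop("no usable candidates in ", path)
  out
}
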