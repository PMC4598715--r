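#' Domain family enumeration
#' @keywords internal
.DOMAIN_FAMILIES <- c("ADENYLATION", "CONDENSATION", "THIOLATION",
                      "KETOSYNTHASE", "ACYLTRANSFERASE", "KETOREDUCTASE",
                      "DEHYDRATASE", "ENOYLREDUCTASE", "THIOESTERASE",
                      "N_METHYLTRANSFERASE", "GLYCOSYLTRANSFERASE",
                      "SUGAR_GENE", "OTHER_TAILORING")

#' Bitscore cutoff profile for domain ingestion
#'
#' Four adjustable significance cutoffs: adenylation, acyltransferase,
#' thiolation/thioesterase, and everything else.
#'
#' @param adenylation,acyltransferase,thiolation_thioesterase,other cutoffs in
#'   bits (all >= 0).
#' @return a `cutoff_profile` list.
#' @export
cutoff_profile <- function(adenylation = 25, acyltransferase = 25,
                           thiolation_thioesterase = 15, other = 20) {
  vals <- c(adenylation, acyltransferase, thiolation_thioesterase, other)
  if (any(vals < 0)) stop("cutoffs must be >= 0")
  structure(list(adenylation = adenylation,
                 acyltransferase = acyltransferase,
                 thiolation_thioesterase = thiolation_thioesterase,
                 other = other),
            class = "cutoff_profile")
}

#' @keywords internal
cutoff_for_family <- function(family, cutoffs) {
  switch(family,
         ADENYLATION = cutoffs$adenylation,
         ACYLTRANSFERASE = cutoffs$acyltransferase,
         THIOLATION = ,
         THIOESTERASE = cutoffs$thiolation_thioesterase,
         cutoffs$other)
}

#' Default model-name to domain-family mapping
#'
#' Maps the model names used by the packaged fixtures (PFAM/SMART-style
#' names for assembly-line domains, plus the sugar-gene family models) to
#' typed domain families. Unmapped models are treated as `OTHER_TAILORING`
#' by [ingest_domain_hits()].
#'
#' @param sugar_code optional sugar code (adds each gene family name as a
#'   `SUGAR_GENE` model).
#' @return named character vector (model name -> family).
#' @export
default_family_map <- function(sugar_code = NULL) {
  map <- c(
    "AMP-binding" = "ADENYLATION",
    "Condensation" = "CONDENSATION",
    "PP-binding" = "THIOLATION",
    "PKS_KS" = "KETOSYNTHASE",
    "PKS_AT" = "ACYLTRANSFERASE",
    "PKS_KR" = "KETOREDUCTASE",
    "PKS_DH" = "DEHYDRATASE",
    "PKS_ER" = "ENOYLREDUCTASE",
    "Thioesterase" = "THIOESTERASE",
    "nMT" = "N_METHYLTRANSFERASE",
    "Glycos_transf" = "GLYCOSYLTRANSFERASE")
  if (!is.null(sugar_code)) {
    fams <- sugar_gene_families(sugar_code)
    map <- c(map, stats::setNames(rep("SUGAR_GENE", length(fams)), fams))
  }
  map
}

#' Parse a HMMER3 domtblout file
#'
#' Column-exact parse of `hmmsearch --domtblout` output (target = protein,
#' query = model). Uses the per-domain score and alignment coordinates.
#'
#' @param path path to a domtblout file.
#' @return data.frame with `orf_id`, `model_name`, `bitscore`, `ali_start`,
#'   `ali_end`.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22) {
      stop("malformed domtblout line ", lineno[i], ": expected >= 22 fields, got ",
           length(f))
    }
    score <- suppressWarnings(as.numeric(f[14]))
    a1 <- suppressWarnings(as.integer(f[18]))
    a2 <- suppressWarnings(as.integer(f[19]))
    if (is.na(score) || is.na(a1) || is.na(a2)) {
      stop("malformed domtblout line ", lineno[i], ": non-numeric score/coords")
    }
    data.frame(orf_id = f[1], model_name = f[4], bitscore = score,
               ali_start = a1, ali_end = a2, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(orf_id = character(), model_name = character(),
                      bitscore = numeric(), ali_start = integer(),
                      ali_end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Ingest domain hits with class-specific cutoffs and overlap merging
#'
#' Drops hits below the cutoff of their domain class and merges overlapping
#' hits of the same family on one protein (overlap > 30% of the shorter hit),
#' keeping the higher bitscore and the union span. Output is sorted by
#' `(orf_id, ali_start)`.
#'
#' @param domtbl path to a HMMER3 domtblout file, or a data.frame from
#'   [read_domtblout()].
#' @param cutoffs a [cutoff_profile()].
#' @param family_map named character vector mapping model names to families;
#'   unmapped models become `OTHER_TAILORING`.
#' @return data.frame of domain hits with columns `orf_id`, `family`,
#'   `model_name`, `bitscore`, `ali_start`, `ali_end`, `sugar_family`,
#'   `substrate`, and list-column `substrate_calls`.
#' @export
ingest_domain_hits <- function(domtbl, cutoffs = cutoff_profile(),
                               family_map = default_family_map()) {
  hits <- if (is.character(domtbl)) read_domtblout(domtbl) else domtbl
  hits$family <- unname(family_map[hits$model_name])
  hits$family[is.na(hits$family)] <- "OTHER_TAILORING"
  thr <- vapply(hits$family, cutoff_for_family, numeric(1), cutoffs = cutoffs)
  hits <- hits[hits$bitscore >= thr, , drop = FALSE]
  hits$sugar_family <- NA_character_
  hits$substrate <- NA_character_
  hits$substrate_calls <- replicate(nrow(hits), NULL, simplify = FALSE)
  if (!nrow(hits)) return(hits[order(hits$orf_id), , drop = FALSE])
  merged <- do.call(rbind, lapply(
    split(hits, list(hits$orf_id, hits$family), drop = TRUE),
    merge_family_hits))
  merged <- merged[order(merged$orf_id, merged$ali_start, merged$ali_end), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' @keywords internal
merge_family_hits <- function(grp, min_overlap = 0.3) {
  grp <- grp[order(grp$ali_start, grp$ali_end), , drop = FALSE]
  out <- grp[1, , drop = FALSE]
  if (nrow(grp) == 1) return(out)
  for (i in 2:nrow(grp)) {
    cur <- out[nrow(out), , drop = FALSE]
    nxt <- grp[i, , drop = FALSE]
    ov <- min(cur$ali_end, nxt$ali_end) - max(cur$ali_start, nxt$ali_start) + 1
    shorter <- min(cur$ali_end - cur$ali_start, nxt$ali_end - nxt$ali_start) + 1
    if (ov > min_overlap * shorter) {
      win <- if (nxt$bitscore > cur$bitscore) nxt else cur
      win$ali_start <- min(cur$ali_start, nxt$ali_start)
      win$ali_end <- max(cur$ali_end, nxt$ali_end)
      out[nrow(out), ] <- win
    } else {
      out <- rbind(out, nxt)
    }
  }
  out
}

#' Attach ranked substrate calls to an adenylation or acyltransferase hit
#'
#' Substrate model names encode the monomer after an underscore (`"A_ser"`,
#' `"AT_mmal"`). Calls are ranked by bitscore, ties broken alphabetically.
#' With no substrate hits the domain is flagged unknown and the top substrate
#' is the wildcard `"X"`.
#'
#' @param hit one row of an [ingest_domain_hits()] data.frame with family
#'   `ADENYLATION` or `ACYLTRANSFERASE`.
#' @param substrate_hits data.frame with columns `model_name`, `bitscore` (may
#'   have zero rows).
#' @return the hit row with `substrate` and `substrate_calls` populated.
#' @export
call_adenylation_substrates <- function(hit, substrate_hits) {
  if (!hit$family %in% c("ADENYLATION", "ACYLTRANSFERASE")) {
    stop("substrate calls apply to ADENYLATION/ACYLTRANSFERASE hits, got ",
         hit$family)
  }
  if (is.null(substrate_hits) || nrow(substrate_hits) == 0) {
    hit$substrate <- "X"
    hit$substrate_calls <- list(data.frame(substrate = character(),
                                           bitscore = numeric()))
    attr(hit, "unknown_substrate") <- TRUE
    return(hit)
  }
  sub <- sub("^[A-Za-z]+_", "", substrate_hits$model_name)
  calls <- data.frame(substrate = sub, bitscore = substrate_hits$bitscore,
                      stringsAsFactors = FALSE)
  calls <- calls[order(-calls$bitscore, calls$substrate), , drop = FALSE]
  rownames(calls) <- NULL
  hit$substrate <- calls$substrate[1]
  hit$substrate_calls <- list(calls)
  hit
}

#' Label sugar-pathway gene hits with their family
#'
#' Hits on models named in `sugar_family_models` become `SUGAR_GENE` hits
#' carrying exactly one family (including the UDP-glucose
#' dehydrogenase/decarboxylase pentose-pathway families). Other hits pass
#' through unchanged.
#'
#' @param hits data.frame from [ingest_domain_hits()].
#' @param sugar_family_models named character vector mapping model names to
#'   sugar-gene family names; defaults to the identity map over the packaged
#'   code's families.
#' @return the hits with `family`/`sugar_family` updated.
#' @export
classify_sugar_genes <- function(hits, sugar_family_models = NULL) {
  if (is.null(sugar_family_models)) {
    fams <- sugar_gene_families(load_sugar_code())
    sugar_family_models <- stats::setNames(fams, fams)
  }
  if (is.null(names(sugar_family_models))) {
    stop("sugar_family_models must be a named mapping (model -> family)")
  }
  idx <- hits$model_name %in% names(sugar_family_models)
  hits$family[idx] <- "SUGAR_GENE"
  hits$sugar_family[idx] <- unname(sugar_family_models[hits$model_name[idx]])
  hits
}

#' @keywords internal
.HEXOSE_IDENTITIES <- c("glucose", "mannose", "gulose", "n_acetylglucosamine")

#' Assign a glycosyltransferase substrate class from homology results
#'
#' The single top-scoring homology hit determines whether the
#' glycosyltransferase transfers a hexose (glucose, mannose, gulose or
#' N-acetylglucosamine) or a deoxysugar. Score ties break to the
#' alphabetically earlier reference. With no homology results the call
#' defaults conservatively to `DEOXYSUGAR` (keeping the enzyme in the
#' deoxysugar slot count) with a warning.
#'
#' @param orf_id id of the glycosyltransferase protein.
#' @param homology_results data.frame with columns `reference_name`, `score`,
#'   `reference_substrate`.
#' @return one-row data.frame: `orf_id`, `substrate_class`, `hexose_identity`,
#'   `top_hit`, `top_score`.
#' @export
assign_gt_substrate <- function(orf_id, homology_results) {
  if (is.null(homology_results) || nrow(homology_results) == 0) {
    warning("no homology results for glycosyltransferase ", orf_id,
            "; defaulting to DEOXYSUGAR")
    return(data.frame(orf_id = orf_id, substrate_class = "DEOXYSUGAR",
                      hexose_identity = NA_character_, top_hit = NA_character_,
                      top_score = NA_real_, stringsAsFactors = FALSE))
  }
  h <- homology_results[order(-homology_results$score,
                              homology_results$reference_name), , drop = FALSE]
  top <- h[1, ]
  subst <- tolower(top$reference_substrate)
  subst <- gsub("-", "_", subst)
  is_hex <- subst %in% .HEXOSE_IDENTITIES
  data.frame(orf_id = orf_id,
             substrate_class = if (is_hex) "HEXOSE" else "DEOXYSUGAR",
             hexose_identity = if (is_hex) subst else NA_character_,
             top_hit = top$reference_name, top_score = top$score,
             stringsAsFactors = FALSE)
}

#' Read a tabular homology-hit file
#'
#' Plain TSV with columns `query`, `reference`, `score`, `substrate`; used
#' both for adenylation/acyltransferase substrate calls and for
#' glycosyltransferase substrate assignment.
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_homology_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("query", "reference", "score", "substrate")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("homology table missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}
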