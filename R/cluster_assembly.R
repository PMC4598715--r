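#' Clustering settings
#'
#' @param max_gene_gap maximum gap in bp between consecutive annotated genes
#'   for them to join one cluster (default 10000).
#' @return a `cluster_settings` list.
#' @export
cluster_settings <- function(max_gene_gap = 10000) {
  if (max_gene_gap <= 0) stop("max_gene_gap must be > 0")
  structure(list(max_gene_gap = max_gene_gap), class = "cluster_settings")
}

#' Group annotated genes into putative biosynthetic clusters
#'
#' Greedy single-pass scan per contig: a new cluster starts whenever the gap
#' from the end of the previous annotated gene to the start of the next
#' exceeds `max_gene_gap`. Only genes carrying at least one domain hit are
#' considered annotated. Genes without coordinates (protein-FASTA mode,
#' `start` missing) are all placed in a single cluster.
#'
#' @param orfs data.frame of genes (`orf_id`, `contig_id`, `start`, `end`);
#'   `start`/`end` may be `NA` in protein mode.
#' @param hits domain-hit data.frame from [ingest_domain_hits()].
#' @param settings a [cluster_settings()].
#' @return list of clusters, each a list with `cluster_id`, `contig_id`,
#'   `orf_ids` (genomic order), `span` (`c(start, end)` or `NA`), `hits`.
#' @export
group_into_clusters <- function(orfs, hits, settings = cluster_settings()) {
  ann <- orfs[orfs$orf_id %in% unique(hits$orf_id), , drop = FALSE]
  if (nrow(ann) == 0) return(list())
  mk <- function(sub, cid) {
    list(cluster_id = cid,
         contig_id = sub$contig_id[1],
         orf_ids = sub$orf_id,
         span = if (all(is.na(sub$start))) c(NA_integer_, NA_integer_)
                else c(min(sub$start), max(sub$end)),
         hits = hits[hits$orf_id %in% sub$orf_id, , drop = FALSE])
  }
  clusters <- list()
  if (all(is.na(ann$start))) {
    # protein mode: no location information, one cluster for the whole file
    clusters[[1]] <- mk(ann, "cluster001")
    return(clusters)
  }
  k <- 0L
  for (contig in unique(ann$contig_id)) {
    sub <- ann[ann$contig_id == contig, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    gap_break <- c(FALSE, sub$start[-1] - sub$end[-nrow(sub)] >
                     settings$max_gene_gap)
    grp <- cumsum(gap_break)
    for (g in unique(grp)) {
      k <- k + 1L
      clusters[[k]] <- mk(sub[grp == g, , drop = FALSE],
                          sprintf("cluster%03d", k))
    }
  }
  clusters
}

#' Discard clusters lacking core assembly-line domains
#'
#' A cluster survives only if it contains at least one adenylation or
#' acyltransferase domain AND at least one condensation or ketosynthase
#' domain.
#'
#' @param clusters list from [group_into_clusters()].
#' @return filtered list.
#' @export
filter_clusters <- function(clusters) {
  Filter(function(cl) {
    fams <- cl$hits$family
    any(fams %in% c("ADENYLATION", "ACYLTRANSFERASE")) &&
      any(fams %in% c("CONDENSATION", "KETOSYNTHASE"))
  }, clusters)
}

#' @keywords internal
.DOMAIN_ABBREV <- c(ADENYLATION = "A", CONDENSATION = "C", THIOLATION = "T",
                    KETOSYNTHASE = "KS", ACYLTRANSFERASE = "AT",
                    KETOREDUCTASE = "KR", DEHYDRATASE = "DH",
                    ENOYLREDUCTASE = "ER", THIOESTERASE = "TE",
                    N_METHYLTRANSFERASE = "nMT",
                    GLYCOSYLTRANSFERASE = "GT", SUGAR_GENE = "SUG",
                    OTHER_TAILORING = "X")

#' Render a cluster's domain string
#'
#' Genes in genomic order joined by `" | "`, domains within each gene in
#' translation order, substrates in parentheses (e.g.
#' `"C-A(ser)-T | C-A(val)-nMT-T | TE"`).
#'
#' @param cluster one cluster from [group_into_clusters()].
#' @return character scalar.
#' @export
domain_string <- function(cluster) {
  per_gene <- vapply(cluster$orf_ids, function(oid) {
    h <- cluster$hits[cluster$hits$orf_id == oid, , drop = FALSE]
    h <- h[order(h$ali_start), , drop = FALSE]
    lab <- .DOMAIN_ABBREV[h$family]
    sub <- ifelse(h$family %in% c("ADENYLATION", "ACYLTRANSFERASE") &
                    !is.na(h$substrate), paste0("(", h$substrate, ")"),
                  ifelse(h$family == "SUGAR_GENE" & !is.na(h$sugar_family),
                         paste0("(", h$sugar_family, ")"), ""))
    paste(paste0(lab, sub), collapse = "-")
  }, character(1))
  paste(per_gene, collapse = " | ")
}

#' Parse a cluster's domain architecture into ordered assembly-line modules
#'
#' Scans the concatenated domain string gene by gene in genomic order.
#' Each condensation-to-thiolation span with an intervening adenylation
#' domain becomes one NRPS module; each ketosynthase-to-thiolation span with
#' an intervening acyltransferase domain becomes one PKS module. A leading
#' adenylation-thiolation span before any condensation/ketosynthase is the
#' initiation module. KR/DH/ER inside a PKS span populate the reductive
#' state; an N-methyltransferase inside an NRPS span sets `n_methylated`.
#' A condensation domain opening module 1 flags starter acylation
#' (lipopeptide-type initiation). Standalone adenylation-thiolation didomain
#' genes (no condensation/ketosynthase on the same gene) are surfaced with
#' `trans_acting = TRUE` and are never placed into the chain automatically.
#'
#' @param cluster a cluster that passed [filter_clusters()].
#' @return data.frame of modules: `index`, `kind`, `substrate`,
#'   `reductive_state` (comma-joined subset of KR,DH,ER), `n_methylated`,
#'   `is_starter`, `trans_acting`, `orf_ids`.
#' @export
define_modules <- function(cluster) {
  empty <- data.frame(index = integer(), kind = character(),
                      substrate = character(), reductive_state = character(),
                      n_methylated = logical(), is_starter = logical(),
                      trans_acting = logical(), orf_ids = character(),
                      stringsAsFactors = FALSE)
  h <- cluster$hits
  if (is.null(h) || nrow(h) == 0) {
    message("cluster ", cluster$cluster_id, ": no domains, no modules")
    return(empty)
  }
  # domains in assembly-line order: genes by genomic order, then ali_start
  ord <- order(match(h$orf_id, cluster$orf_ids), h$ali_start)
  h <- h[ord, , drop = FALSE]

  # trans-acting A-T didomain genes: A and T present, no C/KS on the gene
  trans_rows <- list()
  trans_orfs <- character()
  for (oid in cluster$orf_ids) {
    fams <- h$family[h$orf_id == oid]
    if (any(fams == "ADENYLATION") && any(fams == "THIOLATION") &&
        !any(fams %in% c("CONDENSATION", "KETOSYNTHASE"))) {
      sub <- h$substrate[h$orf_id == oid & h$family == "ADENYLATION"][1]
      trans_orfs <- c(trans_orfs, oid)
      trans_rows[[length(trans_rows) + 1L]] <- data.frame(
        index = NA_integer_, kind = "NRPS",
        substrate = if (is.na(sub)) "X" else sub,
        reductive_state = "", n_methylated = FALSE, is_starter = FALSE,
        trans_acting = TRUE, orf_ids = oid, stringsAsFactors = FALSE)
    }
  }
  chain <- h[!h$orf_id %in% trans_orfs, , drop = FALSE]

  mods <- list()
  fam <- chain$family
  n <- length(fam)
  i <- 1L
  first_anchor <- TRUE
  while (i <= n) {
    f <- fam[i]
    if (f %in% c("CONDENSATION", "KETOSYNTHASE")) {
      t_idx <- which(fam == "THIOLATION" & seq_len(n) > i)
      if (!length(t_idx)) break
      j <- t_idx[1]
      span <- chain[i:j, , drop = FALSE]
      want <- if (f == "CONDENSATION") "ADENYLATION" else "ACYLTRANSFERASE"
      if (any(span$family == want)) {
        mods[[length(mods) + 1L]] <- span_to_module(
          span, kind = if (f == "CONDENSATION") "NRPS" else "PKS",
          is_starter = first_anchor && i == 1L && f == "CONDENSATION")
      }
      first_anchor <- FALSE
      i <- j + 1L
    } else if (f == "ADENYLATION" && first_anchor) {
      # initiation module without a leading condensation domain
      t_idx <- which(fam == "THIOLATION" & seq_len(n) >= i)
      if (!length(t_idx)) break
      j <- t_idx[1]
      mods[[length(mods) + 1L]] <- span_to_module(chain[i:j, , drop = FALSE],
                                                  kind = "NRPS",
                                                  is_starter = FALSE)
      first_anchor <- FALSE
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out <- rbind(
    if (length(mods)) do.call(rbind, mods) else empty,
    if (length(trans_rows)) do.call(rbind, trans_rows) else empty)
  if (nrow(out) == 0) {
    message("cluster ", cluster$cluster_id,
            ": no modules recoverable from domain string")
    return(empty)
  }
  in_chain <- !out$trans_acting
  out$index[in_chain] <- seq_len(sum(in_chain))
  rownames(out) <- NULL
  out
}

#' @keywords internal
span_to_module <- function(span, kind, is_starter) {
  red <- c("KR", "DH", "ER")[c(any(span$family == "KETOREDUCTASE"),
                               any(span$family == "DEHYDRATASE"),
                               any(span$family == "ENOYLREDUCTASE"))]
  sel <- if (kind == "NRPS") "ADENYLATION" else "ACYLTRANSFERASE"
  sub <- span$substrate[span$family == sel][1]
  data.frame(index = NA_integer_, kind = kind,
             substrate = if (is.na(sub)) "X" else sub,
             reductive_state = if (kind == "PKS") paste(red, collapse = ",") else "",
             n_methylated = kind == "NRPS" &&
               any(span$family == "N_METHYLTRANSFERASE"),
             is_starter = is_starter, trans_acting = FALSE,
             orf_ids = paste(unique(span$orf_id), collapse = ","),
             stringsAsFactors = FALSE)
}
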