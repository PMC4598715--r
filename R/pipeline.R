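#' Genome search: sequences to annotated clusters, modules and scaffolds
#'
#' The glue of the genome-search mode. DNA records are scanned for ORFs (for
#' whole genomes, supply pre-called proteins instead: gene calling is
#' delegated); protein records are used directly, with coordinates from
#' `gene_coords` when available (otherwise the whole file forms one
#' cluster). Domain hits come from a HMMER3 domtblout; substrate and
#' glycosyltransferase calls from a homology TSV whose `query` is either the
#' protein id or `id:ali_start` for domain-level assignment.
#'
#' @param fasta_path FASTA of DNA (clusters/contigs) or proteins.
#' @param domtbl_path HMMER3 domtblout for the (translated) proteins.
#' @param homology_path optional homology TSV (`query`, `reference`,
#'   `score`, `substrate`).
#' @param gene_coords optional data.frame (`orf_id`, `contig_id`, `start`,
#'   `end`) for protein-mode coordinates.
#' @param cutoffs a [cutoff_profile()].
#' @param settings a [cluster_settings()].
#' @param family_map model-to-family map (default includes the packaged
#'   sugar code's families).
#' @param sugar_code sugar code for deoxysugar prediction.
#' @param table monomer table.
#' @param min_aa minimum ORF length (DNA mode).
#' @return list of per-cluster results: `cluster`, `domain_string`,
#'   `modules`, `scaffold` (an `np_structure`, or `NULL` when no modules),
#'   `gt_calls`, `sugar_assignment` (or `NULL`).
#' @export
search_genome <- function(fasta_path, domtbl_path, homology_path = NULL,
                          gene_coords = NULL,
                          cutoffs = cutoff_profile(),
                          settings = cluster_settings(),
                          family_map = default_family_map(load_sugar_code()),
                          sugar_code = load_sugar_code(),
                          table = load_monomer_table(), min_aa = 50) {
  recs <- read_fasta(fasta_path)
  if (all(recs$alphabet == "dna")) {
    orfs <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i) {
      find_orfs(recs[i, ], min_aa = min_aa)
    }))
  } else if (all(recs$alphabet == "protein")) {
    orfs <- data.frame(orf_id = recs$id, contig_id = "protein_input",
                       start = NA_integer_, end = NA_integer_,
                       strand = "+", frame = 0L, protein = recs$residues,
                       stringsAsFactors = FALSE)
    if (!is.null(gene_coords)) {
      m <- match(orfs$orf_id, gene_coords$orf_id)
      orfs$contig_id <- gene_coords$contig_id[m]
      orfs$start <- gene_coords$start[m]
      orfs$end <- gene_coords$end[m]
    }
  } else {
    stop("mixed DNA/protein FASTA not supported")
  }
  hits <- ingest_domain_hits(domtbl_path, cutoffs, family_map)
  hits <- classify_sugar_genes(hits, {
    fams <- sugar_gene_families(sugar_code)
    stats::setNames(fams, fams)
  })
  hom <- if (!is.null(homology_path)) read_homology_tsv(homology_path) else NULL
  hits <- attach_substrate_calls(hits, hom)
  clusters <- filter_clusters(group_into_clusters(orfs, hits, settings))
  lapply(clusters, function(cl) {
    mods <- define_modules(cl)
    scaffold <- if (nrow(mods[!mods$trans_acting, , drop = FALSE])) {
      build_scaffold(mods, table)
    } else NULL
    gt_calls <- cluster_gt_calls(cl, hom)
    fams <- unique(stats::na.omit(cl$hits$sugar_family))
    assignment <- if (count_sugar_slots(gt_calls) > 0) {
      predict_sugars(fams, gt_calls, sugar_code)
    } else NULL
    list(cluster = cl, domain_string = domain_string(cl), modules = mods,
         scaffold = scaffold, gt_calls = gt_calls,
         sugar_assignment = assignment)
  })
}

#' @keywords internal
#' Attach substrate calls from a homology table to every A/AT hit.
attach_substrate_calls <- function(hits, hom) {
  if (is.null(hom)) return(hits)
  idx <- which(hits$family %in% c("ADENYLATION", "ACYLTRANSFERASE"))
  for (i in idx) {
    keys <- c(paste0(hits$orf_id[i], ":", hits$ali_start[i]), hits$orf_id[i])
    rows <- hom[hom$query %in% keys & grepl("^(A|AT)_", hom$reference), ,
                drop = FALSE]
    sub_hits <- data.frame(model_name = rows$reference,
                           bitscore = rows$score, stringsAsFactors = FALSE)
    hits[i, ] <- suppressWarnings(
      call_adenylation_substrates(hits[i, , drop = FALSE], sub_hits))
  }
  hits
}

#' @keywords internal
#' Glycosyltransferase substrate calls for the GT hits of one cluster.
cluster_gt_calls <- function(cluster, hom) {
  gt <- cluster$hits[cluster$hits$family == "GLYCOSYLTRANSFERASE", ,
                     drop = FALSE]
  if (!nrow(gt)) {
    return(data.frame(orf_id = character(), substrate_class = character(),
                      hexose_identity = character(), top_hit = character(),
                      top_score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(gt)), function(i) {
    res <- if (!is.null(hom)) {
      keys <- c(paste0(gt$orf_id[i], ":", gt$ali_start[i]), gt$orf_id[i])
      rows <- hom[hom$query %in% keys & grepl("^gtdb_", hom$reference), ,
                  drop = FALSE]
      if (nrow(rows)) {
        data.frame(reference_name = rows$reference, score = rows$score,
                   reference_substrate = rows$substrate,
                   stringsAsFactors = FALSE)
      } else NULL
    } else NULL
    suppressWarnings(assign_gt_substrate(gt$orf_id[i], res))
  }))
}

#' Cluster report as JSON
#'
#' @param result one element of [search_genome()]'s result list.
#' @return JSON text (cluster span, genes, domain string, module table).
#' @export
cluster_report_json <- function(result) {
  jsonlite::toJSON(list(
    cluster_id = result$cluster$cluster_id,
    contig_id = result$cluster$contig_id,
    span = result$cluster$span,
    genes = result$cluster$orf_ids,
    domain_string = result$domain_string,
    modules = result$modules,
    scaffold_smiles = if (!is.null(result$scaffold)) {
      tryCatch(compose_smiles(result$scaffold), error = function(e) NA)
    } else NA,
    sugars = if (!is.null(result$sugar_assignment)) {
      result$sugar_assignment[c("n_slots", "sugars", "missing_genes",
                                "extra_genes", "hexoses")]
    } else NULL
  ), auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
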