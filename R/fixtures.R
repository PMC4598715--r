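#' @keywords internal
.FIXTURE_MODELS <- c(C = "Condensation", A = "AMP-binding", T = "PP-binding",
                     KS = "PKS_KS", AT = "PKS_AT", KR = "PKS_KR",
                     DH = "PKS_DH", ER = "PKS_ER", TE = "Thioesterase",
                     nMT = "nMT", GT = "Glycos_transf")

#' Generate a synthetic annotated-cluster fixture
#'
#' Writes a protein FASTA, a gene-coordinate table, a HMMER3-format
#' domtblout and a homology TSV that, run through the annotation and
#' clustering modules, reproduce the recipe's module list exactly. The
#' recipe is a domain string with genes separated by `|`, e.g.
#' `"C-A(ser)-T | C-A(val)-nMT-T | TE"`; `A(x)`/`AT(x)` carry substrate
#' calls, `GT` and `GT(hexose:mannose)` are glycosyltransferases,
#' `SUG(family)` a sugar-pathway gene. A standalone `A(x)-T` gene is a
#' trans-acting didomain.
#'
#' @param recipe domain-string recipe.
#' @param out_dir output directory (created).
#' @param seed integer seed (protein sequence content).
#' @param gene_gaps bp gaps between consecutive genes (recycled; default
#'   500).
#' @param bitscore bitscore written for every domain hit.
#' @param contig_id contig name for the coordinate table.
#' @return invisible list of paths: `proteins`, `genes`, `domtbl`,
#'   `homology`.
#' @export
make_cluster_fixture <- function(recipe, out_dir, seed = 1, gene_gaps = 500,
                                 bitscore = 80, contig_id = "ctg1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- trimws(strsplit(recipe, "|", fixed = TRUE)[[1]])
  if (!length(genes)) stop("empty cluster recipe")
  gene_gaps <- rep_len(gene_gaps, max(length(genes) - 1, 1))
  aa_pool <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  fasta <- character(); coords <- list(); dom_lines <- character()
  hom_rows <- list()
  pos <- 0L
  with_seed(seed, {
    for (gi in seq_along(genes)) {
      toks <- trimws(strsplit(genes[gi], "-", fixed = TRUE)[[1]])
      orf <- sprintf("orf%02d", gi)
      plen <- 110L * length(toks) + 20L
      prot <- paste(sample(aa_pool, plen, replace = TRUE), collapse = "")
      fasta <- c(fasta, paste0(">", orf), prot)
      start <- pos
      end <- pos + plen * 3L + 3L
      coords[[gi]] <- data.frame(orf_id = orf, contig_id = contig_id,
                                 start = start, end = end,
                                 stringsAsFactors = FALSE)
      pos <- end + if (gi <= length(gene_gaps)) gene_gaps[gi] else 500L
      for (di in seq_along(toks)) {
        m <- regmatches(toks[di],
                        regexec("^([A-Za-z]+)(\\(([^)]*)\\))?$", toks[di]))[[1]]
        if (!length(m)) stop("bad domain token at gene ", gi, ": ", toks[di])
        key <- m[2]; ann <- m[4]
        model <- if (key == "SUG") {
          if (!nzchar(ann)) stop("SUG needs a family, gene ", gi)
          ann
        } else {
          mod <- .FIXTURE_MODELS[key]
          if (is.na(mod)) stop("unknown domain '", key, "' at position ", di,
                               " of gene ", gi)
          unname(mod)
        }
        a1 <- 10L + 110L * (di - 1L); a2 <- a1 + 99L
        dom_lines <- c(dom_lines, sprintf(
          "%-10s -  %6d %-16s - %6d  1e-30  %.1f  0.1  1  1  1e-30  1e-30  %.1f  0.1  1  100  %d  %d  %d  %d  0.95 fixture",
          orf, plen, model, 100L, bitscore, bitscore, a1, a2, a1, a2))
        if (key %in% c("A", "AT") && nzchar(ann)) {
          pre <- if (key == "A") "A_" else "AT_"
          hom_rows[[length(hom_rows) + 1L]] <- data.frame(
            query = paste0(orf, ":", a1),
            reference = paste0(pre, ann), score = 55,
            substrate = ann, stringsAsFactors = FALSE)
          alt <- if (ann == "gly") "ala" else "gly"
          hom_rows[[length(hom_rows) + 1L]] <- data.frame(
            query = paste0(orf, ":", a1),
            reference = paste0(pre, alt), score = 40,
            substrate = alt, stringsAsFactors = FALSE)
        }
        if (key == "GT") {
          subst <- if (nzchar(ann) && startsWith(ann, "hexose:")) {
            sub("^hexose:", "", ann)
          } else if (nzchar(ann)) ann else "mycaminose"
          hom_rows[[length(hom_rows) + 1L]] <- data.frame(
            query = paste0(orf, ":", a1),
            reference = paste0("gtdb_", subst), score = 60,
            substrate = subst, stringsAsFactors = FALSE)
        }
      }
    }
  })
  paths <- list(proteins = file.path(out_dir, "proteins.fasta"),
                genes = file.path(out_dir, "genes.tsv"),
                domtbl = file.path(out_dir, "domains.domtbl"),
                homology = file.path(out_dir, "homology.tsv"))
  writeLines(fasta, paths$proteins)
  utils::write.table(do.call(rbind, coords), paths$genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c("# synthetic domtblout", dom_lines), paths$domtbl)
  hom <- if (length(hom_rows)) do.call(rbind, hom_rows) else {
    data.frame(query = character(), reference = character(),
               score = numeric(), substrate = character())
  }
  utils::write.table(hom, paths$homology, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Generate a synthetic MS/MS spectrum from a known structure
#'
#' The scan's peaks are the structure's theoretical fragment m/z values
#' (fixed high intensity) plus `ceiling(noise_fraction * n)` seeded
#' uniform-random decoy peaks at lower random intensities; the precursor is
#' `[M+H]+`. Written as mzXML (and MGF alongside) so the reading path is
#' exercised.
#'
#' @param x an `np_structure` with defined mass.
#' @param cleavage a [cleavage_settings()] used to generate the peaks.
#' @param noise_fraction fraction (of the signal peak count) of added noise
#'   peaks, in `[0, 1)`.
#' @param seed integer seed.
#' @param rt_min retention time (minutes).
#' @param path output mzXML path (`.mgf` written alongside).
#' @param scan_id scan identifier.
#' @return invisible list of paths `mzxml`, `mgf`.
#' @export
make_spectrum_fixture <- function(x, cleavage = cleavage_settings(amide = c(1, 2),
                                                                  water_loss = c(0, 1)),
                                  noise_fraction = 0, seed = 1, rt_min = 10,
                                  path, scan_id = "fixture_scan") {
  stopifnot(noise_fraction >= 0, noise_fraction < 1)
  mass <- structure_mass(x)
  if (is.na(mass)) stop("structure mass undefined; fill open sites first")
  frags <- ionize(enumerate_fragments(x, cleavage), 1)
  if (!nrow(frags)) stop("structure yields no fragments under these settings")
  mz <- sort(unique(round(frags$mz, 4)))
  peaks <- cbind(mz = mz, intensity = rep(100, length(mz)))
  n_noise <- ceiling(noise_fraction * length(mz))
  if (n_noise > 0) {
    lo <- max(min(mz) - 20, 50); hi <- max(mz) + 20
    noise <- with_seed(seed, cbind(mz = stats::runif(n_noise, lo, hi),
                                   intensity = stats::runif(n_noise, 20, 80)))
    peaks <- rbind(peaks, noise)
  }
  peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  spec <- list(list(scan_id = scan_id, rt_min = rt_min,
                    precursor_mz = mass + MASS_PROTON, precursor_z = 1L,
                    peaks = peaks))
  write_mzxml(spec, path)
  mgf <- sub("\\.mzXML$", ".mgf", path, ignore.case = TRUE)
  if (identical(mgf, path)) mgf <- paste0(path, ".mgf")
  write_mgf(spec, mgf)
  invisible(list(mzxml = path, mgf = mgf))
}

#' Generate a random decoy ("dummy") structure library
#'
#' `n` random linear peptides of 4-10 residues drawn from the amino-acid
#' monomers, with full residue graphs (so decoys fragment exactly like
#' prediction candidates).
#'
#' @param n number of decoys.
#' @param table monomer table.
#' @param seed integer seed.
#' @return library data.frame like [enumerate_library()]'s output.
#' @export
make_decoy_library <- function(n, table = load_monomer_table(), seed = 1) {
  stopifnot(n >= 1)
  aa <- table$name[table$class == "amino_acid"]
  rows <- with_seed(seed, lapply(seq_len(n), function(i) {
    len <- sample(4:10, 1)
    tokens <- sample(aa, len, replace = TRUE)
    x <- build_from_tokens(tokens, table)
    list(compound_id = sprintf("decoy%03d", i),
         smiles = compose_smiles(x),
         neutral_monoisotopic_mass = structure_mass(x),
         provenance = paste0("decoy:", paste(tokens, collapse = "-")),
         structure = x)
  }))
  out <- data.frame(
    compound_id = vapply(rows, `[[`, "", "compound_id"),
    smiles = vapply(rows, `[[`, "", "smiles"),
    neutral_monoisotopic_mass = vapply(rows, `[[`, 0, "neutral_monoisotopic_mass"),
    provenance = vapply(rows, `[[`, "", "provenance"),
    stringsAsFactors = FALSE)
  out$structure <- lapply(rows, `[[`, "structure")
  out
}
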