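#' Load the packaged monomer table
#'
#' The monomer table maps substrate names (amino acids and nonproteinogenic
#' variants, ketide extender units, fatty-acyl starters) to molecular formulas,
#' monoisotopic masses and SMILES residue templates used by the scaffold
#' builder. Side-chain templates mark glycosylation-competent hydroxyls with
#' `{OH}`. Users may supply their own table with the same columns.
#'
#' @param path optional path to a TSV with columns `name`, `class`, `formula`,
#'   `side_smiles`, `piece_override`, `n_oh`, `n_nh2`, `description`.
#' @return data.frame with an added `mass` column (monoisotopic, Da).
#' @export
load_monomer_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "monomers.tsv", package = "napminer")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                           colClasses = "character")
  need <- c("name", "class", "formula", "side_smiles", "piece_override",
            "n_oh", "n_nh2")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("monomer table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$name)) stop("duplicate monomer names in table")
  tab$n_oh <- as.integer(tab$n_oh)
  tab$n_nh2 <- as.integer(tab$n_nh2)
  tab$mass <- formula_mass(tab$formula)
  tab
}

#' @keywords internal
monomer_row <- function(name, table) {
  i <- match(name, table$name)
  if (is.na(i)) stop("unknown monomer: ", name)
  table[i, , drop = FALSE]
}

#' Load the packaged sugar biosynthetic code
#'
#' A reconstruction of a glycogenomic code: each row names a sugar, its
#' molecular formula, a SMILES fragment rooted at the anomeric carbon
#' (`attach_smiles`; the free sugar is this fragment with an anomeric
#' hydroxyl), and the semicolon-joined sugar-gene families whose presence in a
#' cluster implies the pathway. Deoxyhexose and pentose entries carry
#' non-empty family sets; hexoses are assigned from glycosyltransferase
#' homology instead and carry none. The shipped file is a synthetic
#' reconstruction (see the methods vignette) and is user-replaceable.
#'
#' @param path optional path to a TSV with columns `name`, `sugar_class`,
#'   `formula`, `attach_smiles`, `gene_families`, `description`.
#' @return data.frame with `mass` (free-sugar monoisotopic, Da) and
#'   `gene_families` as a list-column of character vectors.
#' @export
load_sugar_code <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sugar_code_synthetic.tsv", package = "napminer")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                           colClasses = "character")
  need <- c("name", "sugar_class", "formula", "attach_smiles", "gene_families")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sugar code missing column(s): ", paste(miss, collapse = ", "))
  tab$mass <- formula_mass(tab$formula)
  fams <- strsplit(tab$gene_families, ";", fixed = TRUE)
  fams <- lapply(fams, function(x) x[nzchar(x)])
  bad <- tab$sugar_class %in% c("deoxyhexose", "pentose") &
    vapply(fams, length, integer(1)) == 0L
  if (any(bad)) {
    stop("deoxysugar/pentose entries need gene families: ",
         paste(tab$name[bad], collapse = ", "))
  }
  tab$gene_families <- fams
  tab
}

#' All sugar-gene family names used by a sugar code
#'
#' @param code a sugar code data.frame from [load_sugar_code()].
#' @return sorted character vector of family names.
#' @export
sugar_gene_families <- function(code) {
  sort(unique(unlist(code$gene_families)))
}
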