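#' Read sequence records from a FASTA file
#'
#' Reads single- or multi-record FASTA and tags each record as DNA or protein.
#' With `alphabet_hint = "auto"` the alphabet is detected from character
#' composition (IUPAC DNA codes dominate in nucleotide records).
#'
#' @param path path to a FASTA file.
#' @param alphabet_hint one of `"auto"`, `"dna"`, `"protein"`.
#' @return data.frame with columns `id`, `alphabet`, `residues`, `source_file`.
#' @export
read_fasta <- function(path, alphabet_hint = c("auto", "dna", "protein")) {
  alphabet_hint <- match.arg(alphabet_hint)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty input file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  residues <- toupper(as.character(set))
  if (any(!nzchar(residues))) {
    stop("record without residues: ", ids[!nzchar(residues)][1])
  }
  alphabet <- vapply(seq_along(residues), function(i) {
    detect_alphabet(residues[i], ids[i], alphabet_hint)
  }, character(1))
  data.frame(id = ids, alphabet = alphabet, residues = residues,
             source_file = path, stringsAsFactors = FALSE)
}

#' @keywords internal
detect_alphabet <- function(seq, id, hint) {
  chars <- strsplit(seq, "")[[1]]
  dna_set <- strsplit("ACGTUNRYSWKMBDHV", "")[[1]]
  aa_set <- strsplit("ACDEFGHIKLMNPQRSTVWYXBZJUO*", "")[[1]]
  is_dna <- all(chars %in% dna_set) &&
    mean(chars %in% c("A", "C", "G", "T", "U", "N")) >= 0.9
  is_aa <- all(chars %in% aa_set)
  if (hint == "dna") {
    if (!all(chars %in% dna_set)) {
      stop("record ", id, " contains non-DNA characters: ",
           paste(unique(setdiff(chars, dna_set)), collapse = ""))
    }
    return("dna")
  }
  if (hint == "protein") {
    if (!is_aa) {
      stop("record ", id, " contains non-amino-acid characters: ",
           paste(unique(setdiff(chars, aa_set)), collapse = ""))
    }
    return("protein")
  }
  if (is_dna) "dna"
  else if (is_aa) "protein"
  else stop("record ", id, " has mixed/invalid characters")
}

#' Translate a DNA string in a given frame
#'
#' Standard genetic code; codons containing ambiguity codes yield `"X"`.
#' A trailing partial codon is dropped. Stop codons translate to `"*"`.
#'
#' @param dna character scalar of DNA.
#' @param frame 0, 1 or 2 (offset into the sequence).
#' @return character scalar of amino acids.
#' @export
translate_dna <- function(dna, frame = 0) {
  stopifnot(frame %in% 0:2)
  dna <- toupper(dna)
  if (nchar(dna) < frame + 3) stop("sequence shorter than frame + one codon")
  s <- substring(dna, frame + 1)
  n <- nchar(s) %/% 3
  codons <- substring(s, 3 * seq_len(n) - 2, 3 * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.START_CODONS <- c("ATG", "GTG", "TTG")

#' Detect open reading frames on all six frames
#'
#' Scans every frame of both strands for start-codon-to-stop spans (accepted
#' starts ATG/GTG/TTG, bacterial convention) whose translated protein is at
#' least `min_aa` residues. Reverse-strand hits are reported on the forward
#' axis with 0-based half-open coordinates; the span includes the stop codon.
#' Output is ordered by start coordinate, with strand `+` before `-` on ties.
#'
#' @param dna one row of a [read_fasta()] data.frame (alphabet `"dna"`), or a
#'   plain character DNA string.
#' @param min_aa minimum protein length in residues (default 50).
#' @param id contig id used when `dna` is a plain string.
#' @return data.frame with columns `orf_id`, `contig_id`, `start`, `end`,
#'   `strand`, `frame`, `protein`.
#' @export
find_orfs <- function(dna, min_aa = 50, id = "seq") {
  stopifnot(min_aa >= 1)
  if (is.data.frame(dna)) {
    if (nrow(dna) != 1) stop("find_orfs expects a single record")
    if (dna$alphabet != "dna") stop("find_orfs requires a DNA record, got ", dna$alphabet)
    id <- dna$id
    seq <- dna$residues
  } else {
    seq <- toupper(dna)
  }
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

  scan_strand <- function(s, strand) {
    out <- list()
    for (frame in 0:2) {
      n <- (nchar(s) - frame) %/% 3
      if (n < 2) next
      codons <- substring(s, frame + 1 + 3 * (seq_len(n) - 1),
                          frame + 3 + 3 * (seq_len(n) - 1))
      is_start <- codons %in% .START_CODONS
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      stop_idx <- which(is_stop)
      if (!length(stop_idx) || !any(is_start)) next
      for (si in which(is_start)) {
        nxt <- stop_idx[stop_idx > si]
        if (!length(nxt)) next
        ei <- nxt[1]
        aa_len <- ei - si           # residues excluding the stop
        if (aa_len < min_aa) next
        s0 <- frame + 3 * (si - 1)  # 0-based on scanned strand
        e0 <- frame + 3 * ei        # end of stop codon, exclusive
        prot <- translate_dna(substring(s, s0 + 1, e0 - 3), 0)
        if (strand == "+") {
          start <- s0; end <- e0
        } else {
          start <- L - e0; end <- L - s0
        }
        out[[length(out) + 1L]] <- data.frame(
          contig_id = id, start = start, end = end, strand = strand,
          frame = frame, protein = prot, stringsAsFactors = FALSE)
      }
    }
    out
  }

  rows <- c(scan_strand(seq, "+"), scan_strand(rc, "-"))
  if (!length(rows)) {
    return(data.frame(orf_id = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      frame = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, rows)
  ord <- order(orfs$start, match(orfs$strand, c("+", "-")), orfs$end)
  orfs <- orfs[ord, , drop = FALSE]
  orfs <- cbind(orf_id = sprintf("%s_orf%03d", id, seq_len(nrow(orfs))),
                orfs, stringsAsFactors = FALSE)
  rownames(orfs) <- NULL
  orfs
}

#' Write an ORF table as GFF3-like TSV
#'
#' @param orfs data.frame from [find_orfs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(orfs, path) {
  utils::write.table(
    orfs[, c("contig_id", "start", "end", "strand", "frame", "orf_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
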