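#' Read MS/MS spectra from mzXML or MGF
#'
#' Returns MS2 scans only, ordered by retention time. mzXML is read through
#' mzR; MGF blocks are parsed directly.
#'
#' @param path spectrum file.
#' @param format `"auto"` (by extension), `"mzXML"` or `"MGF"`.
#' @return list of spectra; each is a list with `scan_id`, `rt_min`,
#'   `precursor_mz`, `precursor_z` (`NA` when unknown), `peaks` (two-column
#'   matrix `mz`, `intensity`, sorted by mz).
#' @export
read_spectra <- function(path, format = c("auto", "mzXML", "MGF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "MGF" else "mzXML"
  }
  spectra <- if (format == "MGF") read_mgf(path) else read_mzxml(path)
  if (!length(spectra)) stop("no MS2 scans in ", path)
  spectra[order(vapply(spectra, `[[`, 0, "rt_min"))]
}

#' @keywords internal
read_mzxml <- function(path) {
  f <- mzR::openMSfile(path)
  on.exit(mzR::close(f))
  hdr <- mzR::header(f)
  idx <- which(hdr$msLevel == 2)
  lapply(idx, function(i) {
    pk <- mzR::peaks(f, i)
    if (is.null(dim(pk))) pk <- matrix(pk, ncol = 2)
    colnames(pk) <- c("mz", "intensity")
    pk <- pk[order(pk[, 1]), , drop = FALSE]
    z <- hdr$precursorCharge[i]
    list(scan_id = as.character(hdr$acquisitionNum[i]),
         rt_min = hdr$retentionTime[i] / 60,
         precursor_mz = hdr$precursorMZ[i],
         precursor_z = if (is.na(z) || z == 0) NA_integer_ else as.integer(z),
         peaks = pk)
  })
}

#' @keywords internal
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends) || any(ends < starts)) {
    stop("malformed MGF: unbalanced BEGIN/END IONS in ", path)
  }
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    blk <- lines[(starts[b] + 1):(ends[b] - 1)]
    kv <- blk[grepl("=", blk, fixed = TRUE)]
    pkl <- blk[!grepl("=", blk, fixed = TRUE) & nzchar(trimws(blk))]
    get <- function(key, default = NA) {
      hit <- kv[startsWith(kv, paste0(key, "="))]
      if (!length(hit)) return(default)
      sub(paste0("^", key, "="), "", hit[1])
    }
    pepmass <- as.numeric(strsplit(trimws(get("PEPMASS", "NA")), "\\s+")[[1]][1])
    rts <- suppressWarnings(as.numeric(get("RTINSECONDS", NA)))
    chg <- get("CHARGE", NA)
    z <- if (is.na(chg)) NA_integer_ else {
      suppressWarnings(as.integer(sub("\\+.*$", "", chg)))
    }
    pk <- do.call(rbind, lapply(strsplit(trimws(pkl), "\\s+"), function(p) {
      as.numeric(p[1:2])
    }))
    if (is.null(pk)) pk <- matrix(numeric(), ncol = 2)
    colnames(pk) <- c("mz", "intensity")
    pk <- pk[order(pk[, 1]), , drop = FALSE]
    out[[b]] <- list(scan_id = get("TITLE", paste0("scan", b)),
                     rt_min = if (is.na(rts)) 0 else rts / 60,
                     precursor_mz = pepmass, precursor_z = z, peaks = pk)
  }
  out
}

#' Write spectra as mzXML
#'
#' Minimal centroided mzXML 3.2 (network-order 32-bit packed peaks),
#' readable by mzR and other standard parsers. Used by the fixture
#' generators so the mzXML reading path is exercised end to end.
#'
#' @param spectra list of spectra as returned by [read_spectra()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mzxml <- function(spectra, path) {
  scan_xml <- vapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    pk <- s$peaks
    interleaved <- as.numeric(t(pk))
    b64 <- jsonlite::base64_enc(writeBin(interleaved, raw(), size = 4,
                                         endian = "big"))
    b64 <- gsub("\n", "", b64, fixed = TRUE)
    zattr <- if (!is.na(s$precursor_z)) {
      sprintf(' precursorCharge="%d"', s$precursor_z)
    } else ""
    paste0(
      sprintf('  <scan num="%d" msLevel="2" peaksCount="%d" retentionTime="PT%.4fS" polarity="+" lowMz="%.4f" highMz="%.4f" basePeakMz="%.4f" basePeakIntensity="%.1f" totIonCurrent="%.1f">\n',
              i, nrow(pk), s$rt_min * 60,
              if (nrow(pk)) min(pk[, 1]) else 0,
              if (nrow(pk)) max(pk[, 1]) else 0,
              if (nrow(pk)) pk[which.max(pk[, 2]), 1] else 0,
              if (nrow(pk)) max(pk[, 2]) else 0,
              sum(pk[, 2])),
      sprintf('   <precursorMz%s>%.6f</precursorMz>\n', zattr, s$precursor_mz),
      sprintf('   <peaks precision="32" byteOrder="network" contentType="m/z-int" compressionType="none" compressedLen="0">%s</peaks>\n',
              b64),
      '  </scan>')
  }, character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="ISO-8859-1"?>\n',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">\n',
    ' <msRun scanCount="', length(spectra), '">\n',
    paste(scan_xml, collapse = "\n"), "\n",
    ' </msRun>\n</mzXML>\n')
  writeLines(xml, path)
  invisible(path)
}

#' Write spectra as MGF
#'
#' @param spectra list of spectra.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    paste0("BEGIN IONS\n",
           "TITLE=", s$scan_id, "\n",
           sprintf("PEPMASS=%.6f\n", s$precursor_mz),
           if (!is.na(s$precursor_z)) sprintf("CHARGE=%d+\n", s$precursor_z) else "",
           sprintf("RTINSECONDS=%.3f\n", s$rt_min * 60),
           paste(sprintf("%.6f %.2f", s$peaks[, 1], s$peaks[, 2]),
                 collapse = "\n"),
           "\nEND IONS")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}
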