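# Plain-text peak-list formats: NIST MSP for libraries, Mascot MGF for
# queries. Both are line-oriented; we accept CR/LF or LF on read and always
# emit LF.

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gsub("\r$", "", readLines(path, warn = FALSE))
}

#' Read an MSP spectral library
#'
#' Parses the NIST text dialect: `Name:`, `PrecursorMZ:`, `RETENTIONTIME:`,
#' `Formula:`, `Subclass:`, `Provenance:`, `Comments:`, `Num Peaks:` followed
#' by `m/z intensity` lines. Records are separated by blank lines. A record
#' whose peak count disagrees with `Num Peaks` or that lacks a `Name` is an
#' error naming the offending record.
#'
#' @param path file path.
#' @return List of [library_record()] objects.
#' @export
read_msp <- function(path) {
  lines <- .read_lines(path)
  # split into blocks on blank lines
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[vapply(blocks, length, 1L) > 0L]
  lapply(blocks, .parse_msp_block)
}

.parse_msp_block <- function(b) {
  header <- list(); peaks <- NULL; n_declared <- NA_integer_
  i <- 1L
  while (i <= length(b)) {
    line <- b[i]
    m <- regmatches(line, regexec("^([A-Za-z _]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) {
      key <- toupper(gsub(" ", "", m[2])); val <- m[3]
      header[[key]] <- val
      if (key == "NUMPEAKS") {
        n_declared <- as.integer(val)
        peak_lines <- b[seq_len(length(b) - i) + i]
        i <- length(b)
        if (length(peak_lines) != n_declared)
          stop("MSP record '", if (is.null(header$NAME)) "<unnamed>" else header$NAME,
               "': Num Peaks is ", n_declared, " but ", length(peak_lines),
               " peak lines found")
        if (n_declared > 0L) {
          parts <- strsplit(trimws(peak_lines), "[\t ]+")
          peaks <- data.frame(
            mz = as.numeric(vapply(parts, `[`, "", 1L)),
            intensity = as.numeric(vapply(parts, `[`, "", 2L)))
        }
      }
    }
    i <- i + 1L
  }
  if (is.null(header$NAME)) stop("MSP record without a Name field")
  if (is.na(n_declared)) stop("MSP record '", header$NAME, "': no Num Peaks field")
  if (is.null(peaks)) peaks <- data.frame(mz = numeric(), intensity = numeric())
  rt <- if (!is.null(header$RETENTIONTIME)) as.numeric(header$RETENTIONTIME) else NA_real_
  pm <- if (!is.null(header$PRECURSORMZ)) as.numeric(header$PRECURSORMZ) else
    stop("MSP record '", header$NAME, "': no PrecursorMZ field")
  sp <- ms_spectrum(
    id = header$NAME, precursor_mz = pm, peaks = peaks,
    adduct = if (!is.null(header$PRECURSORTYPE)) header$PRECURSORTYPE else "[M+H]+",
    rt = rt,
    metadata = if (!is.null(header$COMMENTS)) list(comments = header$COMMENTS) else list())
  library_record(
    sp, name = header$NAME,
    formula = if (!is.null(header$FORMULA)) header$FORMULA else NULL,
    subclass = if (!is.null(header$SUBCLASS)) header$SUBCLASS else NA_character_,
    provenance = if (!is.null(header$PROVENANCE)) header$PROVENANCE else "synthetic")
}

#' @rdname read_msp
#' @param records list of [library_record()] objects to write.
#' @export
write_msp <- function(records, path) {
  out <- character()
  for (r in records) {
    sp <- r$spectrum
    lines <- c(
      paste0("Name: ", r$name),
      paste0("PrecursorMZ: ", sprintf("%.6f", sp$precursor_mz)),
      paste0("PrecursorType: ", sp$adduct))
    if (!is.na(sp$rt))
      lines <- c(lines, paste0("RETENTIONTIME: ", sprintf("%.4f", sp$rt)))
    if (!is.null(r$formula))
      lines <- c(lines, paste0("Formula: ", format_formula(r$formula)))
    if (!is.na(r$subclass))
      lines <- c(lines, paste0("Subclass: ", r$subclass))
    lines <- c(lines, paste0("Provenance: ", r$provenance))
    if (!is.null(sp$metadata$comments))
      lines <- c(lines, paste0("Comments: ", sp$metadata$comments))
    lines <- c(lines, paste0("Num Peaks: ", nrow(sp$peaks)))
    if (nrow(sp$peaks) > 0L)
      lines <- c(lines, sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity))
    out <- c(out, lines, "")
  }
  writeLines(out, path, sep = "\n")
  invisible(path)
}

#' Read a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS`,
#' `RTINSECONDS` and peak lines. Retention time is converted to minutes. An
#' empty block yields a zero-peak spectrum with a warning.
#'
#' @param path file path.
#' @return List of [ms_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- .read_lines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends))
    stop("malformed MGF: unbalanced BEGIN IONS / END IONS in ", path)
  lapply(seq_along(starts), function(k) {
    b <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    b <- b[b != ""]
    kv <- grepl("=", b, fixed = TRUE)
    header <- list()
    for (line in b[kv]) {
      eq <- regexpr("=", line, fixed = TRUE)
      header[[toupper(substr(line, 1, eq - 1))]] <- substr(line, eq + 1, nchar(line))
    }
    peak_lines <- b[!kv]
    if (length(peak_lines) == 0L) {
      warning("MGF block ", k, " has no peaks")
      peaks <- data.frame(mz = numeric(), intensity = numeric())
    } else {
      parts <- strsplit(trimws(peak_lines), "[\t ]+")
      peaks <- data.frame(mz = as.numeric(vapply(parts, `[`, "", 1L)),
                          intensity = as.numeric(vapply(parts, `[`, "", 2L)))
    }
    if (is.null(header$PEPMASS)) stop("MGF block ", k, ": no PEPMASS")
    ms_spectrum(
      id = if (!is.null(header$TITLE)) header$TITLE else paste0("mgf_", k),
      precursor_mz = as.numeric(strsplit(header$PEPMASS, "[\t ]+")[[1]][1]),
      peaks = peaks,
      adduct = if (!is.null(header$ADDUCT)) header$ADDUCT else "[M+H]+",
      rt = if (!is.null(header$RTINSECONDS)) as.numeric(header$RTINSECONDS) / 60 else NA_real_)
  })
}

#' @rdname read_mgf
#' @param spectra list of [ms_spectrum()] objects to write.
#' @export
write_mgf <- function(spectra, path) {
  out <- character()
  for (sp in spectra) {
    lines <- c("BEGIN IONS",
               paste0("TITLE=", sp$id),
               paste0("PEPMASS=", sprintf("%.6f", sp$precursor_mz)),
               paste0("ADDUCT=", sp$adduct))
    if (!is.na(sp$rt))
      lines <- c(lines, paste0("RTINSECONDS=", sprintf("%.4f", sp$rt * 60)))
    if (nrow(sp$peaks) > 0L)
      lines <- c(lines, sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity))
    out <- c(out, lines, "END IONS", "")
  }
  writeLines(out, path, sep = "\n")
  invisible(path)
}
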