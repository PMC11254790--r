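#' Construct a BeatDataset
#'
#' @param beats numeric matrix, one beat per row.
#' @param labels subject identifier per row.
#' @param recordIds source record identifier per row (recycled).
#' @param rrSamples original RR length per row in samples (NA if unknown).
#' @return a \linkS4class{BeatDataset}.
#' @export
beatDataset <- function(beats, labels, recordIds = rep("", nrow(beats)),
                        rrSamples = rep(NA_real_, nrow(beats))) {
  beats <- as.matrix(beats)
  dimnames(beats) <- NULL
  new("BeatDataset", beats = beats, labels = as.character(labels),
      recordIds = rep_len(as.character(recordIds), nrow(beats)),
      rrSamples = rep_len(as.numeric(rrSamples), nrow(beats)))
}

#' Read an ECG record
#'
#' Reads a single channel of a PhysioNet WFDB record (\code{.hea} header +
#' \code{.dat} signal, format 16) or of a two-column \code{time,mV} CSV.
#' Amplitudes are converted to mV using the WFDB gain/baseline when the
#' header declares them; CSV values are passed through. Channel selection
#' is always explicit.
#'
#' @param path path to the \code{.hea} file (WFDB) or the CSV file.
#' @param format \code{"wfdb"} or \code{"csv"}.
#' @param channel channel (signal description) to extract.
#' @param fsHz sampling rate; required for CSV, ignored for WFDB.
#' @param subjectId,recordId identity metadata; default from the file name.
#' @return an \linkS4class{EcgRecord}.
#' @export
readRecord <- function(path, format = c("wfdb", "csv"), channel = "ECG1",
                       fsHz = NULL, subjectId = NULL, recordId = NULL) {
  format <- match.arg(format)
  stopIf(!file.exists(path), "cannot read '%s': no such file", path)
  base <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(recordId)) recordId <- base
  if (is.null(subjectId)) subjectId <- base
  if (format == "wfdb") {
    readWfdbChannel(path, channel, subjectId, recordId)
  } else {
    stopIf(is.null(fsHz), "fsHz must be supplied for CSV records")
    df <- utils::read.csv(path)
    stopIf(!"mV" %in% names(df), "CSV record must have an 'mV' column")
    stopIf(anyNA(df$mV), "CSV record contains missing values")
    new("EcgRecord", samples = as.numeric(df$mV), fs = fsHz,
        subjectId = subjectId, recordId = recordId, lead = channel,
        session = "")
  }
}

# Parse a WFDB header and read one format-16 channel, converting ADC units
# to mV via (adc - baseline) / gain.
readWfdbChannel <- function(heaPath, channel, subjectId, recordId) {
  lines <- readLines(heaPath, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  head <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nSig <- as.integer(head[2])
  fsHz <- as.numeric(head[3])
  nSamp <- as.integer(head[4])
  sigLines <- lines[1 + seq_len(nSig)]
  parse1 <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gainField <- f[3]
    gain <- as.numeric(sub("\\(.*", "", sub("/.*", "", gainField)))
    baseline <- if (grepl("\\(", gainField))
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gainField)) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], format = sub("x.*|:.*|\\+.*", "", f[2]),
         gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = baseline, desc = desc)
  }
  sigs <- lapply(sigLines, parse1)
  descs <- vapply(sigs, `[[`, character(1), "desc")
  ch <- which(descs == channel)
  stopIf(length(ch) == 0,
         "channel '%s' not found; available channels: %s",
         channel, paste(descs, collapse = ", "))
  ch <- ch[1]
  stopIf(sigs[[ch]]$format != "16",
         "only WFDB format 16 is supported (got format %s)", sigs[[ch]]$format)
  datPath <- file.path(dirname(heaPath), sigs[[ch]]$file)
  stopIf(!file.exists(datPath), "signal file '%s' not found", datPath)
  raw <- readBin(datPath, "integer", n = nSig * nSamp, size = 2,
                 signed = TRUE, endian = "little")
  adc <- raw[seq(ch, length(raw), by = nSig)]
  mv <- (adc - sigs[[ch]]$baseline) / sigs[[ch]]$gain
  new("EcgRecord", samples = mv, fs = fsHz, subjectId = subjectId,
      recordId = recordId, lead = channel, session = "")
}

#' Write a record as WFDB (format 16)
#'
#' Single-channel writer used for round-trip testing and data exchange.
#' Voltages are quantized with the given gain (ADC units per mV).
#'
#' @param rec an \linkS4class{EcgRecord}.
#' @param dir output directory.
#' @param name record name (basename of the .hea/.dat pair).
#' @param gain ADC units per mV.
#' @return invisibly, the path to the written header.
#' @export
writeRecordWfdb <- function(rec, dir, name = recordId(rec), gain = 1000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adc <- as.integer(round(rec@samples * gain))
  stopIf(any(abs(adc) > 32767), "signal exceeds 16-bit range at gain %g", gain)
  hea <- file.path(dir, paste0(name, ".hea"))
  writeLines(c(
    sprintf("%s 1 %g %d", name, rec@fs, length(adc)),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
            name, gain, adc[1], rec@lead)
  ), hea)
  writeBin(adc, file.path(dir, paste0(name, ".dat")), size = 2,
           endian = "little")
  invisible(hea)
}

#' Write a record as CSV (time, mV)
#'
#' @param rec an \linkS4class{EcgRecord}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeRecordCsv <- function(rec, path) {
  n <- length(rec@samples)
  df <- data.frame(time = (seq_len(n) - 1L) / rec@fs, mV = rec@samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write ground-truth R indices for synthetic records
#'
#' Sidecar CSV with columns \code{record_id,sample_index} (0-based).
#'
#' @param recs list of \linkS4class{SyntheticEcgRecord}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeTruthCsv <- function(recs, path) {
  rows <- do.call(rbind, lapply(recs, function(r)
    data.frame(record_id = r@recordId, sample_index = r@trueRIndices)))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a beat dataset as CSV
#'
#' Dialect: header \code{subject_id,record_id,s0..s149} (column count
#' follows the beat length), one beat per row, values with at least six
#' significant digits. This is the merged per-database beat table format.
#'
#' @param ds a \linkS4class{BeatDataset}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeBeatsCsv <- function(ds, path) {
  L <- if (nrow(ds@beats)) ncol(ds@beats) else 150L
  header <- paste(c("subject_id", "record_id", paste0("s", seq_len(L) - 1L)),
                  collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(ds@beats) > 0) {
    vals <- apply(ds@beats, 1L, function(r)
      paste(formatC(r, digits = 9, format = "g"), collapse = ","))
    writeLines(paste(ds@labels, ds@recordIds, vals, sep = ","), con)
  }
  invisible(path)
}

#' Read a beat dataset CSV
#'
#' @param path file in the \code{\link{writeBeatsCsv}} dialect.
#' @return a \linkS4class{BeatDataset} (rrSamples are NA; the dialect does
#'   not store them).
#' @export
readBeatsCsv <- function(path) {
  stopIf(!file.exists(path), "cannot read '%s': no such file", path)
  lines <- readLines(path, warn = FALSE)
  stopIf(length(lines) == 0, "empty beats CSV '%s'", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  stopIf(!identical(header[1:2], c("subject_id", "record_id")),
         "not a beats CSV: header must start with subject_id,record_id")
  L <- length(header) - 2L
  body <- lines[-1]
  if (length(body) == 0)
    return(beatDataset(matrix(numeric(0), 0, L), character(0)))
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != L + 2L)
  stopIf(length(bad) > 0,
         "row %d has %d sample columns, expected %d",
         bad[1], nf[bad[1]] - 2L, L)
  labels <- vapply(parts, `[[`, character(1), 1L)
  recIds <- vapply(parts, `[[`, character(1), 2L)
  beats <- matrix(as.numeric(unlist(lapply(parts, `[`, -(1:2)))),
                  nrow = length(parts), ncol = L, byrow = TRUE)
  stopIf(anyNA(beats), "non-numeric beat values in '%s'", path)
  beatDataset(beats, labels, recIds)
}

#' Merge beat datasets
#'
#' Concatenates beat tables from several sources. When \code{namespace}
#' prefixes are given, labels become \code{prefix:subject_id}, so subjects
#' from different source databases can never collide (the construction used
#' for mixed multi-database cohorts). Without namespaces, a label occurring
#' in more than one part is an error: silent identity merging is refused.
#'
#' @param parts non-empty list of \linkS4class{BeatDataset}.
#' @param namespace optional character vector of per-part prefixes.
#' @return the merged \linkS4class{BeatDataset}.
#' @export
mergeDatasets <- function(parts, namespace = NULL) {
  stopIf(length(parts) == 0, "parts must be non-empty")
  if (!is.null(namespace)) {
    stopIf(length(namespace) != length(parts),
           "namespace must have one prefix per part")
    parts <- mapply(function(p, ns) {
      p@labels <- paste(ns, p@labels, sep = ":")
      p
    }, parts, namespace, SIMPLIFY = FALSE)
  } else if (length(parts) > 1L) {
    sets <- lapply(parts, function(p) unique(p@labels))
    for (i in seq_along(sets)[-1]) {
      clash <- intersect(sets[[i]], unlist(sets[seq_len(i - 1L)]))
      stopIf(length(clash) > 0,
             "label(s) %s occur in multiple parts; supply namespaces",
             paste(clash, collapse = ", "))
    }
  }
  beatDataset(
    do.call(rbind, lapply(parts, function(p) p@beats)),
    unlist(lapply(parts, function(p) p@labels)),
    unlist(lapply(parts, function(p) p@recordIds)),
    unlist(lapply(parts, function(p) p@rrSamples))
  )
}

# row-bind beat datasets without the cross-source collision check (internal;
# used where parts deliberately share labels, e.g. originals + SMOTE rows)
bindBeats <- function(parts) {
  beatDataset(
    do.call(rbind, lapply(parts, function(p) p@beats)),
    unlist(lapply(parts, function(p) p@labels)),
    unlist(lapply(parts, function(p) p@recordIds)),
    unlist(lapply(parts, function(p) p@rrSamples))
  )
}

#' Subset a beat dataset by row
#'
#' @param ds a \linkS4class{BeatDataset}.
#' @param idx integer row indices.
#' @return the subset \linkS4class{BeatDataset}.
#' @export
subsetBeats <- function(ds, idx) {
  beatDataset(ds@beats[idx, , drop = FALSE], ds@labels[idx],
              ds@recordIds[idx], ds@rrSamples[idx])
}
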