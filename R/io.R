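#' Read raw signals from the plain per-read signal table
#'
#' The zero-dependency reference format for raw reads: a TSV with columns
#' `read_id`, `sample_rate`, `signal`, the latter holding the
#' comma-separated current samples of the read. Optional columns `label`,
#' `adapter_end`, `polya_end` (truth metadata) are carried through.
#'
#' @param path Path to a signal TSV.
#' @return A read tibble (possibly empty, with a warning for an empty
#'   file) in file order.
#' @export
read_signals <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tbl) == 0) {
    warning("read_signals: empty file ", path)
    return(tibble::tibble(read_id = character(), signal = list(),
                          sample_rate = numeric()))
  }
  if (!all(c("read_id", "sample_rate", "signal") %in% names(tbl))) {
    stop("read_signals: expected columns read_id, sample_rate, signal in ",
         path)
  }
  out <- tibble::tibble(
    read_id = as.character(tbl$read_id),
    signal = lapply(strsplit(tbl$signal, ",", fixed = TRUE), as.numeric),
    sample_rate = as.numeric(tbl$sample_rate))
  for (col in c("label", "adapter_end", "polya_end", "replicate_id")) {
    if (col %in% names(tbl)) out[[col]] <- tbl[[col]]
  }
  out
}

#' Write raw signals to the plain per-read signal table
#'
#' @param reads A read tibble.
#' @param path Output path.
#' @param digits Significant digits kept per sample (default 6).
#' @return `path`, invisibly.
#' @export
write_signals <- function(reads, path, digits = 6) {
  df <- data.frame(
    read_id = reads$read_id,
    sample_rate = reads$sample_rate,
    signal = vapply(reads$signal, function(s) {
      paste(signif(s, digits), collapse = ",")
    }, character(1)))
  for (col in c("label", "adapter_end", "polya_end", "replicate_id")) {
    if (col %in% names(reads)) df[[col]] <- reads[[col]]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write truth labels as TSV
#'
#' @param reads A read tibble with truth columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(reads, path) {
  utils::write.table(
    data.frame(read_id = reads$read_id, label = reads$label,
               adapter_end = reads$adapter_end,
               polya_end = reads$polya_end),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write fingerprints as TSV
#'
#' One row per read: `read_id`, `f1..fN`, `qc_flags` (and `label` when
#' present); failed fingerprints are written with NA values.
#'
#' @param fps Fingerprint tibble from [extract_fingerprints()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  fp_len <- max(c(1, lengths(fps$fingerprint)))
  mat <- t(vapply(fps$fingerprint, function(v) {
    if (is.null(v)) rep(NA_real_, fp_len) else v
  }, numeric(fp_len)))
  df <- data.frame(read_id = fps$read_id, mat)
  names(df)[-1] <- paste0("f", seq_len(fp_len))
  df$qc_flags <- fps$qc_flags
  if ("label" %in% names(fps)) df$label <- fps$label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fingerprints from TSV
#'
#' @param path Path written by [write_fingerprints()].
#' @return A fingerprint tibble.
#' @export
read_fingerprints <- function(path) {
  tbl <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(tbl), value = TRUE)
  out <- tibble::tibble(
    read_id = as.character(tbl$read_id),
    fingerprint = lapply(seq_len(nrow(tbl)), function(i) {
      v <- as.numeric(tbl[i, fcols])
      if (anyNA(v)) NULL else v
    }),
    ok = !vapply(seq_len(nrow(tbl)), function(i) {
      anyNA(as.numeric(tbl[i, fcols]))
    }, logical(1)),
    qc_flags = if ("qc_flags" %in% names(tbl)) {
      ifelse(is.na(tbl$qc_flags), "", tbl$qc_flags)
    } else "")
  if ("label" %in% names(tbl)) out$label <- tbl$label
  out
}

#' Write predictions as TSV
#'
#' Columns, in order: `read_id`, `predicted`, `confidence`, `status`, then
#' one `p_<label>` column per class; NA for unavailable probabilities.
#'
#' @param pred Prediction tibble from [predict.demux_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(as.data.frame(pred), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a barcode set as FASTA
#'
#' @param barcodes Tibble with `barcode_id` and `seq` columns (e.g. from
#'   [design_barcodes()]), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(barcodes, path) {
  if (is.data.frame(barcodes)) {
    seqs <- setNames(barcodes$seq, barcodes$barcode_id)
  } else {
    seqs <- barcodes
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  } else {
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  }
  invisible(path)
}

#' Read a barcode FASTA
#'
#' @param path FASTA file of barcode sequences.
#' @return A tibble with `barcode_id` and `seq`.
#' @export
read_barcode_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    tibble::tibble(barcode_id = names(x), seq = unname(as.character(x)))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    tibble::tibble(barcode_id = sub("^>", "", lines[hdr]),
                   seq = lines[!hdr])
  }
}

#' Write a JSON run manifest
#'
#' Records inputs, parameters and package version next to an output file so
#' the run can be reproduced.
#'
#' @param path Manifest path (conventionally `<output>.manifest.json`).
#' @param inputs Named list or character vector of input descriptions.
#' @param params Named list of parameters.
#' @param seed Seed used, if any.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = list(), params = list(),
                           seed = NULL) {
  jsonlite::write_json(
    list(package = "dtwdemux",
         version = as.character(utils::packageVersion("dtwdemux")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, inputs = inputs, params = params),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
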