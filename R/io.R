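#' Read a long-format plate-reader table
#'
#' Reads a CSV/TSV table with one row per (well, time) observation,
#' validating required columns and unit constraints. The delimiter is
#' sniffed from the header line unless forced. Malformed rows (non-numeric
#' or negative where a non-negative numeric is required) are dropped,
#' counted and reported via an attribute, never silently corrected.
#'
#' @param path File path.
#' @param required_cols Required column names; default the long plate-reader
#'   schema `well`, `condition_id`, `time_min`, `signal`, `signal_kind`.
#' @param delim `NULL` to sniff (`,` vs tab), or an explicit delimiter.
#' @return A data frame; attribute `n_bad_rows` counts dropped rows and
#'   attribute `bad_rows` gives their line numbers.
#' @export
read_long_table <- function(path,
                            required_cols = c("well", "condition_id",
                                              "time_min", "signal",
                                              "signal_kind"),
                            delim = NULL) {
  stopifnot(file.exists(path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, comment.char = "")
  missing_cols <- setdiff(required_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- rep(FALSE, nrow(df))
  for (col in intersect(c("time_min", "signal", "conc_ug_ml", "growth_h",
                          "g0_h", "g_drug_h"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- bad | !is.finite(v) |
      (col %in% c("time_min", "conc_ug_ml") & v < 0)
    df[[col]] <- v
  }
  if (any(bad)) {
    warning(sprintf("%d malformed row(s) dropped (lines %s)", sum(bad),
                    paste(utils::head(which(bad) + 1L, 10), collapse = ", ")))
  }
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_bad_rows") <- sum(bad)
  attr(out, "bad_rows") <- which(bad) + 1L
  out
}

#' Read a checkerboard matrix CSV
#'
#' Expects a matrix CSV whose first row holds the drug concentrations and
#' first column the limitation-axis values.
#'
#' @param path File path.
#' @param normalization_mode Passed to [checkerboard()].
#' @return A [checkerboard()].
#' @export
read_checkerboard_csv <- function(path,
                                  normalization_mode = "per_row_zero_dose") {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(m) <- "double"
  m <- unname(m)
  checkerboard(row_values = m[-1, 1], col_concs = m[1, -1],
               growth = m[-1, -1, drop = FALSE],
               normalization_mode = normalization_mode)
}

#' Write a checkerboard matrix CSV
#'
#' @param board A [checkerboard()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_checkerboard_csv <- function(board, path) {
  stopifnot(inherits(board, "checkerboard"))
  m <- rbind(c(NA, board$col_concs),
             cbind(board$row_values, board$growth))
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write an analysis report
#'
#' Data frames are written as CSV; list-like results (fit summaries,
#' correlation results) as JSON with full precision, so a round-trip read
#' reproduces the values.
#'
#' @param results A data frame or a list (S3 fit objects are converted to
#'   plain lists; function and model components are dropped).
#' @param path Output path; the format follows the extension (`.csv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.data.frame(results)) {
    utils::write.csv(results, path, row.names = FALSE)
  } else {
    x <- unclass(results)
    keep <- !vapply(x, function(el) is.function(el) || inherits(el, "nls"),
                    logical(1))
    jsonlite::write_json(x[keep], path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Hash of a configuration object
#'
#' A short deterministic digest of any configuration list, logged alongside
#' results so reruns can be matched to their settings. Changes in any field
#' change the hash.
#'
#' @param config Any serializable R object.
#' @return A hex string.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(rapply(as.list(config), unclass, how = "replace"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  raw <- as.integer(charToRaw(as.character(json)))
  # FNV-1a over the serialized payload, in double arithmetic mod 2^32
  h <- 2166136261
  for (b in raw) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
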