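#' Read a per-sign phonological annotation table
#'
#' Reads a TSV or CSV annotation table into a sign lexicon. The file must
#' have a header row naming a `gloss` column; a `variant` column, a
#' `language` column, and any subset of the twelve annotation slots (see
#' [slot_schema]) are optional. Row order is preserved — it defines which
#' entry is the "first listed variant" of each gloss. Empty cells become
#' missing slots (one-handed signs, for example, carry no non-dominant
#' annotations). Columns outside the schema are dropped with a warning.
#'
#' @param path Path to a UTF-8 TSV (default) or CSV file; `.csv` extensions
#'   are read comma-separated.
#' @param schema Slot names admitted as annotation columns.
#' @param language Language label used when the file has no `language`
#'   column.
#' @return A `sign_lexicon`: a data frame with columns `gloss`, `language`,
#'   `variant`, and one column per schema slot present in the file (missing
#'   values are `NA`), plus a `provenance` attribute.
#' @export
read_lexicon <- function(path, schema = slot_schema, language = "unknown") {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", fill = TRUE,
                           na.strings = c("", "NA"), fileEncoding = "UTF-8")
  cn <- names(raw)
  if (anyDuplicated(cn)) {
    stop("duplicate header names in ", path, ": ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "), call. = FALSE)
  }
  if (!"gloss" %in% cn) {
    stop("annotation file has no 'gloss' column: ", path, call. = FALSE)
  }
  known <- c("gloss", "variant", "language", schema)
  unknown <- setdiff(cn, known)
  if (length(unknown) > 0) {
    warning("ignoring ", length(unknown), " unknown column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  lex <- data.frame(gloss = normalize_gloss(raw$gloss),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(lex$gloss) | is.na(lex$gloss))) {
    stop("empty gloss after normalization at row(s): ",
         paste(utils::head(which(!nzchar(lex$gloss) | is.na(lex$gloss)), 5),
               collapse = ", "), call. = FALSE)
  }
  lex$language <- if ("language" %in% cn) raw$language else language
  lex$variant <- if ("variant" %in% cn) {
    v <- suppressWarnings(as.integer(raw$variant))
    if (anyNA(v) || any(v < 1L)) {
      stop("variant column must contain positive integers", call. = FALSE)
    }
    v
  } else {
    # no variant column: row order alone defines "first listed"
    stats::ave(seq_len(nrow(raw)), lex$gloss, FUN = seq_along)
  }
  for (s in intersect(schema, cn)) lex[[s]] <- trimws(raw[[s]])
  structure(lex, class = c("sign_lexicon", "data.frame"),
            provenance = path)
}

#' Build a sign lexicon from a data frame
#'
#' Programmatic counterpart of [read_lexicon] for lexicons constructed in
#' code (tests, synthetic data).
#'
#' @param df Data frame with a `gloss` column and optionally `language`,
#'   `variant`, and slot columns.
#' @param language Fallback language label.
#' @param provenance Free-text source note.
#' @return A `sign_lexicon`.
#' @export
as_sign_lexicon <- function(df, language = "synthetic",
                            provenance = "in-memory") {
  stopifnot("gloss" %in% names(df))
  df$gloss <- normalize_gloss(df$gloss)
  if (is.null(df$language)) df$language <- language
  if (is.null(df$variant)) {
    df$variant <- stats::ave(seq_len(nrow(df)), df$gloss, FUN = seq_along)
  }
  keep <- c("gloss", "language", "variant",
            intersect(slot_schema, names(df)))
  structure(df[, keep, drop = FALSE],
            class = c("sign_lexicon", "data.frame"),
            provenance = provenance)
}

#' Keep only the first listed variant of each gloss
#'
#' Dictionaries and signbanks list several entries (variants) for some
#' signs; retaining them all would overweight those glosses in every
#' pairwise statistic, so only the first-occurring entry per gloss is
#' analyzed. Relative order is preserved. Idempotent.
#'
#' @param lex A `sign_lexicon`.
#' @return The deduplicated `sign_lexicon`; the number of removed entries is
#'   reported via `message()`.
#' @export
dedup_first_variant <- function(lex) {
  keep <- !duplicated(lex$gloss)
  removed <- sum(!keep)
  if (removed > 0) {
    message("dedup_first_variant: removed ", removed,
            " later variant(s), ", sum(keep), " unique glosses retained")
  }
  out <- lex[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a result table to CSV or JSON
#'
#' All tabular outputs of the pipeline go through this writer. CSV output is
#' RFC 4180 (quoted strings, no row names); JSON output is an array of
#' records. Numeric round trips are exact to at least 12 significant
#' digits.
#'
#' @param records A data frame.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("auto", "csv", "json")) {
  stopifnot(is.data.frame(records))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}

#' Read a table previously written with [write_table]
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return A data frame.
#' @export
read_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
}

#' Write a sign lexicon as a TSV annotation table
#'
#' Inverse of [read_lexicon]: writes gloss, language, variant, and slot
#' columns tab-separated with empty cells for missing slots.
#'
#' @param lex A `sign_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  out <- as.data.frame(lex)
  for (s in intersect(slot_schema, names(out))) {
    out[[s]][is.na(out[[s]])] <- ""
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
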