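#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of protein records. Sequence ids are the
#' header token before the first whitespace; sequences are upper-cased before
#' any validation so mixed-case input is accepted. Order of entries is
#' preserved.
#'
#' @param path Path to a FASTA file, or `"-"` to read from standard input.
#' @return A tibble with columns `id` (character, unique) and `sequence`
#'   (character, upper-case amino-acid letters).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACD", ">b", "WYW"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  lines <- read_input_lines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    abort(sprintf("FASTA input '%s' is empty (line 1)", path),
          class = "dbpkit_format_error")
  }
  # Pre-scan so format errors carry line numbers; the actual parse is done by
  # Biostrings on the validated text.
  first_content <- which(nzchar(trimws(lines)))[1]
  if (!startsWith(lines[first_content], ">")) {
    abort(sprintf(
      "FASTA input '%s': line %d does not start a header ('>') entry",
      path, first_content
    ), class = "dbpkit_format_error")
  }
  headers <- which(startsWith(lines, ">"))
  ends <- c(headers[-1] - 1L, length(lines))
  for (i in seq_along(headers)) {
    body <- lines[seq.int(headers[i] + 1L, length.out = ends[i] - headers[i])]
    if (!any(nzchar(trimws(body)))) {
      abort(sprintf(
        "FASTA input '%s': entry at line %d has no sequence lines",
        path, headers[i]
      ), class = "dbpkit_format_error")
    }
  }

  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  aset <- Biostrings::readBStringSet(tmp)

  ids <- sub("\\s.*$", "", names(aset))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate FASTA ids: %s", paste(dup, collapse = ", ")),
          class = "dbpkit_format_error")
  }
  tibble(id = ids, sequence = toupper(as.character(aset, use.names = FALSE)))
}

#' Write protein records to a FASTA file
#'
#' @param records A tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  check_records(records)
  aset <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aset, path, width = 70L)
  invisible(path)
}

#' Remove sequences containing non-standard amino-acid letters
#'
#' Drops every record whose sequence contains any of B, J, O, U, X or Z
#' (ambiguity codes and non-standard residues). Removal is whole-sequence:
#' offending records are discarded entirely, never trimmed. The operation is
#' idempotent.
#'
#' @param records A tibble with columns `id` and `sequence`.
#' @return A list with elements `kept` (the filtered record tibble) and
#'   `removed` (character vector of discarded ids).
#' @examples
#' recs <- tibble::tibble(id = c("a", "b"), sequence = c("ACD", "AXD"))
#' filter_standard(recs)
#' @export
filter_standard <- function(records) {
  check_records(records)
  bad <- grepl(paste0("[", paste(AA_NONSTANDARD, collapse = ""), "]"),
               records$sequence)
  invalid <- !grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "]+$"),
                    records$sequence) & !bad
  if (any(invalid)) {
    abort(sprintf(
      "sequences contain characters outside the amino-acid alphabet: %s",
      paste(records$id[invalid], collapse = ", ")
    ), class = "dbpkit_format_error")
  }
  list(kept = records[!bad, , drop = FALSE], removed = records$id[bad])
}

#' Attach binary class labels to protein records
#'
#' Reads a two-column tab-separated table (`id<TAB>label`, no header; label 1 =
#' DNA-binding, 0 = non-binding) and aligns it to a record set. Every record
#' must be labeled and every labeled id must exist among the records.
#'
#' @param path Path to the label TSV, or `"-"` for standard input.
#' @param records A tibble with columns `id` and `sequence`.
#' @return A labeled dataset: the `records` tibble with an integer `label`
#'   column appended, rows in record order.
#' @export
read_labels <- function(path, records) {
  check_records(records)
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort("label table is empty", class = "dbpkit_format_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    bad <- which(lengths(parts) != 2)[1]
    abort(sprintf("label table line %d does not have two tab-separated fields", bad),
          class = "dbpkit_format_error")
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  raw <- vapply(parts, `[[`, character(1), 2)
  if (!all(raw %in% c("0", "1"))) {
    bad <- raw[!raw %in% c("0", "1")][1]
    abort(sprintf("label '%s' is not in {0, 1}", bad),
          class = "dbpkit_value_error")
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate ids in label table: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "dbpkit_format_error")
  }
  unknown <- setdiff(ids, records$id)
  if (length(unknown)) {
    abort(sprintf("label table contains unknown ids: %s",
                  paste(unknown, collapse = ", ")),
          class = "dbpkit_alignment_error")
  }
  missing <- setdiff(records$id, ids)
  if (length(missing)) {
    abort(sprintf("records without a label: %s",
                  paste(missing, collapse = ", ")),
          class = "dbpkit_alignment_error")
  }
  lab <- as.integer(raw)[match(records$id, ids)]
  mutate(records, label = lab)
}

#' Write a label table
#'
#' @param dataset A labeled dataset (tibble with `id` and `label`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(dataset, path) {
  stopifnot(all(c("id", "label") %in% names(dataset)))
  writeLines(paste(dataset$id, dataset$label, sep = "\t"), path)
  invisible(path)
}

check_records <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "sequence") %in% names(records))) {
    abort("records must be a data frame with columns 'id' and 'sequence'",
          class = "dbpkit_value_error")
  }
  if (anyDuplicated(records$id)) {
    abort("record ids must be unique", class = "dbpkit_value_error")
  }
  if (any(!nzchar(records$sequence))) {
    abort("empty sequences are not allowed", class = "dbpkit_value_error")
  }
  invisible(records)
}

read_input_lines <- function(path) {
  if (identical(path, "-")) {
    return(readLines(file("stdin")))
  }
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "dbpkit_io_error")
  }
  readLines(path, warn = FALSE)
}
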