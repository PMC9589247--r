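#' Construct a PSSM profile
#'
#' A PSSM (position-specific scoring matrix) profile holds, for one protein of
#' length L, an L x 20 matrix of substitution scores: entry (j, i) is the score
#' for residue type i at sequence position j. Columns are kept in canonical
#' alphabetical amino-acid order so downstream feature names are stable
#' regardless of the on-disk column order.
#'
#' @param id Sequence identifier.
#' @param residues The amino-acid sequence (length L string).
#' @param scores Numeric L x 20 matrix; columns must be named with the 20
#'   standard amino-acid letters (any order; they are reordered alphabetically).
#' @return An object of class `pssm_profile`.
#' @export
pssm_profile <- function(id, residues, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20) {
    abort("PSSM scores must have exactly 20 columns", class = "dbpkit_value_error")
  }
  if (is.null(colnames(scores))) {
    colnames(scores) <- AA_STANDARD
  }
  if (!setequal(colnames(scores), AA_STANDARD)) {
    abort("PSSM score columns must be the 20 standard amino-acid letters",
          class = "dbpkit_value_error")
  }
  scores <- scores[, AA_STANDARD, drop = FALSE]
  if (nrow(scores) != nchar(residues)) {
    abort(sprintf("PSSM for '%s': %d score rows but %d residues",
                  id, nrow(scores), nchar(residues)),
          class = "dbpkit_value_error")
  }
  rownames(scores) <- NULL
  structure(list(id = id, residues = residues, scores = scores),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("<pssm_profile> %s: %d positions x 20 residues\n",
              x$id, nrow(x$scores)))
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the layout produced by `psiblast -out_ascii_pssm`: header lines, a
#' residue-letter column header, then one row per position carrying the
#' position index, the query residue, 20 log-odds columns, 20 weighted
#' percentage columns and trailing statistics. Only the log-odds block is
#' retained as the score matrix (the convention of the POSSUM/PyFeat
#' descriptor tools); columns are remapped from the file's residue order to
#' canonical alphabetical order.
#'
#' @param path Path to the ASCII PSSM file.
#' @param id Sequence id to record; defaults to the file name without
#'   extension.
#' @return A [pssm_profile()].
#' @export
read_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "dbpkit_io_error")
  }
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  # The column-header line holds 40 single amino-acid letters (two blocks).
  is_header <- vapply(lines, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    length(toks) %in% c(20L, 40L) && all(toks %in% AA_STANDARD)
  }, logical(1), USE.NAMES = FALSE)
  if (!any(is_header)) {
    abort(sprintf("'%s' has no PSSM residue header line", path),
          class = "dbpkit_format_error")
  }
  hline <- which(is_header)[1]
  col_order <- strsplit(trimws(lines[hline]), "\\s+")[[1]][1:20]

  rows <- list()
  residues <- character()
  positions <- integer()
  for (ln in seq.int(hline + 1L, length(lines))) {
    if (ln > length(lines)) break
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) == 0 || !grepl("^[0-9]+$", toks[1])) break  # footer
    num <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (length(num) < 40 || anyNA(num[1:40])) {
      abort(sprintf("'%s' row %d (line %d): expected 40 numeric score fields",
                    path, length(rows) + 1L, ln),
            class = "dbpkit_format_error")
    }
    positions <- c(positions, as.integer(toks[1]))
    residues <- c(residues, toks[2])
    rows[[length(rows) + 1L]] <- num[1:20]
  }
  if (length(rows) == 0) {
    abort(sprintf("'%s' has no PSSM data rows", path),
          class = "dbpkit_format_error")
  }
  if (!identical(positions, seq_along(positions))) {
    abort(sprintf("'%s': position indices are not contiguous from 1", path),
          class = "dbpkit_format_error")
  }
  scores <- do.call(rbind, rows)
  if (all(scores == trunc(scores))) {
    storage.mode(scores) <- "integer"   # PSI-BLAST log-odds are integers
  }
  colnames(scores) <- col_order
  pssm_profile(id, paste(residues, collapse = ""), scores)
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' Emits the dialect [read_pssm()] accepts, with scores in the PSI-BLAST
#' residue column order and a zero-filled weighted-percentage block, so
#' synthetic profiles exercise the same reader as real ones. Integer scores
#' round-trip bit-exactly.
#'
#' @param profile A [pssm_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "pssm_profile"))
  sc <- profile$scores[, PSIBLAST_ORDER, drop = FALSE]
  res <- strsplit(profile$residues, "")[[1]]
  hdr <- c(
    "",
    "Last position-specific scoring matrix computed, weighted, observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("           ", paste(sprintf("%3s", rep(PSIBLAST_ORDER, 2)), collapse = " "))
  )
  body <- vapply(seq_len(nrow(sc)), function(j) {
    paste0(
      sprintf("%5d %s ", j, res[j]),
      paste(sprintf("%3s", format(sc[j, ], trim = TRUE)), collapse = " "),
      " ",
      paste(sprintf("%3d", rep(0L, 20)), collapse = " "),
      "  0.00 0.00"
    )
  }, character(1))
  writeLines(c(hdr, body, ""), path)
  invisible(path)
}

#' Read a manifest of per-sequence PSSM files
#'
#' The manifest is a two-column TSV mapping sequence id to the path of its
#' ASCII PSSM file (paths relative to the manifest's directory are resolved
#' against it).
#'
#' @param path Manifest TSV path.
#' @return A named list of [pssm_profile()] objects.
#' @export
read_pssm_manifest <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort("PSSM manifest rows must be 'id<TAB>path'", class = "dbpkit_format_error")
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  paths <- vapply(parts, `[[`, character(1), 2)
  rel <- !file.exists(paths) & !grepl("^/", paths)
  paths[rel] <- file.path(dirname(path), paths[rel])
  profiles <- map(seq_along(ids), function(i) read_pssm(paths[i], id = ids[i]))
  setNames(profiles, ids)
}

#' Write a set of PSSM profiles plus manifest
#'
#' @param profiles Named list of [pssm_profile()] objects.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_pssm_set <- function(profiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- imap(profiles, function(p, id) {
    f <- paste0(id, ".pssm")
    write_pssm(p, file.path(dir, f))
    paste(id, f, sep = "\t")
  })
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(unlist(rows), manifest)
  invisible(manifest)
}
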