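#' k-mer composition of a protein sequence
#'
#' Counts every overlapping length-`k` word over the 20-letter amino-acid
#' alphabet and normalizes by the number of windows (L - k + 1), giving a
#' frequency vector of length 20^k that sums to 1 for any sequence with
#' L >= k.
#'
#' @param sequence Amino-acid sequence (single string, standard letters only).
#' @param k Word length, in 1..3.
#' @param id Optional sequence id used in error messages.
#' @return A named numeric vector of length `20^k`; names are the words in
#'   lexicographic order.
#' @examples
#' kmer_encode("ACAC", k = 2)[c("AC", "CA")]
#' @export
kmer_encode <- function(sequence, k, id = NULL) {
  stopifnot(length(k) == 1, k >= 1, k <= 3)
  idx <- aa_indices(sequence, id)
  L <- length(idx)
  if (L < k) {
    abort(sprintf("sequence%s of length %d is shorter than k = %d",
                  if (is.null(id)) "" else paste0(" '", id, "'"), L, k),
          class = "dbpkit_encoding_error")
  }
  n_win <- L - k + 1L
  codes <- idx[seq_len(n_win)]
  if (k > 1) {
    for (j in seq_len(k - 1L)) {
      codes <- (codes - 1L) * 20L + idx[seq.int(1L + j, length.out = n_win)]
    }
  }
  v <- tabulate(codes, nbins = 20L^k) / n_win
  names(v) <- kmer_vocabulary(k)
  v
}

#' Gapped mono-di composition (monoDiKGap)
#'
#' For each gap width g in 1..`kgap`, counts patterns of the form
#' X . {g skipped positions} . YZ — one residue, a gap of g positions whose
#' identity is ignored, then a dipeptide — over all valid windows. Each gap
#' width contributes a 20 x 20^2 = 8000-dimensional block normalized by its
#' own window count max(1, L - g - 2), so the full vector has length
#' 8000 * kgap. Sequences too short for a given g contribute an all-zero
#' block for that g.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param kgap Maximum gap width (>= 1).
#' @param id Optional sequence id used in error messages.
#' @return A named numeric vector of length `8000 * kgap`; names are
#'   `g<g>:X_YZ`, blocks ordered g = 1 first, patterns lexicographic within a
#'   block.
#' @examples
#' v <- mono_di_kgap_encode("ACDE", kgap = 1)
#' v[v > 0]  # the single window A.C.DE -> pattern "A_DE"
#' @export
mono_di_kgap_encode <- function(sequence, kgap, id = NULL) {
  stopifnot(length(kgap) == 1, kgap >= 1)
  idx <- aa_indices(sequence, id)
  L <- length(idx)
  blocks <- map(seq_len(kgap), function(g) {
    n_win <- L - g - 2L
    if (n_win < 1L) {
      return(numeric(8000L))
    }
    p <- seq_len(n_win)
    codes <- (idx[p] - 1L) * 400L + (idx[p + g + 1L] - 1L) * 20L + idx[p + g + 2L]
    tabulate(codes, nbins = 8000L) / n_win
  })
  v <- unlist(blocks, use.names = FALSE)
  names(v) <- monodikgap_vocabulary(kgap)
  v
}

#' Cross-covariance transform of a PSSM (CC-PSSM)
#'
#' Converts a variable-length L x 20 profile into a fixed-length descriptor:
#' for every ordered pair of distinct residue columns (i1, i2) and every lag
#' LG in 1..`lag`,
#' \deqn{CC(i1, i2, LG) = \sum_{j=1}^{L-LG}
#'   (S_{j,i1} - \bar S_{i1})(S_{j+LG,i2} - \bar S_{i2}) / (L - LG)}
#' where \eqn{\bar S_i} is the mean of column i over all L rows. With 380
#' ordered pairs the vector has length `380 * lag`. The transform is invariant
#' to adding a constant to any whole column.
#'
#' @param profile A [pssm_profile()].
#' @param lag Maximum lag (>= 1); the profile must have more rows than `lag`.
#' @return A named numeric vector of length `380 * lag`; names are
#'   `lag<LG>:i1|i2`, lags ascending, pairs lexicographic within a lag.
#' @export
cc_pssm_encode <- function(profile, lag) {
  stopifnot(inherits(profile, "pssm_profile"), length(lag) == 1, lag >= 1)
  S <- profile$scores
  L <- nrow(S)
  if (L <= lag) {
    abort(sprintf("PSSM '%s' has %d rows; need more than lag = %d",
                  profile$id, L, lag),
          class = "dbpkit_encoding_error")
  }
  C <- sweep(S, 2L, colMeans(S))
  off_diag <- as.vector(t(outer(1:20, 1:20, "!=")))  # row-major i1 then i2
  blocks <- map(seq_len(lag), function(LG) {
    M <- crossprod(C[seq_len(L - LG), , drop = FALSE],
                   C[seq.int(1L + LG, L), , drop = FALSE]) / (L - LG)
    as.vector(t(M))[off_diag]  # row-major: i1 outer, i2 inner, skip i1 == i2
  })
  v <- unlist(blocks, use.names = FALSE)
  names(v) <- ccpssm_vocabulary(lag)
  v
}

#' Encoder specifications
#'
#' Encoder specs are small descriptor objects consumed by [encode_matrix()];
#' each names its parameters and the feature-vocabulary prefix used in the
#' combined matrix.
#'
#' @param k,kgap,lag Encoder parameters (see [kmer_encode()],
#'   [mono_di_kgap_encode()], [cc_pssm_encode()]).
#' @param profiles For the CC-PSSM encoder: a named list of [pssm_profile()]
#'   objects covering every sequence id, or a path to a PSSM manifest TSV.
#' @return An object of class `encoder_spec`.
#' @name encoder_specs
NULL

#' @rdname encoder_specs
#' @export
encoder_kmer <- function(k = 2) {
  new_encoder_spec("kmer", list(k = k), prefix = paste0("kmer", k))
}

#' @rdname encoder_specs
#' @export
encoder_monodikgap <- function(kgap = 2) {
  new_encoder_spec("monodikgap", list(kgap = kgap), prefix = "kgap")
}

#' @rdname encoder_specs
#' @export
encoder_ccpssm <- function(lag = 2, profiles = NULL) {
  if (is.character(profiles)) {
    profiles <- read_pssm_manifest(profiles)
  }
  new_encoder_spec("ccpssm", list(lag = lag), prefix = "cc", profiles = profiles)
}

new_encoder_spec <- function(name, params, prefix, profiles = NULL) {
  structure(list(name = name, params = params, prefix = prefix,
                 profiles = profiles),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  cat(sprintf("<encoder_spec> %s(%s)\n", x$name,
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  invisible(x)
}

encoder_vocab <- function(spec) {
  switch(spec$name,
    kmer = kmer_vocabulary(spec$params$k),
    monodikgap = monodikgap_vocabulary(spec$params$kgap),
    ccpssm = ccpssm_vocabulary(spec$params$lag),
    abort(sprintf("unknown encoder '%s'", spec$name))
  )
}

encoder_apply <- function(spec, id, sequence) {
  switch(spec$name,
    kmer = kmer_encode(sequence, spec$params$k, id = id),
    monodikgap = mono_di_kgap_encode(sequence, spec$params$kgap, id = id),
    ccpssm = {
      prof <- spec$profiles[[id]]
      if (is.null(prof)) {
        abort(sprintf("no PSSM profile for sequence '%s'", id),
              class = "dbpkit_value_error")
      }
      cc_pssm_encode(prof, spec$params$lag)
    }
  )
}

#' Encode a dataset into a combined feature matrix
#'
#' Applies one or more encoders to every record and concatenates the
#' per-record vectors column-wise in the listed encoder order. Column names
#' are prefixed with the encoder tag (e.g. `kmer2:AC`, `kgap:g1:A_DE`,
#' `cc:lag1:A|C`), so feature provenance survives selection and model reuse.
#'
#' @param dataset A record tibble with columns `id` and `sequence` (a `label`
#'   column, if present, is ignored here).
#' @param encoders A single `encoder_spec` or a list of them.
#' @return A numeric matrix; rows named by sequence id, columns by the
#'   combined feature vocabulary. An empty dataset gives a 0-row matrix with
#'   the full vocabulary.
#' @export
encode_matrix <- function(dataset, encoders) {
  check_records(dataset)
  if (inherits(encoders, "encoder_spec")) encoders <- list(encoders)
  stopifnot(length(encoders) >= 1,
            all(vapply(encoders, inherits, logical(1), "encoder_spec")))
  vocab <- unlist(map(encoders, function(e) {
    paste0(e$prefix, ":", encoder_vocab(e))
  }), use.names = FALSE)
  n <- nrow(dataset)
  out <- matrix(0, nrow = n, ncol = length(vocab),
                dimnames = list(dataset$id, vocab))
  if (n == 0) return(out)
  col_off <- 0L
  for (e in encoders) {
    p <- length(encoder_vocab(e))
    cols <- col_off + seq_len(p)
    for (i in seq_len(n)) {
      out[i, cols] <- encoder_apply(e, dataset$id[i], dataset$sequence[i])
    }
    col_off <- col_off + p
  }
  out
}

#' Write / read a feature matrix as TSV
#'
#' The on-disk form is a header-bearing TSV whose first column (`row_id`)
#' holds sequence ids and remaining columns the named features.
#'
#' @param X Numeric matrix with row and column names.
#' @param path File path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns the matrix.
#' @export
write_feature_matrix <- function(X, path) {
  dt <- data.table::as.data.table(X, keep.rownames = "row_id")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  rn <- dt[[1]]
  X <- as.matrix(dt[, -1, drop = FALSE])
  rownames(X) <- rn
  X
}

# ---- vocabularies ---------------------------------------------------------

kmer_vocabulary <- function(k) {
  words <- AA_STANDARD
  if (k > 1) {
    for (j in seq_len(k - 1L)) {
      words <- as.vector(t(outer(words, AA_STANDARD, paste0)))
    }
  }
  words
}

monodikgap_vocabulary <- function(kgap) {
  di <- kmer_vocabulary(2)
  pats <- as.vector(t(outer(AA_STANDARD, di, paste, sep = "_")))
  unlist(map(seq_len(kgap), function(g) paste0("g", g, ":", pats)),
         use.names = FALSE)
}

ccpssm_vocabulary <- function(lag) {
  grid <- expand.grid(i2 = AA_STANDARD, i1 = AA_STANDARD,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$i1 != grid$i2, ]  # i1 varies slowest -> lexicographic pairs
  pairs <- paste0(grid$i1, "|", grid$i2)
  unlist(map(seq_len(lag), function(LG) paste0("lag", LG, ":", pairs)),
         use.names = FALSE)
}

aa_indices <- function(sequence, id = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, AA_STANDARD)
  if (anyNA(idx)) {
    abort(sprintf(
      "sequence%s contains non-standard residues (%s); run filter_standard() first",
      if (is.null(id)) "" else paste0(" '", id, "'"),
      paste(unique(chars[is.na(idx)]), collapse = ", ")
    ), class = "dbpkit_encoding_error")
  }
  idx
}
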