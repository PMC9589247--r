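#' Specification for a synthetic two-class protein dataset
#'
#' Describes a labeled sequence set with plantable compositional signal:
#' sequences are drawn residue-wise from a background distribution, then
#' signal words (contiguous k-mers) and gapped patterns (mono + gap + di) are
#' inserted at uniformly random positions, overwriting background residues.
#' Copy numbers per sequence are Poisson with rate `base_rate` in the
#' negative class and `base_rate * multiplier` in the positive class, so the
#' enrichment of each planted pattern is exact and auditable. Matching
#' synthetic PSSMs can be derived with [generate_pssms()].
#'
#' @param n_pos,n_neg Class sizes (positives = DNA-binding). The defaults
#'   mirror the mild imbalance of the curated benchmark this generator
#'   emulates (525 binding / 544 non-binding).
#' @param length_range Integer min/max sequence length (min >= 3).
#' @param background Length-20 residue probability vector (alphabetical
#'   amino-acid order); default uniform.
#' @param signal_kmers Named numeric vector: names are signal words, values
#'   their positive-class enrichment multipliers.
#' @param signal_gap_patterns Tibble/data frame with columns `mono`, `gap`,
#'   `di`, `multiplier` describing gapped patterns.
#' @param base_rate Expected planted copies per sequence in the negative
#'   class.
#' @param pssm_noise_sd Spread of the integer noise added to synthetic PSSM
#'   scores.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_pos = 525, n_neg = 544, length_range = c(100, 200),
                     background = rep(1 / 20, 20),
                     signal_kmers = c(WY = 8, CM = 8, HQ = 8),
                     signal_gap_patterns = tibble(
                       mono = c("A", "K"), gap = c(1L, 2L),
                       di = c("DE", "RR"), multiplier = c(8, 8)
                     ),
                     base_rate = 1, pssm_noise_sd = 1, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1,
            length(length_range) == 2, length_range[1] >= 3,
            length_range[1] <= length_range[2],
            length(background) == 20, all(background >= 0),
            abs(sum(background) - 1) < 1e-8,
            base_rate >= 0, pssm_noise_sd >= 0)
  if (length(signal_kmers)) {
    stopifnot(!is.null(names(signal_kmers)), all(signal_kmers > 0),
              all(grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "]+$"),
                        names(signal_kmers))))
  }
  signal_gap_patterns <- as_tibble(signal_gap_patterns)
  if (nrow(signal_gap_patterns)) {
    stopifnot(all(c("mono", "gap", "di", "multiplier") %in%
                    names(signal_gap_patterns)),
              all(signal_gap_patterns$multiplier > 0),
              all(signal_gap_patterns$gap >= 1),
              all(nchar(signal_gap_patterns$mono) == 1),
              all(nchar(signal_gap_patterns$di) == 2))
  }
  widths <- c(nchar(names(signal_kmers)),
              signal_gap_patterns$gap + 3L)
  if (length(widths) && max(widths) > length_range[2]) {
    abort("a signal pattern is longer than the maximum sequence length",
          class = "dbpkit_value_error")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 background = background, signal_kmers = signal_kmers,
                 signal_gap_patterns = signal_gap_patterns,
                 base_rate = base_rate, pssm_noise_sd = pssm_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf("<sim_spec> %d pos / %d neg, lengths %d-%d, %d signal patterns, seed %d\n",
              x$n_pos, x$n_neg, x$length_range[1], x$length_range[2],
              length(x$signal_kmers) + nrow(x$signal_gap_patterns), x$seed))
  invisible(x)
}

#' Preset simulation scenarios
#'
#' Three study conditions used throughout the documentation and tests:
#' `"strong"` (enrichment multiplier 8 on five planted patterns), `"weak"`
#' (multiplier 2) and `"null"` (multiplier 1 — classes exchangeable).
#'
#' @param name One of `"strong"`, `"weak"`, `"null"`.
#' @param ... Overrides passed to [sim_spec()] (e.g. `n_pos`, `seed`).
#' @return A `sim_spec`.
#' @export
sim_preset <- function(name = c("strong", "weak", "null"), ...) {
  name <- match.arg(name)
  mult <- switch(name, strong = 8, weak = 2, null = 1)
  defaults <- list(
    signal_kmers = c(WY = mult, CM = mult, HQ = mult),
    signal_gap_patterns = tibble(
      mono = c("A", "K"), gap = c(1L, 2L),
      di = c("DE", "RR"), multiplier = c(mult, mult)
    )
  )
  do.call(sim_spec, utils::modifyList(defaults, list(...)))
}

#' Generate a labeled synthetic dataset
#'
#' @param spec A [sim_spec()].
#' @return A labeled dataset tibble (`id`, `sequence`, `label`) with
#'   positives first; ids are `pos_####` / `neg_####`. The realized planted
#'   copy counts are attached as attribute `"planted"` (a tibble) for
#'   auditing.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  patterns <- sim_patterns(spec)
  n <- spec$n_pos + spec$n_neg
  labels <- rep(c(1L, 0L), c(spec$n_pos, spec$n_neg))
  ids <- c(sprintf("pos_%04d", seq_len(spec$n_pos)),
           sprintf("neg_%04d", seq_len(spec$n_neg)))
  seqs <- character(n)
  planted <- vector("list", n)
  for (i in seq_len(n)) {
    L <- sample.int(spec$length_range[2] - spec$length_range[1] + 1L, 1L) +
      spec$length_range[1] - 1L
    chars <- sample(AA_STANDARD, L, replace = TRUE, prob = spec$background)
    counts <- integer(nrow(patterns))
    for (pi in seq_len(nrow(patterns))) {
      rate <- spec$base_rate *
        if (labels[i] == 1L) patterns$multiplier[pi] else 1
      copies <- rpois(1L, rate)
      width <- patterns$width[pi]
      if (width > L) copies <- 0L
      counts[pi] <- copies
      if (copies > 0) {
        starts <- sample.int(L - width + 1L, copies, replace = TRUE)
        pat_chars <- strsplit(patterns$pattern[pi], "")[[1]]
        write_at <- which(pat_chars != ".")
        for (s in starts) {
          chars[s + write_at - 1L] <- pat_chars[write_at]
        }
      }
    }
    seqs[i] <- paste(chars, collapse = "")
    planted[[i]] <- counts
  }
  out <- tibble(id = ids, sequence = seqs, label = labels)
  planted_tbl <- as_tibble(do.call(rbind, planted), .name_repair = "minimal")
  names(planted_tbl) <- patterns$name
  attr(out, "planted") <- mutate(planted_tbl, id = ids, .before = 1)
  out
}

# Internal table of planted patterns: gap positions are "." (left as
# background), giving each pattern a literal write mask.
sim_patterns <- function(spec) {
  rows <- list()
  for (w in names(spec$signal_kmers)) {
    rows[[length(rows) + 1]] <- tibble(
      name = w, pattern = w, width = nchar(w),
      multiplier = unname(spec$signal_kmers[[w]]),
      feature = if (nchar(w) == 2) paste0("kmer2:", w) else NA_character_
    )
  }
  gp <- spec$signal_gap_patterns
  for (i in seq_len(nrow(gp))) {
    rows[[length(rows) + 1]] <- tibble(
      name = paste0(gp$mono[i], "_g", gp$gap[i], "_", gp$di[i]),
      pattern = paste0(gp$mono[i], strrep(".", gp$gap[i]), gp$di[i]),
      width = gp$gap[i] + 3L,
      multiplier = gp$multiplier[i],
      feature = paste0("kgap:g", gp$gap[i], ":", gp$mono[i], "_", gp$di[i])
    )
  }
  bind_rows(rows)
}

#' Feature names corresponding to a spec's planted signal
#'
#' Maps each planted pattern to its name in the encoder vocabulary (dimer
#' signal words to `kmer2:XY`, gapped patterns to `kgap:g<g>:X_YZ`), for use
#' in selection-recovery checks.
#'
#' @param spec A [sim_spec()].
#' @return Character vector of feature names.
#' @export
signal_feature_names <- function(spec) {
  pats <- sim_patterns(spec)
  pats$feature[!is.na(pats$feature)]
}

#' Generate synthetic PSSM profiles consistent with a dataset
#'
#' Each position's observed residue receives a high substitution score and
#' all other residues a low one, plus rounded Gaussian noise of spread
#' `pssm_noise_sd`; at noise 0 the profile is exactly a scaled one-hot
#' encoding of the sequence. Scores are integers so profiles round-trip
#' bit-exactly through the ASCII PSSM reader/writer.
#'
#' @param dataset A record tibble (`id`, `sequence`).
#' @param spec The [sim_spec()] (supplies `pssm_noise_sd` and the seed).
#' @param high,low Scores for the observed / unobserved residues.
#' @return A named list of [pssm_profile()] objects.
#' @export
generate_pssms <- function(dataset, spec, high = 7L, low = -1L) {
  check_records(dataset)
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 1L)   # distinct stream from sequence generation
  profiles <- map(seq_len(nrow(dataset)), function(i) {
    idx <- aa_indices(dataset$sequence[i], dataset$id[i])
    L <- length(idx)
    sc <- matrix(low, nrow = L, ncol = 20L,
                 dimnames = list(NULL, AA_STANDARD))
    sc[cbind(seq_len(L), idx)] <- high
    if (spec$pssm_noise_sd > 0) {
      sc <- sc + round(matrix(rnorm(L * 20L, sd = spec$pssm_noise_sd), L, 20L))
      storage.mode(sc) <- "integer"
    }
    pssm_profile(dataset$id[i], dataset$sequence[i], sc)
  })
  setNames(profiles, dataset$id)
}
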