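# Shared multi-seed pipeline runs for the recovery checks. The strong-signal
# study condition (balanced 500/500, lengths 100-200, enrichment 8, kgap2 +
# kmer2 encoders, ensemble selection, 50-epoch CNN) is expensive, so one set
# of runs feeds both the accuracy-recovery and ranking-recovery checks.
#
# Test accuracy is measured on a stratified 20% split held out before
# feature selection (run_pipeline's default), so selection bias cannot
# inflate it — essential for the null-preset control.

.recovery_cache <- new.env(parent = emptyenv())

recovery_config <- function(seed) {
  run_config(list(
    seed = seed,
    encoders = list(list(name = "monodikgap", kgap = 2),
                    list(name = "kmer", k = 2))
  ))
}

recovery_run_once <- function(preset, seed) {
  spec <- sim_preset(preset, n_pos = 500, n_neg = 500,
                     length_range = c(100, 200), seed = seed)
  ds <- generate_dataset(spec)
  res <- suppressWarnings(run_pipeline(ds, recovery_config(seed)))
  fused <- tidy(res$ranking)
  list(
    test_accuracy = res$report$acc,
    signal_ranks = match(signal_feature_names(spec), fused$feature),
    n_features = nrow(fused),
    n_selected = length(res$features)
  )
}

recovery_runs <- function(n_seeds = 10) {
  key <- paste0("strong_", n_seeds)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  runs <- lapply(seq_len(n_seeds), function(i) {
    recovery_run_once("strong", 1000 + i)
  })
  .recovery_cache[[key]] <- runs
  runs
}

null_run <- function(seed) {
  recovery_run_once("null", seed)$test_accuracy
}
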