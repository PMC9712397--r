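# session-level cache for the study-scale synthetic dataset, so the
# acceptance tests build it once and share it across test blocks
.study_env <- new.env(parent = emptyenv())

study_default <- function(seed = 101) {
  key <- paste0("default_", seed)
  if (is.null(.study_env[[key]])) {
    st <- synth_epochs(synth_config(seed = seed))
    st$features <- epoch_features(st$epochs)
    .study_env[[key]] <- st
  }
  .study_env[[key]]
}

# balanced windows for one band, majority capped for desk-scale training
study_windows <- function(st, band, cap = 2000, seed = 202) {
  ws <- balance_subsample(make_windows(st$epochs, band), seed = seed)
  cap_windows(ws, cap, seed = seed + 1)
}

# desk-scaled sequence-model settings used by the acceptance evaluations
lstm_desk_opts <- list(hidden = 48, dropout = 0.2, lr = 5e-3, epochs = 60,
                       patience = 10, restarts = 2)

# disjoint effect topography (right-hemisphere / occipital) for transfer runs
disjoint_effect_groups <- function() {
  list(alpha = c("Fp2", "AF4", "F4", "F8"),
       theta = c("P4", "P8", "CP6"),
       delta = c("O1", "Oz", "O2"))
}
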