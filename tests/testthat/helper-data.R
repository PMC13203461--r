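# Shared small synthetic cohort, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

small_cohort <- function(order = 1L, seed = 42L, procedure = "pre_context") {
  key <- paste0("cohort_", order, "_", seed, "_", procedure)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- synth_config(n_participants = 6, n_items = 4, trials_per_item = 3,
                      order = order, seed = seed, procedure = procedure)
  fx <- generate_fixations(cfg)
  seqs <- build_sequences(suppressMessages(clean_fixations(fx)),
                          cfg$face_layout)
  out <- list(cfg = cfg, fx = fx, seqs = seqs)
  .fixture_cache[[key]] <- out
  out
}

# Hand-built labelled sequence tibble from a list of label vectors.
labels_to_seqs <- function(labels_list) {
  dplyr::bind_rows(lapply(seq_along(labels_list), function(i) {
    tibble::tibble(participant = sprintf("P%02d", i),
                   label = labels_list[[i]])
  }))
}

# Simple one-item layout for hand-constructed fixation geometry tests:
# 300 px wide face, three 100 px bands starting at y = 0.
unit_layout <- function(item = "item01") {
  tibble::tibble(
    item = item,
    zone = c("UFZ", "CFZ", "LFZ"),
    x_min = 0, x_max = 300,
    y_min = c(0, 100, 200),
    y_max = c(100, 200, 300)
  )
}
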