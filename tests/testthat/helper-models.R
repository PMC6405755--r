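# A gap classifier shared across test files, trained once on demand on a
# missing-enriched synthetic set so all four classes are well represented.

shared_gap_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      gaps <- toothnum::generate_gap_training_set(
        toothnum::arch_config(p_missing = 0.30), 1200, seed = 424242)
      model <<- toothnum::train_gap_classifier(gaps$features, gaps$labels,
                                               seed = 424243)
    }
    model
  }
})
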