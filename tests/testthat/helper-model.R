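# Shared trained classifier, built once per test run. Kept small: 10
# training scenes, 200 samples per class, default features.
.wc_cache <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.wc_cache$model)) {
    fcfg <- feature_config()
    scenes <- lapply(1:10, function(s) generate_scene(scene_config(seed = 100 + s)))
    ts <- sample_training_set(scenes, 200, 200, fcfg, seed = 7)
    .wc_cache$model <- train_classifier(ts$descriptors, ts$labels,
                                        detector_config(), fcfg, seed = 7)
  }
  .wc_cache$model
}
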