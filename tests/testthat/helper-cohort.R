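# Shared phantom fixtures, generated once per test run and cached. The small
# grid (48 x 64 x 64) omits the nodal/PAN sheaths, which need the default
# grid's in-plane resolution to stay clear of the vertebral blocks.

small_structures <- c("bladder", "rectum", "cord", "kidney_l", "kidney_r",
                      "bone", "l4", "l5", "vessel")

small_spec <- function(...) {
  phantom_spec(grid_shape = c(48, 64, 64), structures = small_structures, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, make(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 8 jittered phantoms on the small grid; scans 1-6 train, 7-8 held out
small_cohort <- function() {
  cached("small_cohort", function() generate_cohort(small_spec(), n = 8, seed = 11))
}

# a single default-grid phantom with every structure
full_phantom <- function() {
  cached("full_phantom", function() generate_phantom(phantom_spec(), id = "full_001"))
}

# bladder models trained on the small cohort (used by several test files)
small_bladder_models <- function() {
  cached("small_bladder_models", function() {
    co <- small_cohort()[1:6]
    crop <- derive_crop_spec(co, "bladder")
    list(
      classifier = train_presence_classifier(co, "bladder"),
      coarse = train_segmenter(co, "bladder", mode = "volume_3d",
                               opt = adam_config(epochs = 300, seed = 3),
                               region = "extent", coarse_shape = c(32, 32)),
      refine = train_segmenter(co, "bladder", mode = "volume_3d",
                               opt = adam_config(epochs = 300, seed = 4),
                               region = "crop", crop = crop),
      crop = crop)
  })
}
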