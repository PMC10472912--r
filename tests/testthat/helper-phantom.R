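# Shared fixtures, built once per test run. Small grids keep unit tests
# fast; the acceptance tests build full-size phantoms themselves.

# Half-size head: the study-scale 2-3 mm vessel calibres would touch white
# matter in the cramped 48 mm geometry, so the smoke fixture thins them.
small_spec <- function(vessel_radius_mm = 1.5, ...) {
  phantom_spec(grid_shape = c(48, 48, 48),
               vessel_radius_mm = vessel_radius_mm, ...)
}

# memoised small template + derived objects
.fixtures <- new.env()

small_template <- function() {
  if (is.null(.fixtures$tpl)) .fixtures$tpl <- generate_template(small_spec())
  .fixtures$tpl
}

small_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    tpl <- small_template()
    mra <- generate_mra_cohort(small_spec(), tpl, 3, seed = 7)
    .fixtures$bundle <- template_bundle(tpl$t1, tpl$brain_mask,
                                        build_blood_probability_map(mra))
  }
  .fixtures$bundle
}

small_subject <- function(seed = 5) {
  key <- paste0("subj", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_subject(small_spec(), small_template(),
                                         seed = seed)
  .fixtures[[key]]
}

# identity-configuration spec: no misalignment, bias or noise
identity_spec <- function(...) {
  phantom_spec(grid_shape = c(48, 48, 48), vessel_radius_mm = 1.5,
               noise_sigma = 0, bias_amplitude = 0,
               misalign_translation_mm = 0, misalign_rotation_deg = 0,
               misalign_scale = 0, warp_amplitude_mm = 0, ...)
}

# study-scale (96^3) fixture for the heuristics that depend on realistic
# cleft-to-white-matter separations
study_template <- function() {
  if (is.null(.fixtures$stpl))
    .fixtures$stpl <- generate_template(phantom_spec())
  .fixtures$stpl
}

study_subject <- function(seed = 5) {
  key <- paste0("ssubj", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_subject(phantom_spec(), study_template(),
                                         seed = seed)
  .fixtures[[key]]
}

random_volume <- function(dm = c(8, 8, 8), seed = 1, affine = diag(4)) {
  set.seed(seed)
  bn_volume(array(rnorm(prod(dm)), dm), affine)
}

random_mask <- function(dm = c(8, 8, 8), seed = 1, p = 0.5) {
  set.seed(seed)
  bn_mask(array(as.integer(runif(prod(dm)) < p), dm))
}

# largest connected component of the true white matter
truth_main_wm <- function(subject) {
  wm <- bn_mask(array(as.integer(subject$truth_labels$data == 3L),
                      dim(subject$truth_labels$data)),
                subject$truth_labels$affine)
  deblood:::largest_component(wm, 26)
}
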