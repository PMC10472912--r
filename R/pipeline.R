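#' Bundle the template inputs for the pipeline
#'
#' @param t1 template [bn_volume()].
#' @param brain_mask template brain [bn_mask()].
#' @param bpm blood [bn_probmap()] in template space.
#' @return a `template_bundle` list.
#' @export
template_bundle <- function(t1, brain_mask, bpm) {
  stop_if_grid_mismatch(t1, brain_mask, "template inputs")
  stop_if_grid_mismatch(t1, bpm, "template inputs")
  structure(list(t1 = t1, brain_mask = brain_mask, bpm = bpm),
            class = "template_bundle")
}

# resample the template-space blood probability map into subject space
# through the inverse of a subject->template affine
bpm_to_subject <- function(bpm, transform, subject) {
  v <- resample(bn_volume(bpm$data, bpm$affine), invert_affine(transform),
                subject)
  bn_probmap(array(pmin(1, pmax(0, v$data)), dim(v$data)), v$affine)
}

#' Run the blood-removal pipeline for one subject
#'
#' Stage order: bloodless-mask affine registration to the template; brain
#' extraction intersected with the complement of the major-vessel mask;
#' nonuniformity correction and intensity normalisation; re-registration;
#' tissue classification; white-matter grouping; gradient-difference map;
#' artifact seeding and vascular expansion; refined registration with the
#' brain-minus-blood mask; main-group recovery; brain-mask periphery trim;
#' blended CSF replacement.
#'
#' @param t1 subject T1-weighted [bn_volume()].
#' @param bundle a [template_bundle()].
#' @param config a [bn_config()].
#' @param work_dir optional directory; when given, every intermediate is
#'   written under stable filenames. With `resume = TRUE` a completed run is
#'   reloaded instead of recomputed.
#' @param resume reuse results found in `work_dir`.
#' @param verbose print stage progress.
#' @return list of class `deblood_result`: `blood_mask`, `deblooded`,
#'   `corrected` (bias-corrected, intensity-normalised bloody scan),
#'   `brain_mask_initial` (extracted from the bloody scan, artifact
#'   periphery included), `brain_mask` (extracted from the deblooded scan),
#'   `brain_mask_trimmed` (initial mask after periphery trimming, used for
#'   the refined registration), `labels`, `transform` (final
#'   subject-to-template [bn_affine()]), `grad_diff`, `bpm_subject`,
#'   `weights`, `csf`, and a `provenance` data.frame (stage, seconds,
#'   voxels).
#' @export
run_subject <- function(t1, bundle, config = bn_config(), work_dir = NULL,
                        resume = FALSE, verbose = FALSE) {
  if (!is.null(work_dir)) dir.create(work_dir, showWarnings = FALSE,
                                     recursive = TRUE)
  done_file <- if (!is.null(work_dir)) file.path(work_dir, "provenance.tsv")
  if (resume && !is.null(work_dir) && file.exists(done_file))
    return(load_subject_result(work_dir))
  prov <- data.frame(stage = character(), seconds = numeric(),
                     voxels = numeric(), stringsAsFactors = FALSE)
  note <- function(stage, t0, voxels = NA_real_) {
    sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (verbose) message(sprintf("[%s] %.2fs", stage, sec))
    prov <<- rbind(prov, data.frame(stage = stage, seconds = sec,
                                    voxels = voxels))
  }

  t0 <- Sys.time()
  bloodless <- make_bloodless_mask(bundle$bpm, bundle$brain_mask,
                                   config$bloodless_threshold)
  T0 <- register_affine(t1, bundle$t1, bloodless, config = config)
  note("initial_registration", t0)

  t0 <- Sys.time()
  brain0 <- extract_brain_mask(t1)
  bpm_s0 <- bpm_to_subject(bundle$bpm, T0, t1)
  major <- binarize_probmap(bpm_s0, config$major_vessel_threshold)
  workmask <- bn_mask(array(as.integer(brain0$data == 1 & major$data == 0),
                            dim(brain0$data)), brain0$affine)
  note("brain_extraction", t0, mask_count(brain0))

  t0 <- Sys.time()
  corrected <- correct_nonuniformity(t1, workmask)
  normalized <- normalize_intensity(corrected, workmask, bundle$t1,
                                    bundle$brain_mask)
  # re-extract on the corrected scan: bias-darkened CSF that fell below the
  # raw foreground threshold is recovered
  brain0 <- extract_brain_mask(normalized)
  note("nonuniformity_normalization", t0, mask_count(brain0))

  t0 <- Sys.time()
  T1 <- register_affine(normalized, bundle$t1, bloodless, config = config,
                        init = T0)
  note("re_registration", t0)

  t0 <- Sys.time()
  labels <- classify_tissue(normalized, brain0, config$rng_seed)
  grouping <- group_white_matter(labels, config$wm_connectivity)
  note("classification_grouping", t0, sum(labels$data == 3L))

  t0 <- Sys.time()
  subj_grad <- gradient_magnitude(normalized, config$gradient_fwhm_mm)
  tmpl_grad <- gradient_magnitude(bundle$t1, config$gradient_fwhm_mm)
  tmpl_grad_s <- resample(tmpl_grad, invert_affine(T1), t1)
  grad_diff <- gradient_difference_map(subj_grad, tmpl_grad_s,
                                       config$graddiff_blur_fwhm_mm)
  note("gradient_difference", t0)

  t0 <- Sys.time()
  bpm_s <- bpm_to_subject(bundle$bpm, T1, t1)
  seeds <- seed_blood_voxels(labels, grouping, grad_diff, bpm_s, brain0,
                             config)
  blood <- expand_blood_mask(seeds, labels, grouping, grad_diff, bpm_s,
                             brain0, config)
  note("seed_expand", t0, mask_count(blood))

  t0 <- Sys.time()
  refined <- refine_brain_mask(brain0, blood)
  T2 <- register_affine(normalized, bundle$t1, bundle$brain_mask,
                        moving_mask = refined, config = config, init = T1)
  bpm_s2 <- bpm_to_subject(bundle$bpm, T2, t1)
  blood <- recover_main_group_blood(grouping, bpm_s2, grad_diff, blood,
                                    brain0, config)
  note("refined_registration_recovery", t0, mask_count(blood))

  t0 <- Sys.time()
  trimmed <- trim_brain_mask_periphery(brain0, blood)
  csf <- csf_mean(normalized, labels)
  w <- make_replacement_weights(blood, config$replacement_dilate_iters,
                                config$replacement_blur_fwhm_mm)
  deblooded <- apply_deblooding(normalized, w, csf)
  # outside the trimmed brain mask the replacement target is background,
  # not CSF: suppressed flowing blood carries no signal, and there is no
  # CSF compartment past the brain boundary
  outside <- trimmed$data == 0
  deblooded$data[outside] <- normalized$data[outside] * (1 - w$data[outside])
  # the deblooded scan's own brain mask: with the artifacts suppressed,
  # extraction recovers the clean envelope. The corrected scan's
  # foreground threshold is reused since both versions share one intensity
  # scale.
  deblooded_mask <- extract_brain_mask(deblooded,
                                       threshold = attr(brain0, "threshold"))
  note("deblooding", t0, mask_count(deblooded_mask))

  out <- structure(list(blood_mask = blood, deblooded = deblooded,
                        corrected = normalized,
                        brain_mask_initial = brain0,
                        brain_mask = deblooded_mask,
                        brain_mask_trimmed = trimmed,
                        labels = labels, transform = T2,
                        grad_diff = grad_diff, bpm_subject = bpm_s2,
                        weights = w, csf = csf, provenance = prov),
                   class = "deblood_result")
  if (!is.null(work_dir)) save_subject_result(out, work_dir)
  out
}

save_subject_result <- function(res, work_dir) {
  p <- function(f) file.path(work_dir, f)
  write_mask(res$blood_mask, p("blood_mask.nii.gz"))
  write_volume(res$deblooded, p("deblooded.nii.gz"))
  write_volume(res$corrected, p("corrected.nii.gz"))
  write_mask(res$brain_mask_initial, p("brain_mask_initial.nii.gz"))
  write_mask(res$brain_mask, p("brain_mask.nii.gz"))
  write_mask(res$brain_mask_trimmed, p("brain_mask_trimmed.nii.gz"))
  write_volume(res$labels, p("labels.nii.gz"))
  write_volume(res$grad_diff, p("grad_diff.nii.gz"))
  write_volume(bn_volume(res$bpm_subject$data, res$bpm_subject$affine),
               p("bpm_subject.nii.gz"))
  write_volume(bn_volume(res$weights$data, res$weights$affine),
               p("weights.nii.gz"))
  write_affine(res$transform, p("transform.txt"))
  writeLines(format(res$csf, digits = 17), p("csf_mean.txt"))
  utils::write.table(res$provenance, p("provenance.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(work_dir)
}

load_subject_result <- function(work_dir) {
  p <- function(f) file.path(work_dir, f)
  lab <- read_volume(p("labels.nii.gz"))
  structure(list(
    blood_mask = read_mask(p("blood_mask.nii.gz")),
    deblooded = read_volume(p("deblooded.nii.gz")),
    corrected = read_volume(p("corrected.nii.gz")),
    brain_mask_initial = read_mask(p("brain_mask_initial.nii.gz")),
    brain_mask = read_mask(p("brain_mask.nii.gz")),
    brain_mask_trimmed = read_mask(p("brain_mask_trimmed.nii.gz")),
    labels = bn_labels(lab$data, lab$affine),
    transform = read_affine(p("transform.txt")),
    grad_diff = read_volume(p("grad_diff.nii.gz")),
    bpm_subject = bn_probmap(read_volume(p("bpm_subject.nii.gz"))$data,
                             read_volume(p("bpm_subject.nii.gz"))$affine),
    weights = bn_probmap(read_volume(p("weights.nii.gz"))$data,
                         read_volume(p("weights.nii.gz"))$affine),
    csf = as.numeric(readLines(p("csf_mean.txt"))),
    provenance = utils::read.delim(p("provenance.tsv"))),
    class = "deblood_result")
}

#' @export
print.deblood_result <- function(x, ...) {
  cat(sprintf("<deblood_result> %d blood voxels, CSF mean %.2f\n",
              mask_count(x$blood_mask), x$csf))
  invisible(x)
}

#' Run the pipeline and registration-impact evaluation over a cohort
#'
#' Applies [run_subject()] and [evaluate_subject()] to each subject
#' (per-subject seeds derived as `config$rng_seed + index`), then summarises
#' bloody vs deblooded registration quality and computes the cohort impact
#' maps.
#'
#' @param subjects list of subject T1 [bn_volume()]s (bloody scans).
#' @param bundle a [template_bundle()].
#' @param config a [bn_config()].
#' @param work_dir optional root directory for per-subject work dirs.
#' @param compute_impact also run the per-subject impact registration and
#'   return Jacobian/displacement max maps.
#' @param verbose print progress.
#' @return list of class `deblood_cohort`: `per_subject` (metrics
#'   data.frame), `summary` (from [cohort_summary()]), `impact` (from
#'   [impact_maps()] or NULL), `results` (per-subject `deblood_result`s),
#'   `failures` (character).
#' @export
run_cohort <- function(subjects, bundle, config = bn_config(),
                       work_dir = NULL, compute_impact = TRUE,
                       verbose = FALSE) {
  if (length(subjects) < 2) stop("need at least 2 subjects for t-tests")
  evals <- list()
  pairs <- list()
  results <- list()
  failures <- character()
  for (i in seq_along(subjects)) {
    id <- names(subjects)[i]
    if (is.null(id) || id == "") id <- sprintf("subject%02d", i)
    cfg_i <- config
    cfg_i$rng_seed <- config$rng_seed + i
    wd <- if (!is.null(work_dir)) file.path(work_dir, id)
    res <- tryCatch({
      r <- run_subject(subjects[[i]], bundle, cfg_i, work_dir = wd,
                       verbose = verbose)
      ev <- evaluate_subject(r$corrected, r$deblooded, r$brain_mask_initial,
                             r$brain_mask, bundle$t1, bundle$brain_mask,
                             cfg_i, subject_id = id, init = r$transform)
      list(r = r, ev = ev)
    }, error = function(e) {
      warning(sprintf("subject %s failed: %s", id, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      failures <- c(failures, id)
      next
    }
    results[[id]] <- res$r
    evals[[id]] <- res$ev$metrics
    pairs[[id]] <- list(bloody = res$ev$tlinnl_bloody_deblooded,
                        deblooded = res$ev$tlinnl_deblooded_deblooded)
    if (verbose) message(sprintf("subject %s done", id))
  }
  if (length(evals) < 2) stop("fewer than 2 subjects completed")
  per_subject <- do.call(rbind, evals)
  rownames(per_subject) <- NULL
  impact <- if (compute_impact)
    impact_maps(pairs, bundle$t1, bundle$brain_mask, config) else NULL
  out <- structure(list(per_subject = per_subject,
                        summary = cohort_summary(per_subject),
                        impact = impact, results = results,
                        failures = failures),
                   class = "deblood_cohort")
  if (!is.null(work_dir)) {
    utils::write.table(per_subject, file.path(work_dir, "per_subject.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(out$summary, file.path(work_dir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(impact)) {
      write_volume(impact$det_map, file.path(work_dir, "max_abs_jacobian.nii.gz"))
      write_volume(impact$disp_map, file.path(work_dir, "max_displacement.nii.gz"))
      write_mask(impact$det_overlay, file.path(work_dir, "jacobian_gt2.nii.gz"))
      write_mask(impact$disp_overlay, file.path(work_dir, "displacement_gt5.nii.gz"))
    }
  }
  out
}

#' @export
print.deblood_cohort <- function(x, ...) {
  cat(sprintf("<deblood_cohort> %d subject(s), %d failure(s)\n",
              nrow(x$per_subject), length(x$failures)))
  print(x$summary, digits = 4)
  invisible(x)
}
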