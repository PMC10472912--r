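#' Dice overlap of two masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`; two empty masks are defined to overlap
#' perfectly (1.0).
#'
#' @param a,b [bn_mask()]s on the same grid.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  stop_if_grid_mismatch(a, b, "masks")
  na <- sum(a$data)
  nb <- sum(b$data)
  if (na + nb == 0) return(1.0)
  2 * sum(a$data == 1 & b$data == 1) / (na + nb)
}

#' Two-tailed paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = y - x` and the sample SD;
#' two-tailed p from the t distribution with n-1 degrees of freedom.
#' Zero-variance limits: all-zero differences give `t = 0, p = 1`; constant
#' non-zero differences give `t = +-Inf, p = 0`.
#'
#' @param x,y equal-length numeric vectors, n >= 2.
#' @return list with `t` and `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- y - x
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

#' Voxelwise maximum across volumes
#'
#' @param volumes non-empty list of [bn_volume()]s on a common grid.
#' @return a [bn_volume()].
#' @export
max_map <- function(volumes) {
  if (length(volumes) < 1) stop("need at least one volume")
  ref <- volumes[[1]]
  acc <- ref$data
  for (v in volumes[-1]) {
    stop_if_grid_mismatch(ref, v)
    acc <- pmax(acc, v$data)
  }
  bn_volume(acc, ref$affine)
}

#' Threshold overlay mask
#'
#' Binary mask of voxels exceeding a threshold, restricted to a mask.
#'
#' @param map a [bn_volume()].
#' @param threshold scalar; voxels strictly above it are kept.
#' @param mask optional restricting [bn_mask()].
#' @return a [bn_mask()].
#' @export
threshold_overlay <- function(map, threshold, mask = NULL) {
  sel <- map$data > threshold
  if (!is.null(mask)) sel <- sel & mask$data == 1
  bn_mask(array(as.integer(sel), dim(map$data)), map$affine)
}

#' Evaluate the registration impact of artifacts for one subject
#'
#' Registers the subject to the template twice — once driven by the bloody
#' scan, once by the deblooded scan — linearly and nonlinearly, then applies
#' each transform to the deblooded scan (the similarity comparand is always
#' the deblooded scan, so only the transforms are compared) and to the
#' corresponding brain mask, and scores Dice against the template mask and
#' mutual information against the template.
#'
#' @param bloody corrected bloody [bn_volume()] (subject space).
#' @param deblooded deblooded [bn_volume()] (subject space).
#' @param bloody_mask subject brain mask including artifact periphery.
#' @param deblooded_mask trimmed subject brain mask.
#' @param template template [bn_volume()].
#' @param template_mask template brain [bn_mask()].
#' @param config a [bn_config()].
#' @param subject_id identifier carried into the output.
#' @param init optional common initial [bn_affine()] for both arms (for
#'   example the pipeline's final subject-to-template transform); the two
#'   registrations then differ only through the artifacts' local pull, not
#'   through coarse-search path differences.
#' @return list with `metrics` (one-row data.frame of the 8 scores) and the
#'   template-space volumes `tlinnl_bloody_deblooded`,
#'   `tlinnl_deblooded_deblooded` used for the impact maps.
#' @export
evaluate_subject <- function(bloody, deblooded, bloody_mask, deblooded_mask,
                             template, template_mask, config = bn_config(),
                             subject_id = "subject", init = NULL) {
  run_arm <- function(driver, drv_mask) {
    lin <- register_affine(driver, template, template_mask, config = config,
                           init = init)
    nl <- register_nonlinear(driver, template, lin, template_mask, config)
    list(lin = lin, nl = nl,
         mask_lin = resample(drv_mask, lin, template),
         mask_nl = resample(drv_mask, nl, template),
         vol_lin = resample(deblooded, lin, template),
         vol_nl = resample(deblooded, nl, template))
  }
  arm_b <- tryCatch(run_arm(bloody, bloody_mask),
                    error = function(e) stop(sprintf("subject %s (bloody arm): %s",
                                                     subject_id, conditionMessage(e))))
  arm_d <- tryCatch(run_arm(deblooded, deblooded_mask),
                    error = function(e) stop(sprintf("subject %s (deblooded arm): %s",
                                                     subject_id, conditionMessage(e))))
  mi <- function(v) mutual_information(template, v, template_mask, config$mi_bins)
  metrics <- data.frame(
    subject_id = subject_id,
    dice_lin_bloody = dice(arm_b$mask_lin, template_mask),
    dice_lin_deblooded = dice(arm_d$mask_lin, template_mask),
    mi_lin_bloody = mi(arm_b$vol_lin),
    mi_lin_deblooded = mi(arm_d$vol_lin),
    dice_nl_bloody = dice(arm_b$mask_nl, template_mask),
    dice_nl_deblooded = dice(arm_d$mask_nl, template_mask),
    mi_nl_bloody = mi(arm_b$vol_nl),
    mi_nl_deblooded = mi(arm_d$vol_nl),
    stringsAsFactors = FALSE)
  list(metrics = metrics,
       tlinnl_bloody_deblooded = arm_b$vol_nl,
       tlinnl_deblooded_deblooded = arm_d$vol_nl)
}

#' Cohort summary of bloody vs deblooded registration quality
#'
#' Mean and variance per arm and a two-tailed paired t-test per metric, one
#' row for each of: linear mask Dice, linear similarity (MI), nonlinear mask
#' Dice, nonlinear similarity (MI).
#'
#' @param evals data.frame of per-subject metrics (rows from
#'   [evaluate_subject()]).
#' @return data.frame with columns `metric`, `bloody_mean`, `bloody_var`,
#'   `deblooded_mean`, `deblooded_var`, `t`, `p`.
#' @export
cohort_summary <- function(evals) {
  if (nrow(evals) < 2) stop("need at least 2 subjects for t-tests")
  rows <- list(
    c("linear_mask_dice", "dice_lin_bloody", "dice_lin_deblooded"),
    c("linear_similarity_mi", "mi_lin_bloody", "mi_lin_deblooded"),
    c("nonlinear_mask_dice", "dice_nl_bloody", "dice_nl_deblooded"),
    c("nonlinear_similarity_mi", "mi_nl_bloody", "mi_nl_deblooded"))
  out <- do.call(rbind, lapply(rows, function(r) {
    b <- evals[[r[2]]]
    d <- evals[[r[3]]]
    tt <- paired_t_test(b, d)
    data.frame(metric = r[1],
               bloody_mean = mean(b), bloody_var = stats::var(b),
               deblooded_mean = mean(d), deblooded_var = stats::var(d),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }))
  out
}

#' Cohort impact maps from paired template-space volumes
#'
#' For each subject, nonlinearly registers the bloody-transform version of
#' the deblooded scan to the deblooded-transform version (both already in
#' template space); the warp needed is attributed to the artifacts. Outputs
#' the voxelwise cohort maximum of the absolute Jacobian determinant and of
#' the displacement magnitude.
#'
#' @param pairs list of lists with elements `bloody` and `deblooded`
#'   (template-space [bn_volume()]s).
#' @param template template [bn_volume()] (defines the grid).
#' @param template_mask template brain [bn_mask()].
#' @param config a [bn_config()].
#' @return list with `det_map`, `disp_map` ([bn_volume()]s), the overlay
#'   masks `det_overlay` (>2) and `disp_overlay` (>5 mm), and `n_used`.
#' @export
impact_maps <- function(pairs, template, template_mask, config = bn_config()) {
  dets <- list()
  disps <- list()
  for (i in seq_along(pairs)) {
    res <- tryCatch({
      nl <- register_nonlinear(pairs[[i]]$bloody, pairs[[i]]$deblooded,
                               bn_affine(), template_mask, config)
      list(det = jacobian_determinant_map(nl, template),
           disp = displacement_magnitude_map(nl, template))
    }, error = function(e) {
      warning(sprintf("impact registration failed for subject %d: %s",
                      i, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      dets[[length(dets) + 1]] <- res$det
      disps[[length(disps) + 1]] <- res$disp
    }
  }
  if (length(dets) == 0) stop("all impact registrations failed")
  det_map <- max_map(dets)
  disp_map <- max_map(disps)
  list(det_map = det_map, disp_map = disp_map,
       det_overlay = threshold_overlay(det_map, 2, template_mask),
       disp_overlay = threshold_overlay(disp_map, 5, template_mask),
       n_used = length(dets))
}
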