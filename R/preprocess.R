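#' Extract a brain mask by thresholding and morphology
#'
#' Foreground threshold at 0.4 of the Otsu value (Otsu separates the
#' dominant bright tissue from background; the reduced cut keeps
#' low-intensity CSF and its partial-volume boundary layer inside the mask
#' while staying above the noise floor), largest 26-connected
#' component, 6-connected morphological closing, interior hole filling. A
#' lightweight stand-in for dedicated brain extraction tools with the same
#' contract: one connected head-interior component.
#'
#' @param t1 a [bn_volume()].
#' @param threshold optional absolute foreground threshold, overriding the
#'   Otsu-derived one (useful to extract comparable masks from two versions
#'   of the same scan on one intensity scale).
#' @param closing morphological closing passes (6-connected); deeper closing
#'   bridges surface grooves so interior cavities can be hole-filled.
#' @return a [bn_mask()] with attribute `threshold`.
#' @export
extract_brain_mask <- function(t1, threshold = NULL, closing = 2) {
  x <- as.numeric(t1$data)
  if (max(x) <= min(x)) stop("empty foreground: volume is constant")
  thr <- if (is.null(threshold)) 0.4 * otsu_threshold(x) else threshold
  fg <- bn_mask(array(as.integer(t1$data > thr), dim(t1$data)), t1$affine)
  if (mask_count(fg) == 0) stop("empty foreground")
  fg <- largest_component(fg, 26)
  fg <- mask_erode(mask_dilate(fg, closing, 6), closing, 6)
  fg <- largest_component(fg, 26)
  out <- fill_holes(fg, 6)
  attr(out, "threshold") <- thr
  out
}

otsu_threshold <- function(x, nbins = 256) {
  r <- range(x)
  h <- tabulate(pmin(nbins, 1L + as.integer((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + k / nbins * diff(r)
}

#' Correct smooth multiplicative intensity nonuniformity
#'
#' Estimates the bias as a degree-2 3D polynomial fit to the log intensity of
#' the brightest tissue class (nominally white matter, selected by a
#' deterministic 1D 3-means clustering of masked intensities), divides it
#' out, and rescales so the masked mean is preserved. Fitting to one tissue
#' class keeps anatomical contrast out of the bias estimate, so bias-free
#' input passes through essentially unchanged.
#'
#' @param t1 a [bn_volume()].
#' @param mask non-empty brain [bn_mask()] on the same grid.
#' @return bias-corrected [bn_volume()] with attribute `bias_field`.
#' @export
correct_nonuniformity <- function(t1, mask) {
  stop_if_grid_mismatch(t1, mask)
  if (mask_count(mask) == 0) stop("mask is empty")
  inmask <- mask$data == 1 & t1$data > 0
  vals <- t1$data[inmask]
  cl <- kmeans1d(vals, 3)
  top <- inmask & t1$data >= cl$cuts[2]
  # partial-volume voxels at the class surface carry a systematic radial
  # intensity pattern that the polynomial would mistake for bias; keep the
  # class interior only
  top_m <- bn_mask(array(as.integer(top), dim(t1$data)), t1$affine)
  eroded <- mask_erode(top_m, 1, 6)
  if (mask_count(eroded) >= 100) top <- eroded$data == 1
  # anchor on the class mode: even heavy vessel-artifact contamination
  # leaves the true tissue as the plurality, and artifacts sit far (>30%)
  # above it while a plausible bias stays within +-20%
  lx <- log(t1$data[top])
  h <- hist(lx, breaks = 64, plot = FALSE)
  mode_l <- h$mids[which.max(h$counts)]
  keep0 <- abs(lx - mode_l) <= 0.2
  if (sum(keep0) >= 100) {
    idx <- which(top)
    top[] <- FALSE
    top[idx[keep0]] <- TRUE
  }
  g <- world_grid(t1)
  nrm <- function(a) {
    r <- range(a)
    if (diff(r) == 0) a * 0 else 2 * (a - r[1]) / diff(r) - 1
  }
  design <- function(sel) {
    cbind(1, nrm(g$x)[sel], nrm(g$y)[sel], nrm(g$z)[sel],
          nrm(g$x)[sel]^2, nrm(g$y)[sel]^2, nrm(g$z)[sel]^2,
          nrm(g$x)[sel] * nrm(g$y)[sel], nrm(g$x)[sel] * nrm(g$z)[sel],
          nrm(g$y)[sel] * nrm(g$z)[sel])
  }
  # two-pass fit: bright outliers (vessel artifacts) and dark
  # partial-volume voxels would masquerade as bias, so voxels with large
  # residuals against a first fit are dropped before the final fit
  sel <- top
  fit <- NULL
  for (pass in 1:2) {
    X <- design(sel)
    fit <- stats::lm.fit(X, log(t1$data[sel]))
    if (fit$rank < ncol(X)) stop("degenerate fit: rank-deficient bias design")
    if (pass == 1) {
      r <- fit$residuals
      band <- max(3 * stats::mad(r), 0.02)
      keep <- abs(r - stats::median(r)) <= band
      if (sum(keep) >= 100) {
        idx <- which(sel)
        sel <- rep(FALSE, length(sel))
        dim(sel) <- dim(top)
        sel[idx[keep]] <- TRUE
      } else break
    }
  }
  cf <- fit$coefficients
  xn <- nrm(g$x); yn <- nrm(g$y); zn <- nrm(g$z)
  logb <- cf[1] + cf[2] * xn + cf[3] * yn + cf[4] * zn + cf[5] * xn^2 +
    cf[6] * yn^2 + cf[7] * zn^2 + cf[8] * xn * yn + cf[9] * xn * zn +
    cf[10] * yn * zn
  logb <- logb - mean(logb[mask$data == 1])
  # fields below 2% amplitude within the mask are indistinguishable from
  # fit noise on unbiased data and are not applied
  if (max(abs(logb[mask$data == 1])) < 0.02) logb <- logb * 0
  field <- exp(logb)
  out <- t1$data / field
  sc <- mean(t1$data[mask$data == 1]) / mean(out[mask$data == 1])
  out <- out * sc
  res <- bn_volume(out, t1$affine)
  attr(res, "bias_field") <- field
  res
}

# deterministic 1D k-means (quantile init, Lloyd updates); returns centres
# (sorted) and the midpoint cuts between them
kmeans1d <- function(x, k, iters = 30) {
  cen <- as.numeric(quantile(x, (seq_len(k) * 2 - 1) / (2 * k)))
  for (it in seq_len(iters)) {
    cuts <- (head(cen, -1) + tail(cen, -1)) / 2
    grp <- findInterval(x, cuts) + 1
    newc <- vapply(seq_len(k), function(i)
      if (any(grp == i)) mean(x[grp == i]) else cen[i], 0)
    if (max(abs(newc - cen)) < 1e-10) { cen <- newc; break }
    cen <- newc
  }
  cuts <- (head(cen, -1) + tail(cen, -1)) / 2
  list(centres = cen, cuts = cuts)
}

#' Linear intensity normalization by percentile matching
#'
#' Rescales so the subject's masked 10th/90th intensity percentiles match the
#' reference's (computed over the reference's positive voxels, or
#' `ref_mask`). Percentile anchors are robust to the bright artifact tail.
#'
#' @param t1 a [bn_volume()].
#' @param mask non-empty [bn_mask()] on the subject grid.
#' @param reference reference [bn_volume()] (any grid).
#' @param ref_mask optional [bn_mask()] for the reference.
#' @return rescaled [bn_volume()].
#' @export
normalize_intensity <- function(t1, mask, reference, ref_mask = NULL) {
  stop_if_grid_mismatch(t1, mask)
  if (mask_count(mask) == 0) stop("mask is empty")
  sv <- t1$data[mask$data == 1]
  rv <- if (is.null(ref_mask)) reference$data[reference$data > 0]
        else reference$data[ref_mask$data == 1]
  sp <- quantile(sv, c(0.1, 0.9), names = FALSE)
  rp <- quantile(rv, c(0.1, 0.9), names = FALSE)
  if (sp[2] - sp[1] <= 0) stop("zero intensity spread within mask")
  a <- (rp[2] - rp[1]) / (sp[2] - sp[1])
  bn_volume(a * (t1$data - sp[1]) + rp[1], t1$affine)
}

#' Classify tissue into CSF, grey matter and white matter
#'
#' Three-component Gaussian mixture fitted by EM with deterministic 1D
#' k-means initialisation; components are ordered by mean so that
#' CSF < GM < WM. The fit excludes the bright artifact tail (intensities
#' above 1.25 times the provisional WM centre), which would otherwise
#' inflate the top component's variance until it swallows upper grey
#' matter; all masked voxels are then classified under the fitted model, so
#' voxels brighter than white matter fall in the top component and are
#' labelled WM — the property the artifact heuristics rely on.
#'
#' @param t1 (bias-corrected) [bn_volume()].
#' @param mask non-empty brain [bn_mask()].
#' @param seed RNG seed (the default fit is deterministic; kept for
#'   interface stability).
#' @return a [bn_labels()] with attribute `fit` (means, sds, weights).
#' @export
classify_tissue <- function(t1, mask, seed = 1) {
  stop_if_grid_mismatch(t1, mask)
  if (mask_count(mask) == 0) stop("mask is empty")
  x <- t1$data[mask$data == 1]
  if (length(unique(x)) < 3)
    stop("fewer than 3 distinct intensity levels in mask")
  wm_centre <- kmeans1d(x, 3)$centres[3]
  xfit <- x[x <= 1.25 * wm_centre]
  if (length(unique(xfit)) < 3) xfit <- x
  fit <- gmm1d_em(xfit, 3)
  post <- gmm_posteriors(x, fit)
  grp <- max.col(post, ties.method = "first")
  lab <- array(0L, dim(t1$data))
  lab[mask$data == 1] <- as.integer(grp)
  out <- bn_labels(lab, t1$affine)
  attr(out, "fit") <- fit
  out
}

gmm1d_em <- function(x, k, iters = 60, tol = 1e-8) {
  # Lloyd 1D k-means centres: robust to unbalanced class sizes, where raw
  # quantile initialisation can collapse two components onto one mode
  mu <- kmeans1d(x, k)$centres
  sg <- rep(sd(x) / k, k)
  floor_sd <- max(diff(range(x)) * 1e-3, 1e-12)
  sg <- pmax(sg, floor_sd)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(iters)) {
    dens <- vapply(seq_len(k), function(i)
      w[i] * stats::dnorm(x, mu[i], sg[i]), numeric(length(x)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / length(x)
    mu <- colSums(r * x) / nk
    sg <- sqrt(pmax(colSums(r * (x - rep(mu, each = length(x)))^2) / nk,
                    floor_sd^2))
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(means = mu[ord], sds = sg[ord], weights = w[ord])
}

# posteriors in log space: far outside the fitted range (bright artifacts)
# every density underflows to zero and the assignment would be arbitrary;
# log densities keep the comparison well defined everywhere
gmm_posteriors <- function(x, fit) {
  k <- length(fit$means)
  ld <- vapply(seq_len(k), function(i)
    log(fit$weights[i]) + stats::dnorm(x, fit$means[i], fit$sds[i], log = TRUE),
    numeric(length(x)))
  m <- apply(ld, 1, max)
  p <- exp(ld - m)
  p / rowSums(p)
}

#' Mean intensity of CSF-labelled voxels
#'
#' @param t1 a [bn_volume()].
#' @param labels a [bn_labels()] on the same grid.
#' @return scalar mean; error if no voxel is labelled CSF.
#' @export
csf_mean <- function(t1, labels) {
  stop_if_grid_mismatch(t1, labels)
  sel <- labels$data == 1L
  if (!any(sel)) stop("no CSF-labelled voxels")
  mean(t1$data[sel])
}
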