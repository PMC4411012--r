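#' Segmentation parameters for 3D puncta
#'
#' @param maxima_radius Radius (voxels, all axes) of the ellipsoidal
#'   strict-maximum neighbourhood used to seed puncta (default 3).
#' @param detection_floor Intensity floor (a.u.); voxels at or below it
#'   are background. `NULL` (default) selects a robust floor per volume:
#'   median + 3 * MAD.
#' @param mahalanobis_cut Mahalanobis radius of the Gaussian-model mask
#'   (default 2, the "two standard deviations" segmentation width).
#' @param min_mask_voxels Minimum region size for a punctum to be kept
#'   (default 4).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(maxima_radius = 3, detection_floor = NULL,
                                mahalanobis_cut = 2.0, min_mask_voxels = 4) {
  stopifnot(maxima_radius >= 1, mahalanobis_cut > 0, min_mask_voxels >= 1)
  structure(list(maxima_radius = as.integer(maxima_radius),
                 detection_floor = detection_floor,
                 mahalanobis_cut = mahalanobis_cut,
                 min_mask_voxels = as.integer(min_mask_voxels)),
            class = "segmentation_params")
}

robust_floor <- function(vol) {
  med <- stats::median(vol)
  med + 3 * stats::mad(vol, center = med)
}

as_volume3d <- function(volume) {
  if (inherits(volume, "channel_volume")) volume <- volume$data
  if (is.matrix(volume)) dim(volume) <- c(dim(volume), 1L)
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  volume
}

#' Detect punctum seed points (3D strict local maxima)
#'
#' Voxels that are strict maxima within an ellipsoidal neighbourhood of
#' the given radius on every axis and exceed the detection floor. Plateau
#' ties break deterministically to the lowest linear index.
#'
#' @param volume 3D array or [channel_volume()].
#' @param params A [segmentation_params()].
#' @return Integer matrix of 1-based seed coordinates (x, y, z), ordered
#'   by linear index.
#' @export
detect_local_maxima <- function(volume, params = segmentation_params()) {
  vol <- as_volume3d(volume)
  fl <- params$detection_floor
  if (is.null(fl)) fl <- robust_floor(vol)
  r <- params$maxima_radius
  .local_maxima_3d(vol, r, r, r, fl)
}

#' Watershed partition of the foreground around seeds
#'
#' Marker-controlled watershed on inverted intensity: regions grow from
#' the seeds in order of decreasing intensity (6-connectivity), restricted
#' to voxels above the detection floor, so ridge lines between adjacent
#' puncta become region boundaries.
#'
#' @param volume 3D array or [channel_volume()].
#' @param seeds Integer matrix of 1-based seed coordinates (x, y, z);
#'   seed `k` receives label `k`.
#' @param detection_floor Background level (a.u.).
#' @return Integer label array (0 = background).
#' @export
watershed_partition <- function(volume, seeds, detection_floor) {
  vol <- as_volume3d(volume)
  seeds <- rbind(seeds)
  if (nrow(seeds) < 1) stop("need at least one seed", call. = FALSE)
  vals <- vol[seeds]
  if (any(vals <= detection_floor)) {
    warning(sum(vals <= detection_floor),
            " seed(s) outside the foreground produce empty regions")
  }
  .marker_watershed_3d(vol, seeds, detection_floor)
}

#' Gaussian model of one punctum by intensity-weighted moments
#'
#' The punctum is modelled as an anisotropic 3D Gaussian: the centroid is
#' the intensity-weighted mean, the covariance the intensity-weighted
#' second moments (off-diagonals retained for the Mahalanobis mask), and
#' the amplitude the model-consistent peak value
#' `sum(w) / ((2*pi)^{3/2} * sqrt(det(C)))`. Deterministic; no iterative
#' fitting.
#'
#' @param volume 3D array or [channel_volume()].
#' @param voxels Integer matrix of 1-based (x, y, z) voxel coordinates of
#'   the region.
#' @param min_mask_voxels Reject regions with fewer positive-intensity
#'   voxels than this.
#' @param background Intensity subtracted from the weights (default 0).
#' @return A list `centroid`, `sigma`, `cov`, `amplitude`,
#'   `total_intensity`, `n_voxels`, or `NULL` if the region is rejected.
#' @export
fit_gaussian_3d <- function(volume, voxels, min_mask_voxels = 4,
                            background = 0) {
  vol <- as_volume3d(volume)
  voxels <- rbind(voxels)
  w <- vol[voxels] - background
  keep <- w > 0
  if (sum(keep) < min_mask_voxels) return(NULL)
  voxels <- voxels[keep, , drop = FALSE]; w <- w[keep]
  W <- sum(w)
  mu <- colSums(voxels * w) / W
  dx <- sweep(voxels, 2, mu)
  C <- crossprod(dx * sqrt(w)) / W
  # guard against degenerate (planar) regions
  diag(C) <- pmax(diag(C), 1 / 12)
  sig <- sqrt(diag(C))
  amp <- W / ((2 * pi)^1.5 * sqrt(max(det(C), 1e-12)))
  list(centroid = mu, sigma = sig, cov = C, amplitude = amp,
       total_intensity = W, n_voxels = length(w))
}

#' Segment 3D puncta in a channel
#'
#' The full pipeline: strict local maxima seed putative puncta; a
#' marker-controlled watershed draws boundaries between them; each
#' watershed region is modelled as a 3D Gaussian by weighted moments; and
#' the punctum mask is the region's voxels within the chosen Mahalanobis
#' radius of the model (2 SD by default), so punctum extent follows the
#' fitted width rather than the absolute brightness.
#'
#' @param volume 3D array or [channel_volume()].
#' @param params A [segmentation_params()].
#' @param channel Optional channel name recorded in the output.
#' @param voxel A [voxel_size()] for micron-scale centroids (taken from a
#'   `channel_volume` input automatically).
#' @return Data frame with one row per accepted punctum: `id`, `channel`,
#'   centroid in voxels (`x, y, z`, 1-based) and microns (`x_um, y_um,
#'   z_um`), `sigma_x/y/z` (voxels), `mask_voxels`, `total_intensity`
#'   (sum over the mask, a.u.), `peak_intensity` (a.u.) and
#'   `model_integral` (a.u. voxel^3). Rows ordered by centroid (z, y, x).
#' @export
segment_puncta <- function(volume, params = segmentation_params(),
                           channel = NA_character_, voxel = NULL) {
  if (inherits(volume, "channel_volume")) {
    if (is.na(channel)) channel <- volume$name
    if (is.null(voxel)) voxel <- volume$voxel
  }
  if (is.null(voxel)) voxel <- voxel_size()
  vol <- as_volume3d(volume)
  empty <- data.frame(id = integer(0), channel = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      sigma_x = numeric(0), sigma_y = numeric(0),
                      sigma_z = numeric(0), mask_voxels = integer(0),
                      total_intensity = numeric(0), peak_intensity = numeric(0),
                      model_integral = numeric(0))
  if (max(vol) == min(vol)) return(empty)
  fl <- params$detection_floor
  if (is.null(fl)) fl <- robust_floor(vol)
  seeds <- .local_maxima_3d(vol, params$maxima_radius, params$maxima_radius,
                            params$maxima_radius, fl)
  if (nrow(seeds) == 0) return(empty)
  labels <- .marker_watershed_3d(vol, seeds, fl)
  idx <- which(labels > 0)
  if (length(idx) == 0) return(empty)
  d <- dim(vol)
  coords <- cbind((idx - 1) %% d[1] + 1,
                  ((idx - 1) %/% d[1]) %% d[2] + 1,
                  (idx - 1) %/% (d[1] * d[2]) + 1)
  lab <- labels[idx]
  rows <- list()
  for (k in sort(unique(lab))) {
    vx <- coords[lab == k, , drop = FALSE]
    fit <- fit_gaussian_3d(vol, vx, min_mask_voxels = params$min_mask_voxels)
    if (is.null(fit)) next
    # 2-SD Gaussian mask: region voxels within the Mahalanobis radius
    Cinv <- tryCatch(solve(fit$cov), error = function(e) NULL)
    if (is.null(Cinv)) next
    dxm <- sweep(vx, 2, fit$centroid)
    m2 <- rowSums((dxm %*% Cinv) * dxm)
    inmask <- m2 <= params$mahalanobis_cut^2
    if (sum(inmask) < params$min_mask_voxels) next
    mv <- vx[inmask, , drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      id = k, channel = channel,
      x = fit$centroid[1], y = fit$centroid[2], z = fit$centroid[3],
      x_um = (fit$centroid[1] - 0.5) * voxel$vx / 1000,
      y_um = (fit$centroid[2] - 0.5) * voxel$vy / 1000,
      z_um = (fit$centroid[3] - 0.5) * voxel$vz / 1000,
      sigma_x = fit$sigma[1], sigma_y = fit$sigma[2], sigma_z = fit$sigma[3],
      mask_voxels = sum(inmask),
      total_intensity = sum(vol[mv]),
      peak_intensity = max(vol[vx]),
      model_integral = fit$amplitude * (2 * pi)^1.5 * sqrt(det(fit$cov)))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$z, out$y, out$x), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
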