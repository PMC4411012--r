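#' Estimate the neuropil mask from a synapsin channel
#'
#' Synapsin stains synaptic boutons densely throughout the neuropil but
#' is almost completely excluded from cell bodies, so a geometric
#' expansion of its foreground approximates the neuropil: binarize
#' (Otsu by default), dilate with an ellipsoidal element to bridge the
#' gaps between boutons, and fill residual holes smaller than a soma.
#' The complementary soma-sized holes stay excluded, giving the
#' denominator for neuropil-normalized density.
#'
#' @param synapsin 3D array or [channel_volume()] of the synapsin stain.
#' @param threshold `"otsu"` (default) or a numeric intensity threshold.
#' @param dilate_radii Ellipsoid radii `c(rx, ry, rz)` in voxels
#'   (default `c(5, 5, 4)`, about 500 x 500 x 280 nm on the standard
#'   grid); `c(0, 0, 0)` skips dilation.
#' @param max_hole_voxels Fill enclosed background components smaller
#'   than this (default 1000 voxels, well below a soma cross-section).
#' @param voxel A [voxel_size()] (taken from a `channel_volume`).
#' @return A list of class `neuropil_mask`: `mask` (3D logical),
#'   `neuropil_volume_um3`, `dilate_radii`, `threshold`.
#' @export
neuropil_mask <- function(synapsin, threshold = "otsu",
                          dilate_radii = c(5, 5, 4),
                          max_hole_voxels = 1000, voxel = NULL) {
  if (inherits(synapsin, "channel_volume") && is.null(voxel)) {
    voxel <- synapsin$voxel
  }
  if (is.null(voxel)) voxel <- voxel_size()
  vol <- as_volume3d(synapsin)
  if (max(vol) == min(vol)) {
    stop("no signal: constant synapsin channel", call. = FALSE)
  }
  if (identical(threshold, "otsu")) {
    threshold <- EBImage::otsu(EBImage::Image(matrix(as.vector(vol))),
                               range = c(0, 65535))
  }
  mask <- vol > threshold
  if (!any(mask)) stop("empty mask: no voxel exceeds the threshold",
                       call. = FALSE)
  r <- as.integer(dilate_radii)
  if (any(r > 0)) mask <- .dilate_ellipsoid_3d(mask, r[1], r[2], r[3])
  if (max_hole_voxels > 0 && any(!mask)) {
    holes <- .label_components_3d(!mask)
    d <- dim(mask)
    border_labels <- unique(c(holes[c(1, d[1]), , ], holes[, c(1, d[2]), ],
                              holes[, , c(1, d[3])]))
    counts <- tabulate(holes)
    fill <- which(counts < max_hole_voxels)
    fill <- setdiff(fill, border_labels)
    if (length(fill)) mask[holes %in% fill] <- TRUE
  }
  voxvol_um3 <- voxel$vx * voxel$vy * voxel$vz / 1e9
  structure(list(mask = mask,
                 neuropil_volume_um3 = sum(mask) * voxvol_um3,
                 dilate_radii = r, threshold = threshold, voxel = voxel),
            class = "neuropil_mask")
}

#' @export
print.neuropil_mask <- function(x, ...) {
  cat(sprintf("neuropil mask: %.1f um^3 (%.1f%% of volume), threshold %.0f a.u.\n",
              x$neuropil_volume_um3, 100 * mean(x$mask), x$threshold))
  invisible(x)
}

#' Neuropil-normalized puncta density in an ROI
#'
#' Counts the puncta whose centroid voxel lies inside the intersection of
#' the ROI with the neuropil, and normalizes by the physical volume of
#' that intersection.
#'
#' @param puncta A puncta table from [segment_puncta()].
#' @param roi An [roi_mask()] (or `NULL` for the whole volume).
#' @param neuropil A [neuropil_mask()].
#' @return A list of class `density_result`: `roi_label`, `puncta_count`,
#'   `neuropil_volume_um3`, `density_per_um3`, `median_total_intensity`,
#'   `n_puncta_for_median`.
#' @export
roi_density <- function(puncta, roi = NULL, neuropil) {
  stopifnot(inherits(neuropil, "neuropil_mask"))
  region <- neuropil$mask
  label <- "all"
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_mask"))
    if (!identical(dim(roi$mask), dim(neuropil$mask))) {
      stop("ROI and neuropil masks must be congruent", call. = FALSE)
    }
    region <- region & roi$mask
    label <- roi$label
  }
  if (!any(region)) stop("empty ROI-neuropil intersection", call. = FALSE)
  voxvol_um3 <- neuropil$voxel$vx * neuropil$voxel$vy * neuropil$voxel$vz / 1e9
  vol_um3 <- sum(region) * voxvol_um3
  d <- dim(region)
  inside <- if (nrow(puncta) > 0) {
    cc <- cbind(pmin(pmax(round(puncta$x), 1), d[1]),
                pmin(pmax(round(puncta$y), 1), d[2]),
                pmin(pmax(round(puncta$z), 1), d[3]))
    region[cc]
  } else logical(0)
  n <- sum(inside)
  structure(list(roi_label = label, puncta_count = n,
                 neuropil_volume_um3 = vol_um3,
                 density_per_um3 = n / vol_um3,
                 median_total_intensity =
                   if (n > 0) stats::median(puncta$total_intensity[inside])
                   else NA_real_,
                 n_puncta_for_median = n),
            class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("ROI %s: %d puncta in %.1f um^3 neuropil = %.4f /um^3; median intensity %.0f a.u. (n=%d)\n",
              x$roi_label, x$puncta_count, x$neuropil_volume_um3,
              x$density_per_um3, x$median_total_intensity,
              x$n_puncta_for_median))
  invisible(x)
}

# null distribution of 2*W over sign assignments, by dynamic programming;
# ranks may be midranks (half-integers), hence the doubling
signed_rank_distribution <- function(ranks2) {
  counts <- numeric(sum(ranks2) + 1)  # index k+1 <-> 2W = k
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped; absolute differences are ranked with
#' midranks for ties; the statistic `W` is the sum of ranks of the
#' positive differences. For `n <= 25` pairs the two-sided p-value is
#' exact — `min(1, 2 * min(P(W <= w), P(W >= w)))` under the full
#' distribution over all `2^n` sign assignments (computed by dynamic
#' programming, identical to brute-force enumeration) — and a normal
#' approximation with continuity and tie corrections is used above.
#'
#' @param x Differences, or the first member of each pair.
#' @param y Optional second member; differences are `x - y`.
#' @return A list of class `paired_comparison`: `statistic` (W),
#'   `p.value`, `n` (pairs after zero removal), `exact`, `differences`.
#' @export
exact_wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) stop("degenerate input: all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    counts <- signed_rank_distribution(as.integer(round(2 * r)))
    total <- 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = W, p.value = p, n = n, exact = exact,
                 differences = d),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank: W = %g, n = %d, %s two-sided P = %.4g\n",
              x$statistic, x$n, if (x$exact) "exact" else "approximate",
              x$p.value))
  if (!is.null(x$median_pct_difference)) {
    cat(sprintf("  median percent difference: %.2f%%\n",
                x$median_pct_difference))
  }
  invisible(x)
}

#' Compare two ROI classes across ribbons
#'
#' Within each ribbon the chosen statistic is averaged over all ROIs of
#' each class (e.g. spared and deprived L4 together), forming one pair
#' per ribbon; pairs are compared with the exact Wilcoxon signed-rank
#' test, and the median percent difference
#' `median(100 * (g1 - g2) / g1)` is reported.
#'
#' @param results Data frame with columns `ribbon`, `class`, and the
#'   statistic columns `density_per_um3` and/or `median_total_intensity`
#'   (e.g. rows built from [roi_density()] outputs).
#' @param class1,class2 The two ROI classes to compare (g1 and g2).
#' @param statistic `"density"` or `"median_intensity"`.
#' @return A `paired_comparison` with extra fields `pairs` (per-ribbon
#'   data frame) and `median_pct_difference`.
#' @export
compare_rois_across_ribbons <- function(results, class1, class2,
                                        statistic = c("density",
                                                      "median_intensity")) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "density") "density_per_um3" else
    "median_total_intensity"
  stopifnot(is.data.frame(results), all(c("ribbon", "class", col) %in%
                                          names(results)))
  ribbons <- unique(results$ribbon)
  pairs <- list()
  for (rb in ribbons) {
    sub <- results[results$ribbon == rb, ]
    v1 <- sub[[col]][sub$class == class1]
    v2 <- sub[[col]][sub$class == class2]
    if (length(v1) == 0 || length(v2) == 0) {
      warning("ribbon ", rb, " lacks ROI class ",
              if (length(v1) == 0) class1 else class2, "; excluded")
      next
    }
    pairs[[length(pairs) + 1]] <- data.frame(ribbon = rb,
                                             g1 = mean(v1), g2 = mean(v2))
  }
  if (length(pairs) < 2) {
    stop("need at least 2 ribbons with both ROI classes", call. = FALSE)
  }
  tab <- do.call(rbind, pairs)
  cmp <- exact_wilcoxon_signed_rank(tab$g1, tab$g2)
  cmp$pairs <- tab
  cmp$median_pct_difference <- stats::median(100 * (tab$g1 - tab$g2) / tab$g1)
  cmp
}
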