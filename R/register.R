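#' 2D rigid transform
#'
#' Maps a point `p` (0-based pixel coordinates) to
#' `R(theta) %*% (p - center) + center + c(dx, dy)`. For image transforms
#' the centre is conventionally the image centre, so small rotations do
#' not translate the field of view.
#'
#' @param theta Rotation in degrees (counter-clockwise).
#' @param dx,dy Translation in pixels.
#' @param center Rotation centre `c(cx, cy)` in 0-based pixel coordinates.
#' @return An object of class `rigid2d`.
#' @export
rigid2d <- function(theta = 0, dx = 0, dy = 0, center = c(0, 0)) {
  structure(list(theta = theta, dx = dx, dy = dy,
                 center = as.numeric(center)),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("rigid2d: theta = %.4f deg, t = (%.4f, %.4f), center = (%g, %g)\n",
              x$theta, x$dx, x$dy, x$center[1], x$center[2]))
  invisible(x)
}

rot_mat <- function(theta_deg) {
  a <- theta_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid2d()].
#' @param pts `n x 2` matrix of 0-based (x, y) coordinates.
#' @return Transformed `n x 2` matrix.
#' @export
apply_rigid_points <- function(transform, pts) {
  pts <- rbind(pts)  # tolerate a single point given as a vector
  R <- rot_mat(transform$theta)
  sweep(t(R %*% t(sweep(pts, 2, transform$center))), 2,
        transform$center + c(transform$dx, transform$dy), `+`)
}

#' Compose and invert rigid transforms
#'
#' `compose_rigid(b, a)` is the transform "apply `a`, then `b`"; both must
#' share the same centre.
#'
#' @param a,b,transform [rigid2d()] objects.
#' @return A [rigid2d()].
#' @export
compose_rigid <- function(b, a) {
  if (any(abs(a$center - b$center) > 1e-9)) {
    stop("transforms must share a rotation centre", call. = FALSE)
  }
  Rb <- rot_mat(b$theta)
  t_new <- Rb %*% c(a$dx, a$dy) + c(b$dx, b$dy)
  rigid2d(a$theta + b$theta, t_new[1], t_new[2], center = a$center)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(transform) {
  Ri <- rot_mat(-transform$theta)
  t_new <- -Ri %*% c(transform$dx, transform$dy)
  rigid2d(-transform$theta, t_new[1], t_new[2], center = transform$center)
}

# re-express a transform about a different rotation centre
rigid_change_center <- function(transform, center) {
  R <- rot_mat(transform$theta)
  dcen <- center - transform$center
  t_new <- c(transform$dx, transform$dy) + as.vector((R - diag(2)) %*% dcen)
  rigid2d(transform$theta, t_new[1], t_new[2], center = center)
}

#' Resample an image under a rigid transform
#'
#' The output at pixel `p` is the bilinear sample of the input at
#' `T^{-1}(p)`, i.e. image content moves *with* the transform. Samples
#' falling outside the input are zero.
#'
#' @param image 2D matrix (x, y).
#' @param transform A [rigid2d()].
#' @return Transformed matrix of the same size.
#' @export
apply_rigid_image <- function(image, transform) {
  d <- dim(image)
  inv <- invert_rigid(transform)
  grid <- cbind(rep(seq_len(d[1]) - 1, d[2]),
                rep(seq_len(d[2]) - 1, each = d[1]))
  src <- apply_rigid_points(inv, grid)
  x0 <- floor(src[, 1]); y0 <- floor(src[, 2])
  fx <- src[, 1] - x0;   fy <- src[, 2] - y0
  val <- function(ix, iy) {
    ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1
    v <- numeric(length(ix))
    v[ok] <- image[cbind(ix[ok] + 1, iy[ok] + 1)]
    v
  }
  out <- (1 - fx) * (1 - fy) * val(x0, y0) + fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) + fx * fy * val(x0 + 1, y0 + 1)
  matrix(out, d[1], d[2])
}

#' Estimate the integer offset between two overlapping tiles
#'
#' Searches the shift `(dx, dy)` maximizing the Pearson correlation of the
#' overlap `A[i + dx, j + dy] ~ B[i, j]` — i.e. the position of tile B's
#' origin within tile A's frame. Confidence is the peak correlation.
#'
#' @param tileA,tileB 2D matrices.
#' @param dx_range,dy_range Integer search ranges `c(min, max)` (inclusive).
#' @param refine If `TRUE`, refine the peak to subpixel precision by a
#'   separable quadratic fit around the best integer shift.
#' @return A list `dx, dy, confidence`.
#' @export
estimate_pairwise_offset <- function(tileA, tileB,
                                     dx_range = c(-10, 10),
                                     dy_range = c(-10, 10),
                                     refine = FALSE) {
  stopifnot(is.matrix(tileA), is.matrix(tileB))
  dxs <- seq(dx_range[1], dx_range[2]); dys <- seq(dy_range[1], dy_range[2])
  rmap <- matrix(NA_real_, length(dxs), length(dys))
  dA <- dim(tileA); dB <- dim(tileB)
  for (ix in seq_along(dxs)) {
    for (iy in seq_along(dys)) {
      dx <- dxs[ix]; dy <- dys[iy]
      i1 <- max(1, 1 - dx); i2 <- min(dB[1], dA[1] - dx)
      j1 <- max(1, 1 - dy); j2 <- min(dB[2], dA[2] - dy)
      if (i2 - i1 < 2 || j2 - j1 < 2) next
      a <- tileA[(i1 + dx):(i2 + dx), (j1 + dy):(j2 + dy)]
      b <- tileB[i1:i2, j1:j2]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      rmap[ix, iy] <- stats::cor(as.vector(a), as.vector(b))
    }
  }
  if (all(is.na(rmap))) {
    stop("no signal: all candidate overlaps are constant or empty",
         call. = FALSE)
  }
  best <- which(rmap == max(rmap, na.rm = TRUE), arr.ind = TRUE)[1, ]
  dx <- dxs[best[1]]; dy <- dys[best[2]]
  if (refine) {
    qoff <- function(rm1, r0, rp1) {
      den <- rm1 - 2 * r0 + rp1
      if (!is.finite(den) || den >= 0) return(0)
      max(-0.5, min(0.5, 0.5 * (rm1 - rp1) / den))
    }
    if (best[1] > 1 && best[1] < length(dxs)) {
      dx <- dx + qoff(rmap[best[1] - 1, best[2]], rmap[best[1], best[2]],
                      rmap[best[1] + 1, best[2]])
    }
    if (best[2] > 1 && best[2] < length(dys)) {
      dy <- dy + qoff(rmap[best[1], best[2] - 1], rmap[best[1], best[2]],
                      rmap[best[1], best[2] + 1])
    }
  }
  list(dx = dx, dy = dy, confidence = max(rmap, na.rm = TRUE))
}

#' Stitch mosaic tiles from pairwise offsets
#'
#' Solves the least-squares consistency problem for global tile origins
#' given pairwise offset measurements (tile 1 is the fixed reference at
#' the origin), then fuses the tiles with linear feathering in overlaps.
#'
#' @param tiles List of 2D matrices.
#' @param offsets Data frame with columns `from`, `to`, `dx`, `dy`: the
#'   estimated origin of tile `to` minus the origin of tile `from`.
#' @return A list with `layout` (data frame `tile, x, y`), `residuals`
#'   (per-pair least-squares residuals) and `fused` (matrix).
#' @export
stitch_mosaic <- function(tiles, offsets) {
  n <- length(tiles)
  stopifnot(n >= 1)
  if (n == 1) {
    return(list(layout = data.frame(tile = 1L, x = 0, y = 0),
                residuals = data.frame(from = integer(0), to = integer(0),
                                       rx = numeric(0), ry = numeric(0)),
                fused = tiles[[1]]))
  }
  # connectivity of the offset graph
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(offsets))) {
    i <- offsets$from[k]; j <- offsets$to[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  if (!all(seen)) stop("stitching graph is disconnected", call. = FALSE)
  # least squares: origin[to] - origin[from] = (dx, dy), origin[1] = 0
  m <- nrow(offsets)
  A <- matrix(0, m, n - 1)
  for (k in seq_len(m)) {
    i <- offsets$from[k]; j <- offsets$to[k]
    if (j > 1) A[k, j - 1] <- A[k, j - 1] + 1
    if (i > 1) A[k, i - 1] <- A[k, i - 1] - 1
  }
  solx <- stats::lsfit(A, offsets$dx, intercept = FALSE)
  soly <- stats::lsfit(A, offsets$dy, intercept = FALSE)
  ox <- c(0, solx$coefficients); oy <- c(0, soly$coefficients)
  layout <- data.frame(tile = seq_len(n), x = unname(ox), y = unname(oy))
  residuals <- data.frame(from = offsets$from, to = offsets$to,
                          rx = unname(solx$residuals),
                          ry = unname(soly$residuals))
  # fuse with linear feathering (weights ramp to zero at tile borders)
  oxr <- round(ox - min(ox)); oyr <- round(oy - min(oy))
  tw <- vapply(tiles, nrow, integer(1)); th <- vapply(tiles, ncol, integer(1))
  W <- max(oxr + tw); H <- max(oyr + th)
  acc <- matrix(0, W, H); wacc <- matrix(0, W, H)
  for (k in seq_len(n)) {
    wx <- pmin(seq_len(tw[k]), rev(seq_len(tw[k])))
    wy <- pmin(seq_len(th[k]), rev(seq_len(th[k])))
    w <- outer(wx, wy, pmin)
    xi <- oxr[k] + seq_len(tw[k]); yi <- oyr[k] + seq_len(th[k])
    acc[xi, yi] <- acc[xi, yi] + w * tiles[[k]]
    wacc[xi, yi] <- wacc[xi, yi] + w
  }
  fused <- acc / pmax(wacc, 1e-12)
  list(layout = layout, residuals = residuals, fused = fused)
}

#' Detect blob features (Laplacian of Gaussian)
#'
#' Finds bright (or dark) blob-like features — nuclei in a DAPI section,
#' puncta in a synaptic channel — as maxima of the scale-normalized
#' Laplacian-of-Gaussian response over a range of scales, with separable
#' quadratic subpixel refinement. Ordering is deterministic: by strength,
#' then position.
#'
#' @param image 2D matrix.
#' @param sigma_range Range of blob scales (Gaussian sd, pixels).
#' @param n_scales Number of scales spanning `sigma_range` geometrically.
#' @param threshold Absolute response threshold; default is 10% of the
#'   maximum response (an empty set is returned if no response is
#'   positive).
#' @param polarity `"bright"` or `"dark"`.
#' @param min_sep Minimum separation (pixels) between reported blobs; the
#'   stronger of two close detections wins.
#' @return Data frame `x, y, sigma, strength` with 0-based subpixel
#'   coordinates, ordered by decreasing strength.
#' @export
detect_blobs <- function(image, sigma_range = c(2, 6), n_scales = 4,
                         threshold = NULL, polarity = c("bright", "dark"),
                         min_sep = 2) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(image))
  empty <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      strength = numeric(0))
  if (stats::sd(image) == 0) return(empty)
  if (polarity == "dark") image <- -image
  sigmas <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                    length.out = n_scales))
  d <- dim(image)
  resp <- array(0, c(d, length(sigmas)))
  for (s in seq_along(sigmas)) {
    sg <- sigmas[s]
    hw <- ceiling(3.5 * sg)
    x <- -hw:hw
    g1 <- exp(-x^2 / (2 * sg^2)); g1 <- g1 / sum(g1)
    G <- g1 %o% g1
    r2 <- outer(x^2, x^2, `+`)
    K <- (r2 / sg^2 - 2) * G          # sigma^2-normalized LoG (up to sign)
    resp[, , s] <- -conv_same(image, K)
  }
  if (is.null(threshold)) {
    mx <- max(resp)
    if (mx <= 0) return(empty)
    threshold <- 0.1 * mx
  }
  pk <- .local_maxima_3d(resp, 2L, 2L, 1L, threshold)
  if (nrow(pk) == 0) return(empty)
  qoff <- function(rm1, r0, rp1) {
    den <- rm1 - 2 * r0 + rp1
    if (!is.finite(den) || den >= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (rm1 - rp1) / den))
  }
  out <- data.frame(x = numeric(nrow(pk)), y = numeric(nrow(pk)),
                    sigma = sigmas[pk[, 3]],
                    strength = resp[pk])
  for (k in seq_len(nrow(pk))) {
    i <- pk[k, 1]; j <- pk[k, 2]; s <- pk[k, 3]
    ox <- if (i > 1 && i < d[1]) {
      qoff(resp[i - 1, j, s], resp[i, j, s], resp[i + 1, j, s])
    } else 0
    oy <- if (j > 1 && j < d[2]) {
      qoff(resp[i, j - 1, s], resp[i, j, s], resp[i, j + 1, s])
    } else 0
    out$x[k] <- i - 1 + ox; out$y[k] <- j - 1 + oy
  }
  out <- out[order(-out$strength, out$y, out$x), , drop = FALSE]
  keep <- logical(nrow(out))
  for (k in seq_len(nrow(out))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    dmin <- min(sqrt((out$x[keep] - out$x[k])^2 +
                       (out$y[keep] - out$y[k])^2))
    if (dmin >= min_sep) keep[k] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Robust rigid fit between matched point sets (RANSAC)
#'
#' Two-point minimal samples propose rigid transforms (rotation +
#' translation, no scaling); the consensus transform is refit on its
#' inliers by orthogonal Procrustes. Deterministic under a fixed seed.
#'
#' @param pointsA,pointsB `n x 2` matrices of corresponding points
#'   (`pointsB[i, ] ~ T(pointsA[i, ])`).
#' @param inlier_tol Inlier distance tolerance in pixels (default 2).
#' @param iterations RANSAC iterations (default 1000).
#' @param seed Integer seed.
#' @return A list with `transform` (a [rigid2d()] about the origin) and
#'   `inliers` (indices).
#' @export
estimate_rigid_ransac <- function(pointsA, pointsB, inlier_tol = 2,
                                  iterations = 1000, seed = 1L) {
  pointsA <- rbind(pointsA); pointsB <- rbind(pointsB)
  n <- nrow(pointsA)
  if (n < 2 || nrow(pointsB) != n) {
    stop("insufficient correspondences: need >= 2 matched points",
         call. = FALSE)
  }
  fit_pair <- function(idx) {
    va <- pointsA[idx[2], ] - pointsA[idx[1], ]
    vb <- pointsB[idx[2], ] - pointsB[idx[1], ]
    if (sum(va^2) < 1e-12 || sum(vb^2) < 1e-12) return(NULL)
    th <- (atan2(vb[2], vb[1]) - atan2(va[2], va[1])) * 180 / pi
    R <- rot_mat(th)
    t0 <- colMeans(pointsB[idx, ]) - as.vector(R %*% colMeans(pointsA[idx, ]))
    rigid2d(th, t0[1], t0[2])
  }
  count_inliers <- function(tr) {
    pred <- apply_rigid_points(tr, pointsA)
    which(sqrt(rowSums((pred - pointsB)^2)) <= inlier_tol)
  }
  best_in <- integer(0)
  withr::with_seed(seed, {
    for (it in seq_len(iterations)) {
      idx <- sample.int(n, 2)
      tr <- fit_pair(idx)
      if (is.null(tr)) next
      inl <- count_inliers(tr)
      if (length(inl) > length(best_in)) best_in <- inl
    }
  })
  if (length(best_in) < 3) {
    stop("no consensus: fewer than 3 RANSAC inliers", call. = FALSE)
  }
  tr <- procrustes_rigid(pointsA[best_in, , drop = FALSE],
                         pointsB[best_in, , drop = FALSE])
  list(transform = tr, inliers = count_inliers(tr))
}

# least-squares rigid fit (orthogonal Procrustes without scaling)
procrustes_rigid <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  th <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  t0 <- cb - as.vector(R %*% ca)
  rigid2d(th, t0[1], t0[2])
}

# downsample a 2D image by repeated 2x2 mean pooling
downsample2 <- function(img, times) {
  for (i in seq_len(times)) {
    a <- img; dim(a) <- c(dim(img), 1L)
    img <- pool2x2_xy(a)[, , 1]
  }
  img
}

#' Register one imaging session to a reference session
#'
#' Blob features (nuclei in the DAPI channel) are detected in both
#' sections, matched by proximity after a coarse translation search, and
#' filtered by RANSAC to fit the rigid transform between sessions. The
#' returned transform maps reference coordinates to moving-session
#' coordinates, and applies identically to every channel of the moving
#' session (resample each with its inverse to bring them into registry).
#'
#' @param reference,moving 2D sections of the fiducial channel from the
#'   two sessions.
#' @param max_shift Coarse translation search radius, in pixels.
#' @param match_radius Candidate-correspondence radius after the coarse
#'   shift, in pixels.
#' @param blob_args List of extra arguments for [detect_blobs()].
#' @param inlier_tol,iterations,seed Passed to [estimate_rigid_ransac()].
#' @return A list with `transform` (a [rigid2d()] about the image centre),
#'   `inliers` and `n_candidates`.
#' @export
register_session <- function(reference, moving, max_shift = 20,
                             match_radius = 8, blob_args = list(),
                             inlier_tol = 2, iterations = 1000, seed = 1L) {
  stopifnot(is.matrix(reference), is.matrix(moving))
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0) {
    stop("no signal: constant section", call. = FALSE)
  }
  ba <- do.call(detect_blobs, c(list(reference), blob_args))
  bb <- do.call(detect_blobs, c(list(moving), blob_args))
  if (nrow(ba) < 3 || nrow(bb) < 3) {
    stop("no consensus: too few blob features", call. = FALSE)
  }
  # coarse translation on 4x-downsampled images
  f <- 2L
  co <- estimate_pairwise_offset(downsample2(reference, f),
                                 downsample2(moving, f),
                                 dx_range = c(-1, 1) * ceiling(max_shift / 4),
                                 dy_range = c(-1, 1) * ceiling(max_shift / 4))
  shift <- -c(co$dx, co$dy) * 2^f  # content displacement reference -> moving
  # candidate correspondences: moving blob ~ reference blob + shift
  A <- NULL; B <- NULL
  for (k in seq_len(nrow(bb))) {
    dists <- sqrt((ba$x + shift[1] - bb$x[k])^2 +
                    (ba$y + shift[2] - bb$y[k])^2)
    j <- which.min(dists)
    if (dists[j] <= match_radius) {
      A <- rbind(A, c(ba$x[j], ba$y[j])); B <- rbind(B, c(bb$x[k], bb$y[k]))
    }
  }
  if (is.null(A) || nrow(A) < 3) {
    stop("no consensus: too few blob correspondences", call. = FALSE)
  }
  fit <- estimate_rigid_ransac(A, B, inlier_tol = inlier_tol,
                               iterations = iterations, seed = seed)
  ctr <- (dim(reference) - 1) / 2
  list(transform = rigid_change_center(fit$transform, ctr),
       inliers = fit$inliers, n_candidates = nrow(A))
}

# neighbor-section rigid registration used by align_stack; falls back to
# translation-only correlation if blob RANSAC finds no consensus
register_pair <- function(ref, mov, max_shift = 6, blob_args = list(),
                          seed = 1L) {
  ctr <- (dim(ref) - 1) / 2
  tr <- tryCatch(
    register_session(ref, mov, max_shift = max_shift,
                     match_radius = max(4, max_shift),
                     blob_args = blob_args, seed = seed)$transform,
    error = function(e) NULL)
  if (!is.null(tr)) return(tr)
  off <- tryCatch(
    estimate_pairwise_offset(ref, mov, dx_range = c(-max_shift, max_shift),
                             dy_range = c(-max_shift, max_shift),
                             refine = TRUE),
    error = function(e) NULL)
  if (!is.null(off)) return(rigid2d(0, -off$dx, -off$dy, center = ctr))
  warning("no consensus for section pair; substituting identity")
  rigid2d(0, 0, 0, center = ctr)
}

#' Align the sections of a stack (rigid, chained to a middle anchor)
#'
#' Each section is registered rigidly to its predecessor on a reference
#' channel that stains densely across consecutive sections (Synapsin1 in
#' practice), the pairwise transforms are chained to the middle section to
#' halve drift accumulation, and all sections are resampled into the
#' anchor frame.
#'
#' After chaining, a template-refinement pass re-registers every section
#' (translation only, subpixel) against the leave-one-out mean of the
#' aligned stack and re-anchors, which suppresses the random-walk
#' accumulation of small pairwise errors along the chain.
#'
#' @param volume 3D array (x, y, z) of the reference channel.
#' @param max_shift Per-pair search radius (pixels).
#' @param blob_args List of extra arguments for [detect_blobs()] (puncta
#'   are small; the default scale range is `c(1, 3)` pixels).
#' @param seed Integer seed for the per-pair RANSAC.
#' @param refine_passes Number of template-refinement passes (default 2;
#'   0 disables refinement).
#' @return A list with `transforms` (data frame `section, theta, dx, dy`;
#'   the transform maps anchor coordinates to that section's coordinates),
#'   `rigid` (list of [rigid2d()]), `aligned` (resampled volume), `anchor`,
#'   and mean neighbour-section correlations before and after.
#' @export
align_stack <- function(volume, max_shift = 6,
                        blob_args = list(sigma_range = c(1, 3)), seed = 1L,
                        refine_passes = 2) {
  d <- dim(volume)
  if (length(d) != 3 || d[3] < 2) stop("need >= 2 sections", call. = FALSE)
  ctr <- (d[1:2] - 1) / 2
  anchor <- ceiling(d[3] / 2)
  pair <- vector("list", d[3])  # pair[[s]]: coords of s-1 -> coords of s
  for (s in 2:d[3]) {
    pair[[s]] <- register_pair(volume[, , s - 1], volume[, , s],
                               max_shift = max_shift, blob_args = blob_args,
                               seed = seed + s)
  }
  chain <- vector("list", d[3])
  chain[[anchor]] <- rigid2d(0, 0, 0, center = ctr)
  if (anchor < d[3]) {
    for (s in (anchor + 1):d[3]) {
      chain[[s]] <- compose_rigid(pair[[s]], chain[[s - 1]])
    }
  }
  if (anchor > 1) {
    for (s in (anchor - 1):1) {
      chain[[s]] <- compose_rigid(invert_rigid(pair[[s + 1]]), chain[[s + 1]])
    }
  }
  resample_all <- function(ch) {
    out <- volume
    for (s in seq_len(d[3])) {
      if (abs(ch[[s]]$theta) < 1e-12 && abs(ch[[s]]$dx) < 1e-12 &&
          abs(ch[[s]]$dy) < 1e-12) next
      out[, , s] <- apply_rigid_image(volume[, , s],
                                      invert_rigid(ch[[s]]))
    }
    out
  }
  aligned <- resample_all(chain)
  for (pass in seq_len(refine_passes)) {
    total <- apply(aligned, c(1, 2), sum)
    for (s in seq_len(d[3])) {
      template <- (total - aligned[, , s]) / (d[3] - 1)
      off <- tryCatch(
        estimate_pairwise_offset(template, aligned[, , s],
                                 dx_range = c(-2, 2), dy_range = c(-2, 2),
                                 refine = TRUE),
        error = function(e) NULL)
      if (is.null(off)) next
      corr <- rigid2d(0, -off$dx, -off$dy, center = ctr)
      chain[[s]] <- compose_rigid(chain[[s]], corr)
    }
    # re-anchor so the anchor section stays the identity
    anchor_inv <- invert_rigid(chain[[anchor]])
    for (s in seq_len(d[3])) {
      chain[[s]] <- compose_rigid(chain[[s]], anchor_inv)
    }
    aligned <- resample_all(chain)
  }
  ncorr <- function(v) {
    mean(vapply(seq_len(d[3] - 1), function(s) {
      stats::cor(as.vector(v[, , s]), as.vector(v[, , s + 1]))
    }, numeric(1)))
  }
  list(transforms = data.frame(
         section = seq_len(d[3]),
         theta = vapply(chain, `[[`, numeric(1), "theta"),
         dx = vapply(chain, `[[`, numeric(1), "dx"),
         dy = vapply(chain, `[[`, numeric(1), "dy")),
       rigid = chain, aligned = aligned, anchor = anchor,
       mean_corr_before = ncorr(volume), mean_corr_after = ncorr(aligned))
}

#' Serialize / deserialize rigid transforms as JSON
#'
#' @param transforms A list of [rigid2d()] or a single one.
#' @param path Output path.
#' @export
write_transforms_json <- function(transforms, path) {
  if (inherits(transforms, "rigid2d")) transforms <- list(transforms)
  jsonlite::write_json(lapply(transforms, function(tr) {
    list(theta = tr$theta, dx = tr$dx, dy = tr$dy, center = tr$center)
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transforms_json
#' @export
read_transforms_json <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
         function(x) rigid2d(x$theta, x$dx, x$dy, center = unlist(x$center)))
}
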