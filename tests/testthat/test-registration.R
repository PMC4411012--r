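test_that("rigid transforms compose, invert and recentre consistently", {
  withr::with_seed(3, pts <- matrix(stats::runif(20, 0, 100), ncol = 2))
  a <- rigid2d(17, 3.2, -1.5, center = c(10, 20))
  b <- rigid2d(-41, -0.7, 2.2, center = c(10, 20))
  # composition equals sequential application on points
  expect_equal(apply_rigid_points(compose_rigid(b, a), pts),
               apply_rigid_points(b, apply_rigid_points(a, pts)),
               tolerance = 1e-12)
  # inverse round-trips points
  expect_equal(apply_rigid_points(invert_rigid(a), apply_rigid_points(a, pts)),
               pts, tolerance = 1e-12)
  ident <- compose_rigid(invert_rigid(a), a)
  expect_equal(ident$theta, 0, tolerance = 1e-12)
  expect_equal(c(ident$dx, ident$dy), c(0, 0), tolerance = 1e-12)
  # recentring changes the representation, not the mapping
  a2 <- arraytomo:::rigid_change_center(a, c(-5, 40))
  expect_equal(apply_rigid_points(a2, pts), apply_rigid_points(a, pts),
               tolerance = 1e-12)
  expect_error(compose_rigid(a, rigid2d(1, 0, 0, center = c(0, 0))), "centre")
})

test_that("image resampling moves content with the transform", {
  withr::with_seed(4, img <- matrix(stats::runif(30 * 30), 30, 30))
  # integer translation is exact where defined, zero outside
  out <- apply_rigid_image(img, rigid2d(0, 3, -2))
  expect_equal(out[4:30, 1:28], img[1:27, 3:30], tolerance = 1e-12)
  expect_equal(out[1:3, ], matrix(0, 3, 30))
  # a 90-degree rotation about the image centre permutes pixels exactly
  rot <- apply_rigid_image(img, rigid2d(90, 0, 0, center = c(14.5, 14.5)))
  manual <- matrix(0, 30, 30)
  for (i in 1:30) for (j in 1:30) manual[i, j] <- img[j, 30 + 1 - i]
  expect_equal(rot, manual, tolerance = 1e-9)
})

test_that("pairwise offsets are recovered exactly for true crops", {
  withr::with_seed(5, img <- matrix(stats::runif(120 * 80, 0, 1000), 120, 80))
  tileA <- img[1:80, 1:60]
  tileB <- img[41:120, 1:60]   # origin of B in A's frame: (40, 0)
  off <- estimate_pairwise_offset(tileA, tileB, dx_range = c(30, 50),
                                  dy_range = c(-5, 5))
  expect_equal(c(off$dx, off$dy), c(40, 0))
  expect_equal(off$confidence, 1, tolerance = 1e-12)
})

test_that("subpixel refinement improves a fractional shift estimate", {
  g <- function(cx, cy) {
    outer(1:41, 1:41, function(i, j) exp(-((i - cx)^2 + (j - cy)^2) / 18))
  }
  a <- g(21, 21)
  b <- g(21 - 2.3, 21 + 0.4)   # content of b sits at a's content shifted
  off <- estimate_pairwise_offset(a, b, c(-5, 5), c(-5, 5), refine = TRUE)
  expect_lt(abs(off$dx - 2.3), 0.15)
  expect_lt(abs(off$dy - (-0.4)), 0.15)
})

test_that("offset estimation fails loudly on constant tiles", {
  expect_error(estimate_pairwise_offset(matrix(5, 20, 20),
                                        matrix(5, 20, 20)), "no signal")
})

test_that("stitching recovers true tile origins from exact offsets", {
  withr::with_seed(6, sec <- matrix(stats::runif(140 * 100, 0, 1000), 140, 100))
  m <- tile_mosaic(sec, c(80, 60), overlap_fraction = 0.3)
  org <- m$origins
  expect_gt(nrow(org), 2)
  # offsets between all tile pairs that overlap, from the true origins
  pairs <- list()
  for (i in seq_len(nrow(org) - 1)) for (j in (i + 1):nrow(org)) {
    if (abs(org$x0[i] - org$x0[j]) < 80 && abs(org$y0[i] - org$y0[j]) < 60) {
      pairs[[length(pairs) + 1]] <- data.frame(
        from = i, to = j, dx = org$x0[j] - org$x0[i],
        dy = org$y0[j] - org$y0[i])
    }
  }
  offsets <- do.call(rbind, pairs)
  st <- stitch_mosaic(m$tiles, offsets)
  expect_equal(st$layout$x, org$x0, tolerance = 1e-9)
  expect_equal(st$layout$y, org$y0, tolerance = 1e-9)
  expect_true(all(abs(st$residuals$rx) < 1e-9))
  # the fused image reproduces the section over the covered area
  cov <- matrix(FALSE, 140, 100)
  for (k in seq_len(nrow(org))) cov[org$x0[k] + 1:80, org$y0[k] + 1:60] <- TRUE
  expect_equal(st$fused[cov], sec[cov], tolerance = 1e-9)
})

test_that("stitching averages out inconsistent offsets by least squares", {
  tiles <- replicate(3, matrix(0, 10, 10), simplify = FALSE)
  # chain 1->2->3 plus a loop-closing 1->3 measurement that disagrees
  offsets <- data.frame(from = c(1, 2, 1), to = c(2, 3, 3),
                        dx = c(10, 10, 23), dy = c(0, 0, 0))
  st <- stitch_mosaic(tiles, offsets)
  # normal equations give x2 = 9, x3 = 16 -> residuals (-1, ... )
  fit <- stats::lsfit(matrix(c(1, -1, 0, 0, 1, 1), 3, 2), c(10, 10, 23),
                      intercept = FALSE)
  expect_equal(st$layout$x[2:3], unname(fit$coefficients), tolerance = 1e-9)
  expect_true(sum(abs(st$residuals$rx)) > 0)
})

test_that("disconnected stitching graphs and single tiles are handled", {
  tiles <- replicate(3, matrix(1, 5, 5), simplify = FALSE)
  offsets <- data.frame(from = 1, to = 2, dx = 3, dy = 0)
  expect_error(stitch_mosaic(tiles, offsets), "disconnected")
  st <- stitch_mosaic(tiles[1], offsets[0, ])
  expect_equal(st$layout$x, 0)
  expect_equal(st$fused, tiles[[1]])
})

test_that("blob detection localizes isolated Gaussian spots", {
  sec <- make_blob_section(shape = c(120, 120), n = 12, sigma = 3,
                           noise_sigma = 0, seed = 31)
  b <- detect_blobs(sec$image, sigma_range = c(2, 5))
  m <- match_puncta(data.frame(x = b$x, y = b$y, z = 0),
                    data.frame(x = sec$centers[, 1], y = sec$centers[, 2],
                               z = 0), max_dist = 2)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
  expect_lt(max(m$errors), 0.5)
  # detected scale is near the planted scale
  expect_lt(max(abs(b$sigma - 3)), 1.5)
  # dark polarity finds inverted blobs, bright does not
  inv <- max(sec$image) - sec$image
  expect_equal(nrow(detect_blobs(inv, sigma_range = c(2, 5),
                                 polarity = "dark")), 12)
  expect_equal(nrow(detect_blobs(matrix(7, 50, 50))), 0)
})

test_that("RANSAC recovers a rigid transform despite outliers", {
  withr::with_seed(32, {
    A <- matrix(stats::runif(2 * 40, 0, 200), ncol = 2)
    tr_true <- rigid2d(5, 10, -3)
    B <- apply_rigid_points(tr_true, A)
    # corrupt 30% of the correspondences
    bad <- sample.int(40, 12)
    B[bad, ] <- matrix(stats::runif(2 * 12, 0, 200), ncol = 2)
  })
  fit <- estimate_rigid_ransac(A, B, inlier_tol = 1)
  expect_equal(fit$transform$theta, 5, tolerance = 1e-6)
  expect_equal(c(fit$transform$dx, fit$transform$dy), c(10, -3),
               tolerance = 1e-6)
  expect_setequal(fit$inliers, setdiff(1:40, bad))
  expect_error(estimate_rigid_ransac(A[1, , drop = FALSE],
                                     B[1, , drop = FALSE]), "insufficient")
  withr::with_seed(33, {
    junkA <- matrix(stats::runif(20, 0, 200), ncol = 2)
    junkB <- matrix(stats::runif(20, 0, 200), ncol = 2)
  })
  expect_error(estimate_rigid_ransac(junkA, junkB, inlier_tol = 0.5),
               "no consensus")
})

test_that("session registration recovers a planted rigid transform", {
  sec <- make_blob_section(shape = c(160, 160), n = 25, sigma = 3,
                           noise_sigma = 0, seed = 34)
  ctr <- c(159, 159) / 2
  tr_true <- rigid2d(2, 4, -2, center = ctr)
  moving <- apply_rigid_image(sec$image, tr_true)
  fit <- register_session(sec$image, moving, blob_args = list(
    sigma_range = c(2, 5)))
  expect_equal(fit$transform$center, ctr)
  expect_lt(abs(fit$transform$theta - 2), 0.1)
  expect_lt(abs(fit$transform$dx - 4), 0.1)
  expect_lt(abs(fit$transform$dy - (-2)), 0.1)
  expect_gte(length(fit$inliers), 15)
  expect_error(register_session(sec$image, matrix(3, 160, 160)), "no signal")
})

test_that("stack alignment removes planted per-section jitter", {
  base <- make_blob_section(shape = c(120, 120), n = 30, sigma = 2,
                            min_sep = 10, noise_sigma = 0, seed = 35)$image
  nz <- 8
  withr::with_seed(36, jit <- matrix(stats::rnorm(2 * nz, 0, 1.5), ncol = 2))
  vol <- array(0, c(120, 120, nz))
  for (s in seq_len(nz)) {
    vol[, , s] <- apply_rigid_image(base, rigid2d(0, jit[s, 1], jit[s, 2]))
  }
  al <- align_stack(vol, max_shift = 8, blob_args = list(sigma_range = c(1.5, 3)))
  # estimated anchor->section translations vs the planted ones
  resid <- cbind(al$transforms$dx - (jit[, 1] - jit[al$anchor, 1]),
                 al$transforms$dy - (jit[, 2] - jit[al$anchor, 2]))
  expect_lt(sqrt(mean(resid^2)), 0.3)
  expect_true(all(abs(al$transforms$theta) < 0.3))
  expect_gt(al$mean_corr_after, al$mean_corr_before)
  expect_error(align_stack(vol[, , 1, drop = FALSE]), "sections")
})

test_that("transforms survive a JSON round trip", {
  trs <- list(rigid2d(1.5, 2.25, -3.5, center = c(63.5, 63.5)),
              rigid2d(-0.25, 0, 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_transforms_json(trs, path)
  back <- read_transforms_json(path)
  expect_equal(back, trs)
})
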