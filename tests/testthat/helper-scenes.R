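# Shared fixtures for the test suite. Everything is generated
# deterministically from explicit seeds; no binary fixtures are used.

# Volume with n Gaussian puncta planted at uniform positions subject to a
# minimum pairwise separation (rejection sampling), plus camera baseline
# and Gaussian read noise. Returns the volume and the ground-truth table.
plant_puncta_volume <- function(n, shape, sigma = c(1.5, 1.5, 1.4),
                                amplitude = 1000, baseline = 400,
                                noise_sigma = 100, min_sep = 9,
                                margin = 6, seed = 1) {
  withr::with_seed(seed, {
    pos <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(pos) < n && tries < 20000) {
      tries <- tries + 1
      p <- c(stats::runif(1, margin, shape[1] - margin),
             stats::runif(1, margin, shape[2] - margin),
             stats::runif(1, margin, shape[3] - margin))
      if (nrow(pos) == 0 ||
          min(sqrt(colSums((t(pos) - p)^2))) >= min_sep) {
        pos <- rbind(pos, p)
      }
    }
    stopifnot(nrow(pos) == n)
    vol <- array(0, shape)
    for (i in seq_len(n)) {
      vol <- arraytomo:::add_gaussian3(vol, pos[i, ], sigma, amplitude)
    }
    vol <- vol + baseline
    if (noise_sigma > 0) {
      vol <- vol + stats::rnorm(length(vol), 0, noise_sigma)
    }
    vol <- pmin(pmax(round(vol), 0), 65535)
    dim(vol) <- shape
    list(volume = vol,
         truth = data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3]))
  })
}

# Match detected puncta to planted positions greedily by distance; returns
# recall, precision and centroid errors of the matched pairs.
match_puncta <- function(detected, truth, max_dist = 3) {
  if (nrow(detected) == 0) {
    return(list(recall = 0, precision = NA_real_, errors = numeric(0)))
  }
  dmat <- outer(seq_len(nrow(detected)), seq_len(nrow(truth)),
                Vectorize(function(i, j) {
                  sqrt((detected$x[i] - truth$x[j])^2 +
                       (detected$y[i] - truth$y[j])^2 +
                       (detected$z[i] - truth$z[j])^2)
                }))
  used_d <- rep(FALSE, nrow(detected))
  used_t <- rep(FALSE, nrow(truth))
  errors <- numeric(0)
  repeat {
    dmat2 <- dmat
    dmat2[used_d, ] <- Inf
    dmat2[, used_t] <- Inf
    m <- which(dmat2 == min(dmat2), arr.ind = TRUE)[1, , drop = TRUE]
    if (!is.finite(dmat2[m[1], m[2]]) || dmat2[m[1], m[2]] > max_dist) break
    used_d[m[1]] <- TRUE
    used_t[m[2]] <- TRUE
    errors <- c(errors, dmat2[m[1], m[2]])
  }
  list(recall = sum(used_t) / nrow(truth),
       precision = sum(used_d) / nrow(detected),
       errors = errors)
}

# 2D section with n isolated Gaussian blobs (nucleus-like), for the
# registration tests. Coordinates are returned 0-based to match
# detect_blobs().
make_blob_section <- function(shape = c(160, 160), n = 25, sigma = 3,
                              amplitude = 5000, baseline = 400,
                              noise_sigma = 0, min_sep = 14, margin = 12,
                              seed = 1) {
  withr::with_seed(seed, {
    pos <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(pos) < n && tries < 20000) {
      tries <- tries + 1
      p <- c(stats::runif(1, margin, shape[1] - margin),
             stats::runif(1, margin, shape[2] - margin))
      if (nrow(pos) == 0 ||
          min(sqrt(colSums((t(pos) - p)^2))) >= min_sep) {
        pos <- rbind(pos, p)
      }
    }
    img <- matrix(0, shape[1], shape[2])
    xs <- seq_len(shape[1]) - 1
    ys <- seq_len(shape[2]) - 1
    for (i in seq_len(nrow(pos))) {
      gx <- exp(-(xs - pos[i, 1])^2 / (2 * sigma^2))
      gy <- exp(-(ys - pos[i, 2])^2 / (2 * sigma^2))
      img <- img + amplitude * outer(gx, gy)
    }
    img <- img + baseline
    if (noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), 0, noise_sigma)
    }
    list(image = img, centers = pos)
  })
}

# Naive spatial-domain convolution with reflective boundary handling,
# written independently of the package FFT implementation (2D or 3D).
conv_same_for_test <- function(x, k) {
  d <- dim(x); dk <- dim(k); pad <- dk %/% 2L
  reflect <- function(i, n) {
    # reflect indices off the edges (no repeated edge sample)
    i <- abs(i - 1) + 1
    i[i > n] <- 2 * n - i[i > n]
    i
  }
  out <- array(0, d)
  if (length(d) == 2) {
    for (a in seq_len(dk[1])) for (b in seq_len(dk[2])) {
      w <- k[a, b]
      if (w == 0) next
      ii <- reflect(seq_len(d[1]) + a - 1 - pad[1], d[1])
      jj <- reflect(seq_len(d[2]) + b - 1 - pad[2], d[2])
      out <- out + w * x[ii, jj]
    }
  } else {
    for (a in seq_len(dk[1])) for (b in seq_len(dk[2])) for (c3 in seq_len(dk[3])) {
      w <- k[a, b, c3]
      if (w == 0) next
      ii <- reflect(seq_len(d[1]) + a - 1 - pad[1], d[1])
      jj <- reflect(seq_len(d[2]) + b - 1 - pad[2], d[2])
      kk <- reflect(seq_len(d[3]) + c3 - 1 - pad[3], d[3])
      out <- out + w * x[ii, jj, kk]
    }
  }
  out
}

# Naive Pearson cross-correlation of two 2D sections at one shift,
# written independently of crosscorr_map() as an oracle.
naive_shift_cor <- function(a, b, du, dv) {
  d <- dim(a)
  i1 <- max(1, 1 - du); i2 <- min(d[1], d[1] - du)
  j1 <- max(1, 1 - dv); j2 <- min(d[2], d[2] - dv)
  if (i1 > i2 || j1 > j2) return(NA_real_)
  av <- as.vector(a[i1:i2, j1:j2])
  bv <- as.vector(b[(i1 + du):(i2 + du), (j1 + dv):(j2 + dv)])
  stats::cor(av, bv)
}
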