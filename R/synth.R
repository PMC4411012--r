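#' Model for one synthetic channel
#'
#' @param role `"presynaptic"` (punctum centred on the synapse locus),
#'   `"postsynaptic"` (displaced along the synapse's pre/post axis) or
#'   `"nuclear"` (renders nuclei, no synaptic puncta).
#' @param participation Fraction of synapse loci bearing a punctum in this
#'   channel (ignored for nuclear channels).
#' @param amplitude_mean,amplitude_sdlog Punctum peak amplitude (a.u.):
#'   log-normal with the given linear-scale mean and log-scale sd.
#' @param sigma_nm Gaussian widths (x, y, z) in nanometres.
#' @param offset_nm,offset_sd_nm Mean length and spread of the pre/post
#'   displacement (postsynaptic channels); presynaptic channels receive an
#'   isotropic jitter of `offset_sd_nm`.
#' @return A list of class `channel_model`.
#' @export
channel_model <- function(role = c("presynaptic", "postsynaptic", "nuclear"),
                          participation = 1, amplitude_mean = 20000,
                          amplitude_sdlog = 0.35,
                          sigma_nm = c(150, 150, 120),
                          offset_nm = 150, offset_sd_nm = 30) {
  role <- match.arg(role)
  stopifnot(participation >= 0, participation <= 1, all(sigma_nm > 0),
            amplitude_mean > 0, offset_nm >= 0, offset_sd_nm >= 0)
  structure(list(role = role, participation = participation,
                 amplitude_mean = amplitude_mean,
                 amplitude_sdlog = amplitude_sdlog,
                 sigma_nm = sigma_nm, offset_nm = offset_nm,
                 offset_sd_nm = offset_sd_nm),
            class = "channel_model")
}

default_channel_models <- function() {
  list("Synapsin1-1" = channel_model("presynaptic", participation = 1),
       "vGluT2-2"    = channel_model("presynaptic", participation = 0.5),
       "PSD95-1"     = channel_model("postsynaptic", participation = 0.9),
       "DAPI-1"      = channel_model("nuclear", amplitude_mean = 30000))
}

#' Specification of a synthetic array tomography scene
#'
#' Describes what [generate_scene()] renders: sparse 3D Gaussian puncta at
#' a controlled density in the neuropil, shared synapse loci across
#' channels (with small pre/post offsets), DAPI-like nuclei inside
#' synapsin-excluded somata, anisotropic voxels, and additive/shot noise.
#'
#' @param shape Voxel counts `c(nx, ny, nz)`.
#' @param voxel A [voxel_size()].
#' @param synapse_density Expected synapse loci per cubic micrometre of
#'   neuropil (tissue outside somata).
#' @param channel_models Named list of [channel_model()]s; names are the
#'   channel tokens.
#' @param soma_count,soma_radius_nm Number and radius of spherical somata
#'   (synapsin-excluded cell bodies).
#' @param nucleus_radius_nm Radius of the DAPI-bright nucleus rendered at
#'   each soma centre.
#' @param baseline Constant camera offset (a.u.) added to every voxel, as
#'   on a real detector; keeps the background away from the zero-clip so
#'   robust background statistics behave.
#' @param noise_sigma Additive Gaussian read-noise sd (a.u.).
#' @param shot_noise If `TRUE`, voxel values are Poisson-resampled before
#'   read noise is added.
#' @param seed Integer; fixes the full scene.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(128, 128, 16), voxel = voxel_size(),
                       synapse_density = 1.0,
                       channel_models = default_channel_models(),
                       soma_count = 2, soma_radius_nm = 2500,
                       nucleus_radius_nm = 1800, baseline = 400,
                       noise_sigma = 100, shot_noise = FALSE, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), synapse_density >= 0,
            soma_count >= 0, noise_sigma >= 0,
            length(channel_models) >= 1L,
            !is.null(names(channel_models)),
            all(nzchar(names(channel_models))))
  ok <- vapply(channel_models, inherits, logical(1), "channel_model")
  if (!all(ok)) stop("channel_models must be channel_model objects", call. = FALSE)
  structure(list(shape = as.integer(shape), voxel = voxel,
                 synapse_density = synapse_density,
                 channel_models = channel_models,
                 soma_count = as.integer(soma_count),
                 soma_radius_nm = soma_radius_nm,
                 nucleus_radius_nm = nucleus_radius_nm,
                 baseline = baseline,
                 noise_sigma = noise_sigma, shot_noise = shot_noise,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# add an anisotropic 3D Gaussian (truncated at 4 sigma) in place
add_gaussian3 <- function(vol, center, sigma, amp, trunc = 4) {
  d <- dim(vol)
  lo <- pmax(1L, floor(center - trunc * sigma))
  hi <- pmin(d, ceiling(center + trunc * sigma))
  if (any(lo > hi)) return(vol)
  gx <- exp(-((lo[1]:hi[1]) - center[1])^2 / (2 * sigma[1]^2))
  gy <- exp(-((lo[2]:hi[2]) - center[2])^2 / (2 * sigma[2]^2))
  gz <- exp(-((lo[3]:hi[3]) - center[3])^2 / (2 * sigma[3]^2))
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
    amp * (gx %o% gy %o% gz)
  vol
}

# soft-edged sphere (superellipse falloff) for nuclei
add_sphere3 <- function(vol, center, radius_vox, amp) {
  d <- dim(vol)
  lo <- pmax(1L, floor(center - radius_vox * 1.5))
  hi <- pmin(d, ceiling(center + radius_vox * 1.5))
  if (any(lo > hi)) return(vol)
  rx <- ((lo[1]:hi[1]) - center[1]) / radius_vox[1]
  ry <- ((lo[2]:hi[2]) - center[2]) / radius_vox[2]
  rz <- ((lo[3]:hi[3]) - center[3]) / radius_vox[3]
  r2 <- outer(outer(rx^2, ry^2, `+`), rz^2, `+`)
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + amp * exp(-(r2^4))
  vol
}

runit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a ground-truthed synthetic scene
#'
#' Synapse loci are a homogeneous Poisson process in the neuropil (the
#' volume minus the somata). Each synaptic channel renders an anisotropic
#' 3D Gaussian punctum at the locus (presynaptic) or at the locus plus the
#' synapse's pre/post displacement (postsynaptic); nuclear channels render
#' soft-edged spheres at soma centres. Noise is applied last. The same
#' seed yields a bit-identical scene.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `synthetic_scene` with elements `spec`, `truth`
#'   (lists `loci`, `puncta`, `somata` data frames), and `rendered`
#'   (a [data_volume()]).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  d <- spec$shape
  nm <- c(spec$voxel$vx, spec$voxel$vy, spec$voxel$vz)
  vol_um3 <- prod(d) * prod(nm) / 1e9

  # somata (voxel coordinates of centres; radii in voxels per axis)
  soma_r_vox <- spec$soma_radius_nm / nm
  somata <- if (spec$soma_count > 0) {
    cbind(x = stats::runif(spec$soma_count, 1, d[1]),
          y = stats::runif(spec$soma_count, 1, d[2]),
          z = stats::runif(spec$soma_count, 1, d[3]))
  } else matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))

  inside_soma <- function(p) {
    if (nrow(somata) == 0) return(rep(FALSE, nrow(p)))
    hit <- rep(FALSE, nrow(p))
    for (s in seq_len(nrow(somata))) {
      m <- ((p[, 1] - somata[s, 1]) / soma_r_vox[1])^2 +
        ((p[, 2] - somata[s, 2]) / soma_r_vox[2])^2 +
        ((p[, 3] - somata[s, 3]) / soma_r_vox[3])^2
      hit <- hit | m <= 1
    }
    hit
  }

  # homogeneous Poisson loci in the neuropil: sample over the whole box at
  # the neuropil intensity, then reject points inside somata
  n_loci <- stats::rpois(1, spec$synapse_density * vol_um3)
  loci <- cbind(x = stats::runif(n_loci, 0.5, d[1] + 0.5),
                y = stats::runif(n_loci, 0.5, d[2] + 0.5),
                z = stats::runif(n_loci, 0.5, d[3] + 0.5))
  loci <- loci[!inside_soma(loci), , drop = FALSE]
  n_loci <- nrow(loci)
  post_dir <- if (n_loci > 0) runit_vectors(n_loci) else
    matrix(numeric(0), 0, 3)

  loci_df <- data.frame(locus = seq_len(n_loci),
                        x_vox = loci[, 1], y_vox = loci[, 2],
                        z_vox = loci[, 3],
                        x_um = (loci[, 1] - 0.5) * nm[1] / 1000,
                        y_um = (loci[, 2] - 0.5) * nm[2] / 1000,
                        z_um = (loci[, 3] - 0.5) * nm[3] / 1000)

  puncta_rows <- list()
  channels <- vector("list", length(spec$channel_models))
  names(channels) <- names(spec$channel_models)

  for (cn in names(spec$channel_models)) {
    cm <- spec$channel_models[[cn]]
    vol <- array(0, d)
    if (cm$role == "nuclear") {
      nuc_r_vox <- spec$nucleus_radius_nm / nm
      for (s in seq_len(nrow(somata))) {
        vol <- add_sphere3(vol, somata[s, ], nuc_r_vox, cm$amplitude_mean)
      }
    } else if (n_loci > 0) {
      take <- stats::runif(n_loci) < cm$participation
      idx <- which(take)
      if (length(idx) > 0) {
        sig_vox <- cm$sigma_nm / nm
        amps <- stats::rlnorm(length(idx),
                              meanlog = log(cm$amplitude_mean) -
                                cm$amplitude_sdlog^2 / 2,
                              sdlog = cm$amplitude_sdlog)
        centers <- loci[idx, , drop = FALSE]
        if (cm$role == "postsynaptic") {
          len <- pmax(0, stats::rnorm(length(idx), cm$offset_nm,
                                      cm$offset_sd_nm))
          centers <- centers +
            post_dir[idx, , drop = FALSE] * len / rep(nm, each = length(idx))
        } else if (cm$offset_sd_nm > 0) {
          centers <- centers +
            matrix(stats::rnorm(3 * length(idx), 0, cm$offset_sd_nm),
                   ncol = 3) / rep(nm, each = length(idx))
        }
        for (k in seq_along(idx)) {
          vol <- add_gaussian3(vol, centers[k, ], sig_vox, amps[k])
        }
        puncta_rows[[cn]] <- data.frame(locus = idx, channel = cn,
                                        x_vox = centers[, 1],
                                        y_vox = centers[, 2],
                                        z_vox = centers[, 3],
                                        amplitude = amps)
      }
    }
    if (mean(vol >= 65535) > 0.5) {
      stop("degenerate spec: more than half of the voxels saturate",
           call. = FALSE)
    }
    vol <- vol + spec$baseline
    if (spec$shot_noise) {
      vol[] <- stats::rpois(length(vol), pmax(vol, 0))
    }
    if (spec$noise_sigma > 0) {
      vol <- vol + stats::rnorm(length(vol), 0, spec$noise_sigma)
    }
    vol <- round(pmin(pmax(vol, 0), 65535))
    channels[[cn]] <- channel_volume(cn, vol, voxel = spec$voxel)
  }

  puncta <- if (length(puncta_rows)) do.call(rbind, puncta_rows) else
    data.frame(locus = integer(0), channel = character(0),
               x_vox = numeric(0), y_vox = numeric(0), z_vox = numeric(0),
               amplitude = numeric(0))
  rownames(puncta) <- NULL

  structure(list(spec = spec,
                 truth = list(loci = loci_df, puncta = puncta,
                              somata = as.data.frame(somata),
                              soma_radius_vox = soma_r_vox,
                              neuropil_volume_um3 = vol_um3 *
                                neuropil_fraction(d, somata, soma_r_vox)),
                 rendered = data_volume("synthetic", channels),
                 session_transforms = NULL),
            class = "synthetic_scene")
}

# fraction of the box outside the (possibly clipped, overlapping) somata,
# by voxel-centre counting
neuropil_fraction <- function(d, somata, soma_r_vox) {
  if (nrow(somata) == 0) return(1)
  inside <- array(FALSE, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  for (s in seq_len(nrow(somata))) {
    mx <- ((xs - somata[s, 1]) / soma_r_vox[1])^2
    my <- ((ys - somata[s, 2]) / soma_r_vox[2])^2
    mz <- ((zs - somata[s, 3]) / soma_r_vox[3])^2
    inside <- inside | (outer(outer(mx, my, `+`), mz, `+`) <= 1)
  }
  1 - mean(inside)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %s, %d synapse loci, %d somata\n",
              paste(x$spec$shape, collapse = " x "),
              nrow(x$truth$loci), nrow(x$truth$somata)))
  print(x$rendered)
  invisible(x)
}

#' Apply a rigid between-session transform with per-section jitter
#'
#' Emulates the small shifts of the coverslip-affixed ribbon between
#' imaging sessions: every z-section of the listed channels is resampled
#' under a common rigid transform (rotation about the section centre plus
#' translation) composed with an independent per-section translation
#' jitter. The applied transforms are recorded in
#' `scene$session_transforms` so registration can be scored against truth.
#'
#' @param scene A [synthetic_scene()].
#' @param channels Character vector of channel tokens to move.
#' @param rotation Rotation in degrees.
#' @param translation Translation `c(dx, dy)` in voxels.
#' @param per_section_jitter Sd (voxels) of the per-section translation
#'   jitter.
#' @param seed Integer seed for the jitter draws.
#' @return The scene with moved channels and a `session_transforms`
#'   data frame (channel, section, theta, dx, dy).
#' @export
apply_session_transform <- function(scene, channels, rotation = 0,
                                    translation = c(0, 0),
                                    per_section_jitter = 0, seed = 1L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  miss <- setdiff(channels, names(scene$rendered$channels))
  if (length(miss)) stop("channel token not found: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d <- dim(scene$rendered$channels[[channels[1]]]$data)
  ctr <- (d[1:2] - 1) / 2
  jit <- withr::with_seed(seed,
    matrix(stats::rnorm(2 * d[3], 0, per_section_jitter), ncol = 2))
  recs <- list()
  for (cn in channels) {
    a <- scene$rendered$channels[[cn]]$data
    for (s in seq_len(d[3])) {
      tr <- rigid2d(rotation, translation[1] + jit[s, 1],
                    translation[2] + jit[s, 2], center = ctr)
      a[, , s] <- apply_rigid_image(a[, , s], tr)
    }
    a <- round(pmin(pmax(a, 0), 65535))
    scene$rendered$channels[[cn]] <- channel_volume(cn, a, scene$spec$voxel)
    recs[[cn]] <- data.frame(channel = cn, section = seq_len(d[3]),
                             theta = rotation,
                             dx = translation[1] + jit[, 1],
                             dy = translation[2] + jit[, 2])
  }
  tab <- do.call(rbind, recs); rownames(tab) <- NULL
  scene$session_transforms <- rbind(scene$session_transforms, tab)
  scene
}

#' Split a section into overlapping mosaic tiles
#'
#' Emulates adjacent microscope fields of view: tiles of `tile_shape`
#' cover the section with stride `ceiling(tile * (1 - overlap_fraction))`;
#' a final tile flush with the far edge guarantees coverage. True origins
#' are returned for stitching-recovery tests.
#'
#' @param section 2D matrix (x, y).
#' @param tile_shape Tile size `c(tx, ty)` in pixels.
#' @param overlap_fraction Nominal overlap between neighbours, in `(0, 0.5]`.
#' @return A list with `tiles` (list of matrices, row-major over the grid)
#'   and `origins` (data frame `tile, x0, y0`, 0-based).
#' @export
tile_mosaic <- function(section, tile_shape, overlap_fraction = 0.2) {
  stopifnot(is.matrix(section), length(tile_shape) == 2L)
  if (overlap_fraction <= 0 || overlap_fraction > 0.5) {
    stop("overlap_fraction must lie in (0, 0.5]", call. = FALSE)
  }
  d <- dim(section)
  if (any(tile_shape > d)) stop("tile larger than section", call. = FALSE)
  origins_axis <- function(n, t) {
    stride <- max(1L, as.integer(ceiling(t * (1 - overlap_fraction))))
    o <- seq(0L, max(0L, n - t), by = stride)
    if (o[length(o)] + t < n) o <- c(o, n - t)
    unique(o)
  }
  ox <- origins_axis(d[1], tile_shape[1])
  oy <- origins_axis(d[2], tile_shape[2])
  grid <- expand.grid(x0 = ox, y0 = oy)
  tiles <- lapply(seq_len(nrow(grid)), function(k) {
    section[grid$x0[k] + seq_len(tile_shape[1]),
            grid$y0[k] + seq_len(tile_shape[2])]
  })
  list(tiles = tiles,
       origins = data.frame(tile = seq_len(nrow(grid)),
                            x0 = grid$x0, y0 = grid$y0))
}
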