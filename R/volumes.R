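#' A single antibody channel
#'
#' Intensity data are held as a 3D array with dimension order (x, y, z),
#' x fastest, on the 16-bit acquisition scale (0-65535 a.u.). Channel
#' names follow the `<antibody>-<round>` convention in which the suffix
#' encodes the staining/imaging round, e.g. `"Synapsin1-2"`.
#'
#' @param name Channel token of the form `<antibody>-<round>`.
#' @param data 3D numeric array (a 2D matrix is promoted to a single
#'   section); values in `[0, 65535]`.
#' @param voxel A [voxel_size()].
#' @return An object of class `channel_volume`.
#' @export
channel_volume <- function(name, data, voxel = voxel_size()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!grepl("^.+-[0-9]+$", name)) {
    stop("channel name must have the form '<antibody>-<round>': ", name,
         call. = FALSE)
  }
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("channel data must be a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("channel dimensions must be >= 1", call. = FALSE)
  if (anyNA(data) || min(data) < 0 || max(data) > 65535) {
    stop("intensities must lie in [0, 65535] a.u.", call. = FALSE)
  }
  stopifnot(inherits(voxel, "voxel_size"))
  structure(list(name = name, data = data, voxel = voxel),
            class = "channel_volume")
}

#' @export
print.channel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("channel '%s': %d x %d x %d voxels, [%g, %g] a.u.\n",
              x$name, d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' A multichannel data volume
#'
#' An ordered collection of co-registered [channel_volume()]s sharing one
#' voxel grid. Channels are addressed by name or by their 1-based numeric
#' token (position in the list).
#'
#' @param token Volume identifier (e.g. `"Ex2R18C1"`).
#' @param channels List of `channel_volume` objects with identical
#'   dimensions and voxel size; names must be unique.
#' @return An object of class `data_volume`.
#' @export
data_volume <- function(token, channels) {
  stopifnot(is.character(token), length(token) == 1L, is.list(channels),
            length(channels) >= 1L)
  ok <- vapply(channels, inherits, logical(1), "channel_volume")
  if (!all(ok)) stop("all channels must be channel_volume objects", call. = FALSE)
  nms <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("channel names must be unique", call. = FALSE)
  dims <- vapply(channels, function(ch) dim(ch$data), integer(3))
  if (any(dims != dims[, 1])) {
    stop("all channels must share identical dimensions", call. = FALSE)
  }
  names(channels) <- nms
  structure(list(token = token, channels = channels,
                 voxel = channels[[1]]$voxel),
            class = "data_volume")
}

#' @export
print.data_volume <- function(x, ...) {
  d <- dim(x$channels[[1]]$data)
  cat(sprintf("data volume '%s': %d channels, %d x %d x %d voxels\n",
              x$token, length(x$channels), d[1], d[2], d[3]))
  cat(" ", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Look up a channel by name or numeric token
#'
#' @param volume A [data_volume()].
#' @param channel Channel name, or 1-based numeric position.
#' @return The matching `channel_volume`.
#' @export
get_channel <- function(volume, channel) {
  stopifnot(inherits(volume, "data_volume"))
  if (is.numeric(channel)) {
    k <- as.integer(channel)
    if (length(k) != 1L || is.na(k) || k < 1L || k > length(volume$channels)) {
      stop("channel token not found: ", channel, call. = FALSE)
    }
    return(volume$channels[[k]])
  }
  if (!channel %in% names(volume$channels)) {
    stop("channel token not found: ", channel, call. = FALSE)
  }
  volume$channels[[channel]]
}

#' A region-of-interest mask
#'
#' @param label ROI label, e.g. `"C2-L4"`.
#' @param mask 3D logical array congruent with its parent volume.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(label, mask) {
  stopifnot(is.character(label), length(label) == 1L)
  if (is.matrix(mask)) dim(mask) <- c(dim(mask), 1L)
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask)) {
    stop("mask must be a 3D logical array", call. = FALSE)
  }
  structure(list(label = label, mask = mask), class = "roi_mask")
}

# 2x2 mean pooling in x and y; odd trailing row/column dropped; z untouched.
pool2x2_xy <- function(a) {
  d <- dim(a)
  nx <- d[1] %/% 2L; ny <- d[2] %/% 2L
  if (nx < 1L || ny < 1L) stop("volume too small to downsample", call. = FALSE)
  a <- a[seq_len(2L * nx), seq_len(2L * ny), , drop = FALSE]
  ix <- seq(1L, 2L * nx, by = 2L); iy <- seq(1L, 2L * ny, by = 2L)
  (a[ix, iy, , drop = FALSE] + a[ix + 1L, iy, , drop = FALSE] +
     a[ix, iy + 1L, , drop = FALSE] + a[ix + 1L, iy + 1L, , drop = FALSE]) / 4
}

check_range <- function(r, n, axis, scalar = FALSE) {
  if (is.null(r)) r <- if (scalar) 0L else c(0L, n)
  if (scalar) {
    if (length(r) != 1L || r < 0 || r >= n) {
      stop(sprintf("%s index out of range [0, %d)", axis, n), call. = FALSE)
    }
    return(as.integer(r))
  }
  if (length(r) != 2L || r[1] < 0 || r[2] > n || r[1] >= r[2]) {
    stop(sprintf("%s range must be half-open [min, max) within [0, %d)",
                 axis, n), call. = FALSE)
  }
  as.integer(r)
}

#' Extract a cutout from a data volume
#'
#' Addressing follows the web-cutout convention: 0-based voxel indices,
#' half-open `[min, max)` ranges, so a range `c(700, 1700)` is 1000 voxels
#' wide. Resolution level 1 downsamples x and y by 2x2 mean pooling
#' (display mipmaps are built in-plane only; z is untouched); ranges are
#' then interpreted on the downsampled grid.
#'
#' @param volume A [data_volume()].
#' @param channel Channel name or numeric token.
#' @param plane One of `"xy"`, `"xz"`, `"yz"` (2D slices) or `"3d"`.
#' @param resolution 0 (native) or 1 (half resolution in x and y).
#' @param x_range,y_range,z_range Half-open `c(min, max)` ranges for the
#'   in-plane axes; the axis orthogonal to a 2D plane takes a single
#'   0-based index. `NULL` means full range (or index 0 for the
#'   orthogonal axis).
#' @return For a 2D plane, a matrix (first index along the first named
#'   axis of the plane); for `"3d"`, a 3D array. Always a copy.
#' @export
cutout <- function(volume, channel, plane = c("xy", "xz", "yz", "3d"),
                   resolution = 0, x_range = NULL, y_range = NULL,
                   z_range = NULL) {
  plane <- match.arg(plane)
  if (!resolution %in% c(0, 1)) stop("resolution must be 0 or 1", call. = FALSE)
  a <- get_channel(volume, channel)$data
  if (resolution == 1) a <- pool2x2_xy(a)
  d <- dim(a)
  if (plane == "3d") {
    xr <- check_range(x_range, d[1], "x"); yr <- check_range(y_range, d[2], "y")
    zr <- check_range(z_range, d[3], "z")
    return(a[(xr[1] + 1L):xr[2], (yr[1] + 1L):yr[2], (zr[1] + 1L):zr[2],
             drop = FALSE])
  }
  if (plane == "xy") {
    xr <- check_range(x_range, d[1], "x"); yr <- check_range(y_range, d[2], "y")
    z <- check_range(z_range, d[3], "z", scalar = TRUE)
    return(a[(xr[1] + 1L):xr[2], (yr[1] + 1L):yr[2], z + 1L])
  }
  if (plane == "xz") {
    xr <- check_range(x_range, d[1], "x"); zr <- check_range(z_range, d[3], "z")
    y <- check_range(y_range, d[2], "y", scalar = TRUE)
    return(a[(xr[1] + 1L):xr[2], y + 1L, (zr[1] + 1L):zr[2]])
  }
  yr <- check_range(y_range, d[2], "y"); zr <- check_range(z_range, d[3], "z")
  x <- check_range(x_range, d[1], "x", scalar = TRUE)
  a[x + 1L, (yr[1] + 1L):yr[2], (zr[1] + 1L):zr[2]]
}

# CYMRGB slot colors used by multi-channel false-color composites
mcfc_colors <- function() {
  rbind(cyan    = c(0, 1, 1),
        yellow  = c(1, 1, 0),
        magenta = c(1, 0, 1),
        red     = c(1, 0, 0),
        green   = c(0, 1, 0),
        blue    = c(0, 0, 1))
}

#' Multi-channel false-color composite
#'
#' Listed channels are assigned, in order, to the color slots cyan,
#' yellow, magenta, red, green, blue; the placeholder token `"0"` skips a
#' slot so e.g. `c("0","0","0","Synapsin1-2","PSD95-1","DAPI-1")` renders
#' red/green/blue. Each channel is min-max scaled, multiplied by its slot
#' color, additively blended and clipped to the displayable range.
#'
#' @param volume A [data_volume()].
#' @param tokens Up to 6 channel tokens (names or numeric tokens given as
#'   strings/numbers), with `"0"` as placeholder.
#' @inheritParams cutout
#' @return An `nx x ny x 3` RGB array in `[0, 1]`.
#' @export
mcfc_composite <- function(volume, tokens, plane = "xy", resolution = 0,
                           x_range = NULL, y_range = NULL, z_range = NULL) {
  tokens <- as.list(tokens)
  if (length(tokens) > 6L) {
    stop("at most 6 channel tokens may be composited", call. = FALSE)
  }
  is_ph <- vapply(tokens, function(t) identical(as.character(t), "0"),
                  logical(1))
  if (all(is_ph)) stop("empty composite: all tokens are placeholders",
                       call. = FALSE)
  cols <- mcfc_colors()
  rgb <- NULL
  for (k in seq_along(tokens)) {
    if (is_ph[k]) next
    img <- cutout(volume, tokens[[k]], plane = plane, resolution = resolution,
                  x_range = x_range, y_range = y_range, z_range = z_range)
    if (length(dim(img)) != 2L && !is.matrix(img)) {
      stop("composites require a 2D plane", call. = FALSE)
    }
    rng <- range(img)
    scaled <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
    if (is.null(rgb)) rgb <- array(0, c(dim(img), 3L))
    for (c3 in 1:3) rgb[, , c3] <- rgb[, , c3] + scaled * cols[k, c3]
  }
  rgb[rgb > 1] <- 1
  rgb
}

#' Write / read a channel as a multi-page TIFF
#'
#' One z-paged 16-bit TIFF per channel, pages in ImageJ axis order
#' (rows = y, columns = x).
#'
#' @param channel A [channel_volume()].
#' @param path Output file path.
#' @return `write_channel_tiff` returns `path` invisibly;
#'   `read_channel_tiff` returns a `channel_volume`.
#' @export
write_channel_tiff <- function(channel, path) {
  stopifnot(inherits(channel, "channel_volume"))
  pages <- lapply(seq_len(dim(channel$data)[3]), function(k) {
    t(channel$data[, , k]) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @param name Channel token to assign to the read data.
#' @param voxel A [voxel_size()].
#' @rdname write_channel_tiff
#' @export
read_channel_tiff <- function(path, name, voxel = voxel_size()) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # tolerate gray-as-RGB
    t(p)
  }, matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  channel_volume(name, round(arr * 65535), voxel = voxel)
}

#' Write / read a data volume as a directory container
#'
#' The container is a directory with one multi-page TIFF per channel and
#' a `volume.json` sidecar recording the token, voxel size (nm) and the
#' channel order.
#'
#' @param volume A [data_volume()].
#' @param dir Container directory (created if needed).
#' @return `write_data_volume` returns `dir` invisibly;
#'   `read_data_volume` returns a `data_volume`.
#' @export
write_data_volume <- function(volume, dir) {
  stopifnot(inherits(volume, "data_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in volume$channels) {
    write_channel_tiff(ch, file.path(dir, paste0(ch$name, ".tif")))
  }
  meta <- list(token = volume$token,
               voxel_nm = c(volume$voxel$vx, volume$voxel$vy, volume$voxel$vz),
               channels = names(volume$channels))
  jsonlite::write_json(meta, file.path(dir, "volume.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_data_volume
#' @export
read_data_volume <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "volume.json"),
                              simplifyVector = TRUE)
  vox <- voxel_size(meta$voxel_nm[1], meta$voxel_nm[2], meta$voxel_nm[3])
  chans <- lapply(meta$channels, function(nm) {
    read_channel_tiff(file.path(dir, paste0(nm, ".tif")), nm, voxel = vox)
  })
  data_volume(meta$token, chans)
}

#' Write a 2D image or RGB composite to PNG
#'
#' Grayscale images are min-max scaled; RGB composites are written as-is.
#'
#' @param img A matrix (x, y) or an `nx x ny x 3` RGB array.
#' @param path Output path.
#' @export
write_png_image <- function(img, path) {
  if (is.matrix(img)) {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
    png::writePNG(t(img), path)
  } else {
    png::writePNG(aperm(img, c(2, 1, 3)), path)
  }
  invisible(path)
}
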