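#' Rotate an image 180 degrees
#'
#' Reverses both in-plane axes (each z-section independently for a 3D
#' array). An exact involution: rotating twice restores the input
#' bit-for-bit. Used as the chance-colocalization null when comparing
#' staining rounds.
#'
#' @param image 2D matrix or 3D array (x, y, z).
#' @return Rotated image of the same shape.
#' @export
rotate180 <- function(image) {
  if (is.matrix(image)) {
    return(image[rev(seq_len(nrow(image))), rev(seq_len(ncol(image))),
                 drop = FALSE])
  }
  stopifnot(length(dim(image)) == 3)
  image[rev(seq_len(dim(image)[1])), rev(seq_len(dim(image)[2])), ,
        drop = FALSE]
}

#' Percent-consistent foreground between two staining rounds
#'
#' With `A` and `B` the sets of pixels strictly above `threshold` in each
#' image, returns `100 * |A intersect B| / |A union B|` — a Jaccard index
#' on foreground masks, symmetric in its arguments. Pixels bright in
#' either round that are bright in both measure how repeatable the stain
#' is after elution and re-staining.
#'
#' @param imageA,imageB Same-shape intensity images (a.u., 16-bit scale).
#' @param threshold Foreground threshold in a.u. (default 1000; strict
#'   inequality).
#' @return Percent in `[0, 100]`; 0 with a warning when neither image has
#'   foreground.
#' @export
percent_consistent <- function(imageA, imageB, threshold = 1000) {
  if (!identical(dim(imageA), dim(imageB))) {
    stop("images must have identical shape", call. = FALSE)
  }
  A <- imageA > threshold; B <- imageB > threshold
  uni <- sum(A | B)
  if (uni == 0) {
    warning("no foreground pixels in either image; returning 0")
    return(0)
  }
  100 * sum(A & B) / uni
}

#' @rdname percent_consistent
#' @details `background_percent_consistent` applies the same measure to
#'   the sub-threshold (background) pixel sets.
#' @export
background_percent_consistent <- function(imageA, imageB, threshold = 1000) {
  if (!identical(dim(imageA), dim(imageB))) {
    stop("images must have identical shape", call. = FALSE)
  }
  A <- !(imageA > threshold); B <- !(imageB > threshold)
  uni <- sum(A | B)
  if (uni == 0) {
    warning("no background pixels in either image; returning 0")
    return(0)
  }
  100 * sum(A & B) / uni
}

#' Between-round stain-consistency report
#'
#' Compares two registered imaging rounds of the same antibody: Pearson
#' correlation of pixel intensities, percent-consistent foreground and
#' background, and the same three statistics with the later round rotated
#' 180 degrees as a control for chance colocalization.
#'
#' @param round1,round3 Registered same-shape images (2D or 3D).
#' @param threshold Foreground threshold in a.u. (default 1000).
#' @return A list of class `consistency_report` with fields `r`,
#'   `r_rotated`, `pct_consistent`, `pct_consistent_rotated`,
#'   `bg_pct_consistent`, `bg_pct_consistent_rotated`, `threshold`.
#' @export
consistency_report <- function(round1, round3, threshold = 1000) {
  if (!identical(dim(round1), dim(round3))) {
    stop("images must have identical shape", call. = FALSE)
  }
  if (stats::sd(round1) == 0 || stats::sd(round3) == 0) {
    stop("no signal: zero-variance image, correlation undefined",
         call. = FALSE)
  }
  rot <- rotate180(round3)
  structure(list(
    r = stats::cor(as.vector(round1), as.vector(round3)),
    r_rotated = stats::cor(as.vector(round1), as.vector(rot)),
    pct_consistent = percent_consistent(round1, round3, threshold),
    pct_consistent_rotated = percent_consistent(round1, rot, threshold),
    bg_pct_consistent = background_percent_consistent(round1, round3,
                                                      threshold),
    bg_pct_consistent_rotated = background_percent_consistent(round1, rot,
                                                              threshold),
    threshold = threshold), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(paste0("consistency: R = %.3f (rotated %.3f); ",
                     "%% consistent = %.1f (rotated %.1f); ",
                     "background %% = %.1f (rotated %.1f); threshold %g a.u.\n"),
              x$r, x$r_rotated, x$pct_consistent, x$pct_consistent_rotated,
              x$bg_pct_consistent, x$bg_pct_consistent_rotated, x$threshold))
  invisible(x)
}

#' Consistency table for several antibodies
#'
#' @param pairs Named list; each element is a list with elements `round1`
#'   and `round3` (registered images), named by antibody.
#' @param threshold Foreground threshold (a.u.).
#' @return Data frame mirroring the standard consistency-table columns.
#' @export
consistency_table <- function(pairs, threshold = 1000) {
  rows <- lapply(names(pairs), function(ab) {
    rep <- consistency_report(pairs[[ab]]$round1, pairs[[ab]]$round3,
                              threshold)
    data.frame(antibody = ab, R = rep$r, R_rotated = rep$r_rotated,
               pct_consistent = rep$pct_consistent,
               pct_consistent_rotated = rep$pct_consistent_rotated,
               bg_pct_consistent = rep$bg_pct_consistent,
               bg_pct_consistent_rotated = rep$bg_pct_consistent_rotated)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
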