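#' Simulate a multi-ribbon two-layer cohort and compare densities
#'
#' End-to-end harness for planning layer-comparison studies: for each
#' ribbon, two ROI volumes (one per layer class) are simulated at the
#' given synapse densities, puncta are segmented in the counted channel,
#' the neuropil is estimated from the synapsin channel, and the
#' per-ribbon neuropil-normalized densities are compared across ribbons
#' with the exact Wilcoxon signed-rank test.
#'
#' The total synapse density (and hence the synapsin channel that
#' defines the neuropil) is held fixed across classes, as it is across
#' cortical layers in tissue; the planted difference is carried entirely
#' by the participation of the counted marker, so `density1 / density2`
#' is the planted density ratio of counted puncta over an unchanged
#' neuropil.
#'
#' @param n_ribbons Number of ribbons (paired observations).
#' @param density1,density2 Planted densities of the counted marker
#'   (per um^3 of neuropil) for the two layer classes, e.g. L4 and L5a.
#'   Both must be `<= synapse_density`.
#' @param synapse_density Total synapse density, identical in both
#'   classes.
#' @param shape Voxel counts of each ROI volume.
#' @param seed Integer seed for the cohort.
#' @param dilate_radii Neuropil dilation radii (voxels).
#' @param params A [segmentation_params()].
#' @return A `paired_comparison` (see
#'   [compare_rois_across_ribbons()]) with the per-ribbon density pairs
#'   attached.
#' @export
simulate_density_cohort <- function(n_ribbons = 7, density1 = 5,
                                    density2 = 2.5, synapse_density = 5,
                                    shape = c(48, 48, 10),
                                    seed = 1L, dilate_radii = c(3, 3, 2),
                                    params = segmentation_params()) {
  if (density1 > synapse_density || density2 > synapse_density) {
    stop("marker densities cannot exceed the total synapse density",
         call. = FALSE)
  }
  rows <- list()
  for (rb in seq_len(n_ribbons)) {
    for (cl in 1:2) {
      dens <- if (cl == 1) density1 else density2
      models <- list(
        "Synapsin1-1" = channel_model("presynaptic", participation = 1),
        "vGluT2-2" = channel_model("presynaptic",
                                   participation = dens / synapse_density))
      sc <- generate_scene(scene_spec(
        shape = shape, synapse_density = synapse_density,
        channel_models = models,
        soma_count = 0, seed = seed * 1009L + rb * 23L + cl))
      puncta <- segment_puncta(get_channel(sc$rendered, "vGluT2-2"), params)
      np <- neuropil_mask(get_channel(sc$rendered, "Synapsin1-1"),
                          dilate_radii = dilate_radii)
      dres <- roi_density(puncta, roi = NULL, neuropil = np)
      rows[[length(rows) + 1]] <- data.frame(
        ribbon = paste0("R", rb), class = c("L4", "L5a")[cl],
        density_per_um3 = dres$density_per_um3,
        median_total_intensity = dres$median_total_intensity)
    }
  }
  compare_rois_across_ribbons(do.call(rbind, rows), "L4", "L5a",
                              statistic = "density")
}

#' Power of the cohort comparison over repeated cohorts
#'
#' Runs [simulate_density_cohort()] for many independently seeded
#' cohorts and reports how often the planted difference is detected at
#' the minimum attainable two-sided p for the cohort size
#' (`2 / 2^n_ribbons`), together with the distribution of the median
#' percent difference.
#'
#' @inheritParams simulate_density_cohort
#' @param n_cohorts Number of cohorts.
#' @param seed Base seed; cohort `i` uses `seed + i`.
#' @return A list: `fraction_min_p`, `p_values`, `median_pct_differences`.
#' @export
density_ratio_power <- function(n_cohorts = 100, n_ribbons = 7, density1 = 5,
                                density2 = 2.5, synapse_density = 5,
                                shape = c(48, 48, 10),
                                seed = 1L, ...) {
  p_min <- 2 / 2^n_ribbons
  ps <- numeric(n_cohorts); md <- numeric(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    cmp <- simulate_density_cohort(n_ribbons = n_ribbons,
                                   density1 = density1, density2 = density2,
                                   synapse_density = synapse_density,
                                   shape = shape, seed = seed + i, ...)
    ps[i] <- cmp$p.value; md[i] <- cmp$median_pct_difference
  }
  list(fraction_min_p = mean(ps <= p_min + 1e-12), p_values = ps,
       median_pct_differences = md)
}
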