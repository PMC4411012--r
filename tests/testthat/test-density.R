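test_that("the neuropil mask excludes a planted soma", {
  # dense synapsin puncta everywhere outside a central soma sphere
  shape <- c(48, 48, 24)
  soma_c <- c(24, 24, 12); soma_r <- c(8, 8, 8)
  vol <- array(0, shape)
  withr::with_seed(1, {
    for (k in 1:600) {
      p <- c(stats::runif(1, 1, 48), stats::runif(1, 1, 48),
             stats::runif(1, 1, 24))
      if (sum(((p - soma_c) / soma_r)^2) <= 1) next
      vol <- arraytomo:::add_gaussian3(vol, p, c(1.5, 1.5, 1.4), 2000)
    }
    vol <- pmin(pmax(round(vol + stats::rnorm(length(vol), 400, 80)), 0),
                65535)
    dim(vol) <- shape
  })
  np <- neuropil_mask(vol, dilate_radii = c(3, 3, 3), max_hole_voxels = 50)
  inside <- array(FALSE, shape)
  for (x in 1:48) for (y in 1:48) for (z in 1:24) {
    inside[x, y, z] <- sum(((c(x, y, z) - soma_c) / soma_r)^2) <= 1
  }
  # soma core (well inside the boundary, beyond the dilation reach) is out
  core <- array(FALSE, shape)
  for (x in 1:48) for (y in 1:48) for (z in 1:24) {
    core[x, y, z] <- sum(((c(x, y, z) - soma_c) / (soma_r - 4))^2) <= 1
  }
  expect_lt(mean(np$mask[core]), 0.05)
  # neuropil fraction within 10% of the geometric complement
  expect_lt(abs(mean(np$mask) - (1 - mean(inside))), 0.10)
  expect_equal(np$neuropil_volume_um3,
               sum(np$mask) * 100 * 100 * 70 / 1e9)
})

test_that("numeric thresholds and degenerate inputs behave", {
  withr::with_seed(2, vol <- array(stats::rnorm(20^3, 2000, 10), c(20, 20, 20)))
  np <- neuropil_mask(vol, threshold = 1000, dilate_radii = c(0, 0, 0),
                      max_hole_voxels = 0)
  expect_true(all(np$mask))
  # with zero dilation and no hole filling the mask is the raw binarization
  np2 <- neuropil_mask(vol, threshold = 2000, dilate_radii = c(0, 0, 0),
                       max_hole_voxels = 0)
  expect_equal(np2$mask, vol > 2000)
  expect_error(neuropil_mask(array(7, c(5, 5, 5))), "no signal")
  expect_error(neuropil_mask(vol, threshold = 1e6), "empty mask")
})

test_that("dilation closes gaps between puncta", {
  vol <- array(0, c(30, 30, 10))
  vol <- arraytomo:::add_gaussian3(vol, c(10, 15, 5), c(1.5, 1.5, 1.4), 5000)
  vol <- arraytomo:::add_gaussian3(vol, c(18, 15, 5), c(1.5, 1.5, 1.4), 5000)
  raw <- neuropil_mask(vol, threshold = 1000, dilate_radii = c(0, 0, 0),
                       max_hole_voxels = 0)
  dil <- neuropil_mask(vol, threshold = 1000, dilate_radii = c(5, 5, 4),
                       max_hole_voxels = 0)
  expect_false(raw$mask[14, 15, 5])
  expect_true(dil$mask[14, 15, 5])
  expect_true(all(dil$mask[raw$mask]))
})

test_that("roi density is puncta count over neuropil volume", {
  # 1 um^3 voxels on a 10 x 10 x 10 grid: 1000 um^3 of neuropil
  mask <- array(TRUE, c(10, 10, 10))
  np <- structure(list(mask = mask, neuropil_volume_um3 = 1000,
                       dilate_radii = c(0, 0, 0), threshold = 0,
                       voxel = voxel_size(1000, 1000, 1000)),
                  class = "neuropil_mask")
  withr::with_seed(3, {
    puncta <- data.frame(x = stats::runif(100, 1, 10),
                         y = stats::runif(100, 1, 10),
                         z = stats::runif(100, 1, 10),
                         total_intensity = stats::runif(100, 1e4, 1e5))
  })
  d <- roi_density(puncta, roi = NULL, neuropil = np)
  expect_equal(d$puncta_count, 100)
  expect_equal(d$density_per_um3, 0.1)
  expect_equal(d$median_total_intensity, stats::median(puncta$total_intensity))
  # restricting the ROI to half the volume keeps only the puncta inside
  half <- array(FALSE, c(10, 10, 10)); half[1:5, , ] <- TRUE
  r <- roi_mask("left-half", half)
  dh <- roi_density(puncta, roi = r, neuropil = np)
  expect_equal(dh$puncta_count, sum(round(puncta$x) <= 5))
  expect_equal(dh$neuropil_volume_um3, 500)
  expect_equal(dh$roi_label, "left-half")
  none <- roi_mask("empty", array(FALSE, c(10, 10, 10)))
  expect_error(roi_density(puncta, none, np), "empty ROI")
})

test_that("doubling the planted marker density doubles the measured density", {
  # the neuropil (synapsin) stays fixed; the counted marker's density is
  # planted through its participation, as in tissue where the total
  # synapse density is constant but a synapse subtype varies
  dens <- vapply(c(0.5, 1), function(part) {
    models <- list(
      "Synapsin1-1" = channel_model("presynaptic", participation = 1),
      "vGluT2-2" = channel_model("presynaptic", participation = part))
    sc <- generate_scene(scene_spec(shape = c(96, 96, 24),
                                    synapse_density = 4, soma_count = 0,
                                    channel_models = models, seed = 40))
    np <- neuropil_mask(get_channel(sc$rendered, "Synapsin1-1"))
    tr <- sc$truth$puncta
    tr <- tr[tr$channel == "vGluT2-2", ]
    puncta <- data.frame(x = tr$x_vox, y = tr$y_vox, z = tr$z_vox,
                         total_intensity = 1)
    roi_density(puncta, roi = NULL, neuropil = np)$density_per_um3
  }, numeric(1))
  # > 500 planted puncta total: Poisson/binomial tolerance 10%
  expect_lt(abs(dens[2] / dens[1] - 2), 0.2)
})

test_that("exact Wilcoxon p-values match full 2^n enumeration", {
  enumerate_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% r
    p_le <- mean(Ws <= W + 1e-9); p_ge <- mean(Ws >= W - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  }
  withr::with_seed(5, {
    for (n in c(5, 8, 12)) {
      for (rep in 1:3) {
        d <- round(stats::rnorm(n, 0.2, 1), 1)  # rounding creates ties
        d <- d[d != 0]
        if (length(d) < 2) next
        got <- exact_wilcoxon_signed_rank(d)
        expect_equal(got$p.value, enumerate_p(d), tolerance = 1e-12)
      }
    }
  })
})

test_that("hallmark n = 7 sign patterns give the published p-values", {
  # all seven pairs in the same direction
  expect_equal(exact_wilcoxon_signed_rank(1:7)$p.value, 0.015625)
  # smallest-rank pair discordant
  d <- c(-1, 2:7)
  expect_equal(exact_wilcoxon_signed_rank(d)$p.value, 0.03125)
})

test_that("the exact test agrees with the reference implementation", {
  withr::with_seed(6, {
    for (rep in 1:5) {
      x <- stats::rnorm(9); y <- stats::rnorm(9)
      # continuous values: no ties or zeros, reference exact test applies
      got <- exact_wilcoxon_signed_rank(x, y)
      want <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
      expect_equal(got$p.value, unname(want$p.value), tolerance = 1e-12)
      expect_equal(unname(got$statistic), unname(want$statistic))
    }
  })
})

test_that("Wilcoxon edge cases behave", {
  expect_error(exact_wilcoxon_signed_rank(c(0, 0, 0)), "degenerate")
  expect_equal(exact_wilcoxon_signed_rank(c(3))$p.value, 1)
  # large n switches to the corrected normal approximation
  withr::with_seed(7, d <- stats::rnorm(40, 0.4))
  big <- exact_wilcoxon_signed_rank(d)
  expect_false(big$exact)
  ref <- stats::wilcox.test(d, correct = TRUE)
  expect_equal(big$p.value, unname(ref$p.value), tolerance = 0.02)
})

test_that("ribbon comparison averages classes and reports differences", {
  results <- data.frame(
    ribbon = rep(paste0("R", 1:7), each = 3),
    class = rep(c("L4", "L4", "L5a"), 7),
    density_per_um3 = c(rbind(seq(2, 2.6, 0.1), seq(2.2, 2.8, 0.1),
                              seq(1, 1.6, 0.1))),
    median_total_intensity = 1)
  cmp <- compare_rois_across_ribbons(results, "L4", "L5a")
  expect_equal(cmp$n, 7)
  expect_equal(cmp$p.value, 0.015625)
  # g1 per ribbon is the mean of the two L4 rows
  expect_equal(cmp$pairs$g1, (seq(2, 2.6, 0.1) + seq(2.2, 2.8, 0.1)) / 2)
  expect_equal(cmp$median_pct_difference,
               stats::median(100 * (cmp$pairs$g1 - cmp$pairs$g2) /
                               cmp$pairs$g1))
  # a ribbon missing one class is excluded with a warning
  broken <- results[!(results$ribbon == "R1" & results$class == "L5a"), ]
  expect_warning(cmp2 <- compare_rois_across_ribbons(broken, "L4", "L5a"),
                 "lacks ROI class")
  expect_equal(cmp2$n, 6)
  one <- results[results$ribbon == "R1", ]
  expect_error(compare_rois_across_ribbons(one, "L4", "L5a"), "at least 2")
})

test_that("a simulated cohort with a planted ratio is detected", {
  cmp <- simulate_density_cohort(n_ribbons = 5, density1 = 5, density2 = 2.5,
                                 shape = c(48, 48, 10), seed = 3)
  expect_equal(cmp$p.value, 2 / 2^5)
  expect_gt(cmp$median_pct_difference, 15)
  expect_error(simulate_density_cohort(density1 = 10, synapse_density = 5),
               "cannot exceed")
})
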