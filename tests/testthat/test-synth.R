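one_channel_models <- function(participation = 1) {
  list("Synapsin1-1" = channel_model("presynaptic",
                                     participation = participation))
}

test_that("the same seed reproduces a scene bit-identically", {
  s1 <- generate_scene(scene_spec(shape = c(48, 48, 8), seed = 11))
  s2 <- generate_scene(scene_spec(shape = c(48, 48, 8), seed = 11))
  s3 <- generate_scene(scene_spec(shape = c(48, 48, 8), seed = 12))
  expect_identical(s1$truth$loci, s2$truth$loci)
  for (nm in names(s1$rendered$channels)) {
    expect_identical(get_channel(s1$rendered, nm)$data,
                     get_channel(s2$rendered, nm)$data)
  }
  expect_false(identical(get_channel(s1$rendered, 1)$data,
                         get_channel(s3$rendered, 1)$data))
})

test_that("locus counts follow the requested Poisson density", {
  # 60 x 60 x 20 voxels at 100 x 100 x 70 nm = 50.4 um^3; density 2/um^3
  counts <- vapply(1:30, function(s) {
    sc <- generate_scene(scene_spec(shape = c(60, 60, 20),
                                    synapse_density = 2, soma_count = 0,
                                    channel_models = one_channel_models(),
                                    seed = 100 + s))
    nrow(sc$truth$loci)
  }, numeric(1))
  expected <- 2 * 60 * 60 * 20 * 100 * 100 * 70 / 1e9
  expect_equal(expected, 100.8)
  # mean of 30 Poisson(100.8) draws: sd ~ 1.83, so +-6 is a 3.3 sigma band
  expect_lt(abs(mean(counts) - expected), 6)
})

test_that("somata exclude synapse loci and shrink the neuropil volume", {
  sc <- generate_scene(scene_spec(shape = c(64, 64, 24), synapse_density = 3,
                                  soma_count = 2, soma_radius_nm = 2000,
                                  channel_models = one_channel_models(),
                                  seed = 21))
  expect_gt(nrow(sc$truth$somata), 0)
  r <- sc$truth$soma_radius_vox
  for (s in seq_len(nrow(sc$truth$somata))) {
    m <- ((sc$truth$loci$x_vox - sc$truth$somata$x[s]) / r[1])^2 +
      ((sc$truth$loci$y_vox - sc$truth$somata$y[s]) / r[2])^2 +
      ((sc$truth$loci$z_vox - sc$truth$somata$z[s]) / r[3])^2
    expect_true(all(m > 1))
  }
  box_um3 <- physical_volume(64, 64, 24)$um3
  expect_lt(sc$truth$neuropil_volume_um3, box_um3)
  # realized density should match the request over the neuropil volume
  expect_lt(abs(nrow(sc$truth$loci) / sc$truth$neuropil_volume_um3 - 3), 1)
})

test_that("participation controls the fraction of loci with a punctum", {
  models <- list("Synapsin1-1" = channel_model("presynaptic", 1),
                 "vGluT2-2" = channel_model("presynaptic", 0.5))
  sc <- generate_scene(scene_spec(shape = c(80, 80, 24), synapse_density = 3,
                                  soma_count = 0, channel_models = models,
                                  seed = 31))
  n <- nrow(sc$truth$loci)
  expect_gt(n, 200)
  pt <- sc$truth$puncta
  expect_equal(sum(pt$channel == "Synapsin1-1"), n)
  frac <- sum(pt$channel == "vGluT2-2") / n
  expect_lt(abs(frac - 0.5), 0.1)
})

test_that("a noiseless punctum renders at its planted position", {
  sc <- generate_scene(scene_spec(shape = c(40, 40, 10),
                                  synapse_density = 0.5, soma_count = 0,
                                  channel_models = one_channel_models(),
                                  baseline = 0, noise_sigma = 0, seed = 41))
  pt <- sc$truth$puncta
  expect_gt(nrow(pt), 0)
  a <- get_channel(sc$rendered, 1)$data
  peak <- which(a == max(a), arr.ind = TRUE)[1, , drop = TRUE]
  err <- sqrt(min((pt$x_vox - peak[1])^2 + (pt$y_vox - peak[2])^2 +
                    (pt$z_vox - peak[3])^2))
  expect_lt(err, 1)
})

test_that("nuclear channels render nuclei at soma centres", {
  sc <- generate_scene(scene_spec(shape = c(64, 64, 24), soma_count = 1,
                                  synapse_density = 0.1, seed = 51,
                                  noise_sigma = 0))
  dapi <- get_channel(sc$rendered, "DAPI-1")$data
  # the nucleus has a flat top, so score the centroid of the plateau;
  # the nucleus may be clipped by the volume in z, so score x and y
  plateau <- which(dapi == max(dapi), arr.ind = TRUE)
  ctr <- as.numeric(sc$truth$somata[1, ])
  expect_lt(abs(mean(plateau[, 1]) - ctr[1]), 2)
  expect_lt(abs(mean(plateau[, 2]) - ctr[2]), 2)
})

test_that("a saturating spec is rejected as degenerate", {
  models <- list("Synapsin1-1" = channel_model(
    "presynaptic", amplitude_mean = 5e5, sigma_nm = c(1500, 1500, 1000)))
  spec <- scene_spec(shape = c(16, 16, 4), synapse_density = 50,
                     soma_count = 0, channel_models = models, seed = 61)
  expect_error(generate_scene(spec), "degenerate")
})

test_that("an identity session transform leaves the data unchanged", {
  sc <- generate_scene(scene_spec(shape = c(48, 48, 6), seed = 71))
  before <- get_channel(sc$rendered, "Synapsin1-1")$data
  sc2 <- apply_session_transform(sc, "Synapsin1-1", rotation = 0,
                                 translation = c(0, 0))
  expect_equal(get_channel(sc2$rendered, "Synapsin1-1")$data, before)
})

test_that("a pure translation is recoverable from the moved sections", {
  sc <- generate_scene(scene_spec(shape = c(64, 64, 4), synapse_density = 2,
                                  soma_count = 0,
                                  channel_models = one_channel_models(),
                                  noise_sigma = 0, seed = 81))
  before <- get_channel(sc$rendered, 1)$data[, , 2]
  sc2 <- apply_session_transform(sc, "Synapsin1-1", translation = c(5, -3))
  after <- get_channel(sc2$rendered, 1)$data[, , 2]
  grid <- expand.grid(du = -8:8, dv = -8:8)
  r <- mapply(function(du, dv) naive_shift_cor(before, after, du, dv),
              grid$du, grid$dv)
  best <- grid[which.max(r), ]
  expect_equal(c(best$du, best$dv), c(5, -3))
})

test_that("session transforms are recorded per channel and section", {
  sc <- generate_scene(scene_spec(shape = c(32, 32, 5), seed = 91))
  sc <- apply_session_transform(sc, c("Synapsin1-1", "PSD95-1"),
                                rotation = 1.0, translation = c(2, 1),
                                per_section_jitter = 0.5, seed = 9)
  tab <- sc$session_transforms
  expect_equal(nrow(tab), 2 * 5)
  expect_true(all(tab$theta == 1.0))
  # both channels of one session share the jitter draws
  expect_equal(tab$dx[tab$channel == "Synapsin1-1"],
               tab$dx[tab$channel == "PSD95-1"])
  expect_error(apply_session_transform(sc, "Gephyrin-9"), "not found")
})

test_that("mosaic tiling covers the section with the documented stride", {
  sec <- matrix(stats::runif(100 * 60), 100, 60)
  m <- tile_mosaic(sec, c(60, 60), overlap_fraction = 0.2)
  # stride ceiling(60 * 0.8) = 48; a flush tile at 40 completes coverage
  expect_equal(m$origins$x0, c(0, 40))
  expect_equal(m$origins$y0, c(0, 0))
  cover <- matrix(0L, 100, 60)
  for (k in seq_len(nrow(m$origins))) {
    expect_equal(m$tiles[[k]],
                 sec[m$origins$x0[k] + 1:60, m$origins$y0[k] + 1:60])
    cover[m$origins$x0[k] + 1:60, m$origins$y0[k] + 1:60] <-
      cover[m$origins$x0[k] + 1:60, m$origins$y0[k] + 1:60] + 1L
  }
  expect_true(all(cover >= 1L))
  expect_error(tile_mosaic(sec, c(60, 60), overlap_fraction = 0.6), "overlap")
  expect_error(tile_mosaic(sec, c(200, 60)), "larger")
})
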