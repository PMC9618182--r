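test_that("noiseless stacks are segmented back to the planted puncta", {
  st <- simulate_image_stack(shape = c(10, 48, 48), n_puncta = c(25, 20),
                             coloc_fraction = 0.5, noise_sd = 0,
                             psf_sigma = 0, seed = 101)
  pa <- segment_puncta(st$channels$A, st$voxel_size)
  pb <- segment_puncta(st$channels$B, st$voxel_size)
  expect_equal(nrow(pa), 25L)
  expect_equal(nrow(pb), 20L)

  # centroids match planted centers within one voxel on every axis
  truth_a <- st$truth[st$truth$channel == "A", ]
  for (i in seq_len(nrow(pa))) {
    dz <- abs(truth_a$z_nm - pa$z_nm[i]) / st$voxel_size[1]
    dy <- abs(truth_a$y_nm - pa$y_nm[i]) / st$voxel_size[2]
    dx <- abs(truth_a$x_nm - pa$x_nm[i]) / st$voxel_size[3]
    expect_lte(min(pmax(dz, pmax(dy, dx))), 1)
  }
  expect_true(all(pa$voxels == 8L))
  expect_true(all(pa$slices == 2L))
})

test_that("background-only and sub-minimum objects yield no puncta", {
  empty <- simulate_image_stack(shape = c(6, 20, 20), n_puncta = c(0, 0),
                                seed = 1)
  expect_equal(nrow(empty$truth), 0L)
  expect_equal(max(empty$channels$A), 0)
  expect_equal(nrow(segment_puncta(empty$channels$A, empty$voxel_size)), 0L)

  # one bright single voxel is removed by the min_voxels = 2 size filter
  speck <- array(0, c(5, 16, 16))
  speck[3, 8, 8] <- 10
  expect_equal(nrow(segment_puncta(speck, min_voxels = 2L)), 0L)
  expect_equal(nrow(segment_puncta(speck, min_voxels = 1L)), 1L)
  expect_error(segment_puncta(array(numeric(0), c(0, 2, 2))), "non-empty")
})

test_that("segmentation is invariant to intensity rescaling", {
  st <- simulate_image_stack(shape = c(8, 40, 40), n_puncta = c(15, 0),
                             noise_sd = 0.05, seed = 7)
  p1 <- segment_puncta(st$channels$A, st$voxel_size)
  p2 <- segment_puncta(st$channels$A * 37.5, st$voxel_size)
  expect_equal(p1, p2)
})

test_that("colocalization recovers the planted opposed fraction", {
  for (cf in c(0, 0.6, 1)) {
    st <- simulate_image_stack(shape = c(12, 64, 64),
                               n_puncta = c(30, 20),
                               coloc_fraction = cf, noise_sd = 0,
                               seed = 55)
    pa <- segment_puncta(st$channels$A, st$voxel_size)
    pb <- segment_puncta(st$channels$B, st$voxel_size)
    frac <- colocalize(pa, pb, max_distance_nm = 500)
    expect_equal(frac, cf, tolerance = 1 / 20 + 1e-9)  # within one punctum
  }

  st <- simulate_image_stack(shape = c(10, 48, 48), n_puncta = c(10, 10),
                             coloc_fraction = 0.5, seed = 3)
  pa <- segment_puncta(st$channels$A, st$voxel_size)
  expect_equal(colocalize(pa, pa), 1.0)  # any list against itself
  expect_equal(colocalize(pa[0, ], pa), 0)
  expect_error(colocalize(pa, pa, max_distance_nm = -1), ">= 0")
})

test_that("density is count over physical volume and scales with depth", {
  # 100 puncta in a 10 x 10 x 10 um volume -> 0.1 per um^3
  fake <- data.frame(id = 1:100)
  expect_equal(puncta_density(fake, shape = c(100, 100, 100),
                              voxel_size = c(100, 100, 100)), 0.1)
  expect_equal(puncta_density(fake[0, ], c(10, 10, 10), c(70, 100, 100)), 0)
  half <- puncta_density(fake, shape = c(50, 100, 100),
                         voxel_size = c(100, 100, 100))
  expect_equal(half, 0.2)
  expect_error(puncta_density(fake, c(0, 10, 10), c(70, 100, 100)),
               "zero analyzed volume")
})

test_that("group percent change is the relative difference of means", {
  expect_equal(group_percent_change(c(1, 1), c(1.27, 1.27)), 27)
  expect_equal(group_percent_change(c(2, 2), c(2, 2)), 0)
  a <- c(0.9, 1.1)
  b <- c(1.2, 1.3)
  expect_equal(group_percent_change(a, b),
               -group_percent_change(b, a) * mean(b) / mean(a))
  expect_error(group_percent_change(numeric(0), 1), "non-empty")
  expect_error(group_percent_change(c(0, 0), c(1, 1)), "zero")
})

test_that("stacks round-trip through multi-page TIFF", {
  st <- simulate_image_stack(shape = c(6, 24, 24), n_puncta = c(8, 5),
                             noise_sd = 0.02, seed = 9)
  dir <- tempfile()
  paths <- write_image_stack(st, dir)
  back <- read_image_stack(file.path(dir, "A.tif"))
  expect_equal(dim(back), dim(st$channels$A))
  # written stack is max-rescaled; segmentation is scale invariant
  expect_equal(segment_puncta(back, st$voxel_size),
               segment_puncta(st$channels$A, st$voxel_size))
})
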