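test_that("mask generation is symmetric, deterministic, and validates shape", {
  for (kind in c("ellipsoid", "two_lobes")) {
    g <- make_mask(c(20, 20, 20), kind)
    expect_gt(sum(g$mask), 0)
    expect_identical(g$mask, g$mask[20:1, , ])  # midsagittal mirror
  }
  expect_identical(make_mask(c(12, 10, 8), "ellipsoid", seed = 5)$mask,
                   make_mask(c(12, 10, 8), "ellipsoid", seed = 5)$mask)
  expect_error(make_mask(c(2, 2, 2)), ">= 8")
})

test_that("tessellation saturates at K = number of masked voxels", {
  g <- make_mask(c(8, 8, 8))
  n <- sum(g$mask)
  parc <- tessellate(g, n, seed = 1)
  expect_identical(parc$K, n)
  expect_true(all(parc$sizes == 1L))
})

test_that("tessellation rejects invalid K", {
  g <- tiny_grid()
  expect_error(tessellate(g, sum(g$mask) + 1L, seed = 1), "exceeds")
  expect_error(tessellate(g, 0, seed = 1), "positive")
})

test_that("assignment matches a brute-force nearest-centroid oracle", {
  # random anisotropic masks; tied voxels must pick a tied centroid
  set.seed(99)
  for (rep in 1:8) {
    dims <- sample(8:14, 3, replace = TRUE)
    mask <- array(runif(prod(dims)) < 0.5, dims)
    mask[1, 1, 1] <- TRUE
    g <- volume_grid(mask, voxel_size = sample(c(1, 2, 3), 3, replace = TRUE))
    K <- sample(5:25, 1)
    parc <- tessellate(g, K, seed = rep)
    vox <- mask_voxels(g)
    orc <- oracle_nearest(vox, parc$centroids_vox, g$voxel_size)
    lab <- parc$labels[vox]
    untied <- orc[, "n_tied"] == 1
    expect_identical(lab[untied], as.integer(orc[untied, "label"]))
    if (any(!untied)) {
      for (v in which(!untied)) {
        d2 <- colSums((t(parc$centroids_vox) - vox[v, ])^2 * g$voxel_size^2)
        expect_equal(d2[lab[v]], min(d2))
      }
    }
  }
})

test_that("labels partition the mask and reruns are bit-identical", {
  g <- tiny_grid()
  p1 <- tessellate(g, 30, seed = 11)
  p2 <- tessellate(g, 30, seed = 11)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$centroids_vox, p2$centroids_vox)
  expect_identical(sum(p1$sizes), sum(g$mask))
  expect_true(all(p1$sizes > 0))
})

test_that("coverage exclusion follows the any-subject rule and re-indexes", {
  parc <- tiny_parc()
  full <- array(TRUE, parc$grid$dims)
  expect_identical(apply_coverage_exclusion(parc, list(full, full))$excluded_ids,
                   integer(0))
  # knock out 3 regions entirely in one subject only
  drop_ids <- c(4L, 9L, 17L)
  cov2 <- full
  cov2[parc$labels %in% drop_ids] <- FALSE
  out <- apply_coverage_exclusion(parc, list(full, cov2), min_fraction = 0.5)
  expect_identical(out$excluded_ids, drop_ids)
  expect_identical(out$K, parc$K - 3L)
  expect_identical(sort(unique(out$labels[out$labels > 0L])), seq_len(out$K))
  # conservation: surviving labels cover exactly the non-excluded voxels
  expect_identical(sum(out$sizes), sum(parc$labels > 0L) - sum(parc$labels %in% drop_ids))
  # vacuous threshold excludes nothing
  none <- array(FALSE, parc$grid$dims)
  expect_identical(apply_coverage_exclusion(parc, list(none), min_fraction = 0)$excluded_ids,
                   integer(0))
  expect_error(apply_coverage_exclusion(parc, list()), "nonempty")
})

test_that("region size stats use the n-1 sd convention", {
  fake <- structure(list(sizes = c(2L, 4L, 6L)), class = "parcellation")
  st <- region_size_stats(fake)
  expect_equal(st$mean, 4)
  expect_equal(st$sd, 2)
  # mean = masked voxels / K for any tessellation
  mask <- array(FALSE, c(10, 10, 10)); mask[1:100] <- TRUE
  parc <- tessellate(volume_grid(mask), 4, seed = 2)
  expect_equal(region_size_stats(parc)$mean, 25)
  eq <- structure(list(sizes = rep(7L, 5)), class = "parcellation")
  expect_equal(region_size_stats(eq)$sd, 0)
})

test_that("contiguity fraction is 1 on convex single-voxel-ish regions", {
  g <- make_mask(c(8, 8, 8))
  parc <- tessellate(g, 3, seed = 4)
  frac <- region_contiguity(parc)
  expect_length(frac, 3)
  expect_true(all(frac > 0 & frac <= 1))
})
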