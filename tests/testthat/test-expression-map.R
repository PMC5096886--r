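mk_samples <- function(values, donor = "d1", hemi = "L", labels = NULL, x = NULL) {
  n <- nrow(values)
  data.frame(donor_id = rep_len(donor, n),
             structure_label = labels %||% sprintf("s%02d", seq_len(n)),
             hemisphere = rep_len(hemi, n),
             x_mm = x %||% rep(-10, n), y_mm = seq_len(n), z_mm = 0,
             values, check.names = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("within-donor normalization centers and scales per probe", {
  probes <- data.frame(probe_id = c("p1", "p2"), gene = "G", qc_pass = TRUE)
  s <- mk_samples(data.frame(p1 = c(1, 2, 3), p2 = c(5, 5, 5)))
  expect_warning(n <- normalize_within_donor(s, probes), "constant probe")
  expect_equal(n$p1, c(-1, 0, 1))
  expect_true(all(is.na(n$p2)))
  # idempotence
  probes1 <- probes[1, ]
  n2 <- normalize_within_donor(n[, names(n) != "p2"], probes1)
  expect_equal(n2$p1, n$p1, tolerance = 1e-12)
  # per donor per probe: mean 0, sd 1 whenever defined
  set.seed(2)
  s3 <- rbind(mk_samples(data.frame(p1 = rnorm(5), p2 = rnorm(5)), donor = "a"),
              mk_samples(data.frame(p1 = rnorm(4), p2 = rnorm(4)), donor = "b"))
  n3 <- normalize_within_donor(s3, probes)
  for (d in c("a", "b")) for (p in c("p1", "p2")) {
    v <- n3[[p]][n3$donor_id == d]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(sd(v) - 1), 1e-10)
  }
  expect_error(normalize_within_donor(s[1, ], probes), "< 2 samples")
})

test_that("mirroring flips x and hemisphere, and never re-mirrors", {
  s <- mk_samples(data.frame(p1 = 1:3), x = c(-30, -5, -12))
  s$y_mm <- c(10, 2, 8); s$z_mm <- c(5, 1, 2)
  m <- mirror_samples(s)
  expect_identical(nrow(m), 6L)
  mir <- m[m$mirrored, ]
  expect_equal(mir$x_mm, c(30, 5, 12))
  expect_true(all(mir$hemisphere == "R"))
  expect_equal(mir$y_mm, s$y_mm)
  # mirroring twice leaves original + one mirror set only
  m2 <- mirror_samples(m)
  expect_identical(nrow(m2), 6L)
})

test_that("region matching equals brute force and applies the tie rule", {
  parc <- tiny_parc()
  set.seed(17)
  n <- 120
  cent <- voxel_to_mm(parc$grid, parc$centroids_vox)
  s <- mk_samples(data.frame(p1 = rnorm(n)),
                  labels = sprintf("lab%03d", sample(40, n, replace = TRUE)),
                  x = runif(n, -15, 15))
  s$y_mm <- runif(n, -15, 15); s$z_mm <- runif(n, -12, 12)
  map <- match_regions(parc, s)
  pos <- as.matrix(s[, c("x_mm", "y_mm", "z_mm")])
  for (i in seq_len(parc$K)) {
    d2 <- colSums((t(pos) - cent[i, ])^2)
    expect_identical(map$sample_row[i], which.min(d2))
    expect_equal(map$distance_mm[i], sqrt(min(d2)))
  }
  # region centroid coinciding with a sample takes that sample's label
  s2 <- s
  s2[1, c("x_mm", "y_mm", "z_mm")] <- cent[3, ]
  expect_identical(match_regions(parc, s2)$structure_label[3], s2$structure_label[1])
  # exact tie: equidistant duplicates -> lowest row index, logged
  s3 <- rbind(s2[1, ], s2[1, ])
  s3$structure_label <- c("first", "second")
  map3 <- match_regions(parc, s3)
  expect_identical(map3$structure_label[3], "first")
  expect_true(3L %in% attr(map3, "ties"))
  expect_error(match_regions(parc, s[0, ]), "empty sample")
})

test_that("aggregation pools QC-passing probes over matching samples", {
  probes <- toy_probes()
  vals <- matrix(0, 3, 6, dimnames = list(NULL, probes$probe_id))
  vals[, "MAPT_probe_1"] <- c(0.7, 0.2, 0.2)
  vals[, "MAPT_probe_2"] <- c(0.7, 0.4, 0.4)
  vals[, "MAPT_probe_3"] <- c(0.7, 0.3, 0.3)
  vals[, "MAPT_probe_4"] <- 99          # must be ignored (qc_fail)
  s <- mk_samples(as.data.frame(vals), labels = c("A", "B", "B"))
  map <- data.frame(region_id = 1:3, structure_label = c("A", "B", "C"),
                    distance_mm = 0, sample_row = 1)
  expect_warning(agg <- aggregate_expression(map, s, probes, "MAPT"), "no matching")
  expect_equal(agg$value[1], 0.7)            # one matching sample, 3 passing probes
  expect_equal(agg$value[2], 0.3)            # mean over 2 samples x 3 probes
  expect_identical(agg$n_samples, c(1L, 2L, 0L))
  expect_true(is.na(agg$value[3]))           # missing, not zero
  expect_identical(attr(agg, "missing_regions"), 3L)
  pp <- attr(agg, "per_probe")
  expect_equal(as.numeric(pp[2, "MAPT_probe_2"]), 0.4)
  expect_identical(colnames(pp),
                   c("MAPT_probe_1", "MAPT_probe_2", "MAPT_probe_3"))
  # invariance to sample ordering
  agg2 <- suppressWarnings(aggregate_expression(map, s[3:1, ], probes, "MAPT"))
  expect_equal(agg2$value, agg$value)
  expect_error(aggregate_expression(map, s, probes, "NOPE"), "no QC-passing")
})

test_that("inter-donor variability uses donor means with the n-1 sd", {
  probes <- data.frame(probe_id = "p1", gene = "G", qc_pass = TRUE)
  s <- rbind(mk_samples(data.frame(p1 = c(-0.5, 1)), donor = "a", labels = c("A", "B")),
             mk_samples(data.frame(p1 = c(0.5, 1)), donor = "b", labels = c("A", "B")),
             mk_samples(data.frame(p1 = 2), donor = "c", labels = "B"))
  map <- data.frame(region_id = 1:3, structure_label = c("A", "B", "Z"),
                    distance_mm = 0, sample_row = 1)
  iv <- interdonor_variability(map, s, probes, "G")
  expect_equal(iv$sd_across_donors[1], sd(c(-0.5, 0.5)))      # ~0.7071
  expect_equal(iv$sd_across_donors[2], sd(c(1, 1, 2)))        # donor c included
  expect_identical(iv$n_donors, c(2L, 3L, 0L))
  # identical donors: sd 0
  s0 <- rbind(mk_samples(data.frame(p1 = 0.3), donor = "a", labels = "A"),
              mk_samples(data.frame(p1 = 0.3), donor = "b", labels = "A"))
  expect_equal(interdonor_variability(map[1, ], s0, probes, "G")$sd_across_donors, 0)
  # single-donor regions flagged, not reported
  expect_true(is.na(interdonor_variability(map[1, ], s0[1, ], probes, "G")$sd_across_donors))
})

test_that("symmetry test returns the clipped z for identical hemispheres", {
  set.seed(5)
  n_struct <- 12; n_probe <- 110
  vals <- matrix(rnorm(n_struct * n_probe), n_struct, n_probe,
                 dimnames = list(NULL, sprintf("p%03d", seq_len(n_probe))))
  probes <- data.frame(probe_id = colnames(vals), gene = colnames(vals),
                       qc_pass = TRUE)
  labs <- sprintf("s%02d", seq_len(n_struct))
  sl <- mk_samples(as.data.frame(vals), labels = labs, hemi = "L")
  sr <- mk_samples(as.data.frame(vals), labels = labs, hemi = "R",
                   x = rep(10, n_struct))
  res <- interhemispheric_symmetry_test(rbind(sl, sr), probes,
                                        n_random_pairs = 1200, seed = 3)
  expect_length(res, 1)
  r1 <- res[[1]]
  expect_equal(r1$observed_mean_z, atanh(1 - 1e-6))
  expect_lt(r1$p_value, 0.05)
  expect_gt(r1$p_value, 0)
  expect_identical(length(r1$per_pair_z), as.integer(n_struct))
  # too few probes is an error
  expect_error(interhemispheric_symmetry_test(rbind(sl, sr), probes[1:20, ]),
               ">= 100 probes")
  # donor without both hemispheres is an error
  expect_error(interhemispheric_symmetry_test(sl, probes), "both hemispheres")
})
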