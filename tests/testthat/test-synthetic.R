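test_that("scenario validates its invariants", {
  expect_error(scenario(n_timepoints = 32), ">= 64")
  expect_error(scenario(repetition_time = 0), "> 0")
  expect_error(scenario(single_hemisphere_donors = 7, n_donors = 6), "exceeds")
  expect_error(scenario(genes = c(MAPT = 1L)), ">= 2 probes")
})

test_that("ground truth honors its invariants and is seed-determined", {
  gt <- tiny_gt()
  expect_gt(length(gt$hub_region_ids), 0)
  expect_true(all(gt$attenuation_map >= 0 & gt$attenuation_map <= 1))
  expect_identical(gt$seeds$ground_truth, 7L)
  gt2 <- ground_truth(tiny_parc(), tiny_scen(), seed = 7)
  expect_identical(gt, gt2)
  expect_error(ground_truth(tiny_parc(), tiny_scen(), 1,
                            attenuation_max = c(PD = 1.2)), "\\[0,1\\]")
})

test_that("the planted expression-strength correlation is exact at the population level", {
  gt <- tiny_gt()
  expect_equal(cor(gt$expression_profiles[, 1], gt$expected_strength[, "control"]),
               gt$expression_strength_corr, tolerance = 1e-10)
  # second gene profile standardized, not strength-coupled by construction
  expect_equal(sd(gt$expression_profiles[, 2]), 1, tolerance = 1e-10)
  # profiles are symmetric across mirror pairs
  paired <- which(!is.na(gt$mirror_pair))
  expect_equal(gt$expression_profiles[paired, 1],
               gt$expression_profiles[gt$mirror_pair[paired], 1])
})

test_that("planted hubs dominate expected covariance row sums", {
  gt <- tiny_gt()
  s <- gt$expected_strength[, "control"]
  top_decile <- order(s, decreasing = TRUE)[seq_len(ceiling(0.1 * length(s)))]
  expect_true(all(gt$hub_region_ids %in% top_decile))
  # and clear the mean + 1.5 sd hub threshold in expectation
  expect_true(all(s[gt$hub_region_ids] > mean(s) + 1.5 * sd(s)))
})

test_that("BOLD simulation is deterministic, group-checked, and identity at zero attenuation", {
  parc <- tiny_parc(); scen <- tiny_scen(); gt <- tiny_gt()
  expect_error(simulate_bold(parc, scen, "HD", gt, 1), "unknown group")
  a <- simulate_bold(parc, scen, "control", gt, seed = 5, voxelwise = FALSE)
  b <- simulate_bold(parc, scen, "control", gt, seed = 5, voxelwise = FALSE)
  expect_identical(a$series, b$series)
  expect_identical(a$motion, b$motion)
  # zero attenuation: disease generation coincides with control exactly
  gt0 <- ground_truth(parc, scen, seed = 7, attenuation_max = c(PD = 0, PSP = 0))
  c1 <- simulate_bold(parc, scen, "control", gt0, seed = 5, voxelwise = FALSE)
  d1 <- simulate_bold(parc, scen, "PD", gt0, seed = 5, voxelwise = FALSE)
  expect_identical(unclass(c1$series), unclass(d1$series))
})

test_that("voxelwise volumes embed the region signals", {
  parc <- tiny_parc()
  scen <- scenario(n_regions = 40, n_timepoints = 64,
                   noise_sd = list(signal = 2, voxel = 0, expression = 0.3,
                                   donor_offset = 0.5, probe_offset = 0.3))
  sim <- simulate_bold(parc, scen, "control", tiny_gt(), seed = 9, voxelwise = TRUE)
  ts <- extract_timeseries(sim$bold, parc, n_discard = 0)
  expect_equal(unclass(ts), unclass(sim$series), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(attr(sim$bold, "repetition_time"), 2)
})

test_that("donor sampling matches the stated hemisphere design", {
  parc <- tiny_parc(); scen <- tiny_scen(); gt <- tiny_gt()
  expr <- simulate_expression(parc, scen, gt, seed = 21)
  hemi_per_donor <- tapply(expr$samples$hemisphere, expr$samples$donor_id,
                           function(h) length(unique(h)))
  expect_identical(sum(hemi_per_donor == 2L), 2L)  # 2 of 6 donors span both
  expect_identical(sum(hemi_per_donor == 1L), 4L)
  # probe annotation: 4 tau-like probes with 1 QC failure leaves 3
  expect_identical(sum(expr$probes$gene == "MAPT"), 4L)
  expect_identical(sum(expr$probes$gene == "MAPT" & expr$probes$qc_pass), 3L)
})

test_that("zero noise and offsets make donors agree after normalization", {
  parc <- tiny_parc()
  scen <- scenario(n_regions = 40, n_timepoints = 150,
                   single_hemisphere_donors = 0L,
                   noise_sd = list(signal = 2, voxel = 1, expression = 0,
                                   donor_offset = 0, probe_offset = 0))
  gt <- ground_truth(parc, scen, seed = 7)
  expr <- simulate_expression(parc, scen, gt, seed = 3, sample_fraction = 1,
                              jitter_sd = 0)
  norm <- normalize_within_donor(expr$samples, expr$probes)
  # same regions sampled by every donor: normalized values identical per region
  probe <- "MAPT_probe_1"
  byreg <- split(norm[[probe]], norm$structure_label)
  expect_true(all(vapply(byreg, function(v) diff(range(v)) < 1e-10, logical(1))))
})

test_that("behaviour generator hits intercepts, means, and recoverable slope", {
  gt <- tiny_gt()
  n <- 30
  grp <- rep(c("control", "PD", "PSP"), each = 10)
  hs <- rnorm(n, mean = rep(vapply(c("control", "PD", "PSP"), function(g)
    mean(gt$expected_strength[gt$hub_region_ids, g]), numeric(1)), each = 10))
  zero_sd <- c(control = 0, PD = 0, PSP = 0)
  # slope 0, noise 0: fluency equals the group intercept exactly
  beh0 <- simulate_behaviour(hs, grp, gt, seed = 1, slope = 0, noise_sd = zero_sd)
  expect_equal(unique(beh0$fluency[grp == "control"]), 40.3)
  means <- tapply(beh0$fluency, beh0$group, mean)
  expect_equal(as.numeric(means[c("control", "PD", "PSP")]), c(40.3, 34.3, 14.1))
  # least squares on generator output recovers the slope as noise -> 0
  behs <- simulate_behaviour(hs, grp, gt, seed = 2,
                             noise_sd = c(control = 1e-6, PD = 1e-6, PSP = 1e-6))
  fit <- lm(fluency ~ group + hs, data = data.frame(behs, hs = hs))
  expect_equal(unname(coef(fit)["hs"]), gt$fluency_slope, tolerance = 1e-3)
  # motor score carries no hub-strength signal (slope consistent with 0)
  beh <- simulate_behaviour(hs, grp, gt, seed = 3)
  fitu <- lm(updrs ~ group + hs, data = data.frame(beh, hs = hs))
  expect_gt(summary(fitu)$coefficients["hs", "Pr(>|t|)"], 0.01)
})

test_that("ground-truth serialization fully determines regeneration", {
  tmp <- withr::local_tempdir()
  parc <- tiny_parc(); scen <- tiny_scen(); gt <- tiny_gt()
  p <- file.path(tmp, "gt.json")
  write_ground_truth(gt, scen, p)
  back <- read_ground_truth(p, parc)
  expect_identical(back$gt, gt)
  expect_equal(unclass(back$scenario), unclass(scen))
})

test_that("generator outputs round-trip through the io module", {
  tmp <- withr::local_tempdir()
  parc <- tiny_parc(); scen <- tiny_scen(); gt <- tiny_gt()
  expr <- simulate_expression(parc, scen, gt, seed = 33)
  write_tsv(expr$samples, file.path(tmp, "s.tsv"))
  back <- read_tsv(file.path(tmp, "s.tsv"))
  for (cc in names(expr$samples)) expect_identical(back[[cc]], expr$samples[[cc]])
  sim <- simulate_bold(parc, scen, "control", gt, seed = 44, voxelwise = FALSE)
  write_motion(sim$motion, file.path(tmp, "m.tsv"))
  mb <- read_motion(file.path(tmp, "m.tsv"), repetition_time = 2)
  expect_identical(mb$translations, unname(sim$motion$translations))
  expect_identical(mb$rotations, unname(sim$motion$rotations))
})

test_that("zero attenuation with matched seeds gives matching group mean matrices", {
  parc <- tiny_parc()
  scen <- scenario(n_regions = 40, n_timepoints = 1024)
  gt0 <- ground_truth(parc, scen, seed = 7, attenuation_max = c(PD = 0, PSP = 0))
  mats_c <- lapply(1:3, function(i) build_association_matrix(
    simulate_bold(parc, scen, "control", gt0, seed = i, voxelwise = FALSE)$series))
  mats_d <- lapply(1:3, function(i) build_association_matrix(
    simulate_bold(parc, scen, "PD", gt0, seed = i, voxelwise = FALSE)$series))
  diffm <- abs(unclass(group_mean_matrix(mats_c)) - unclass(group_mean_matrix(mats_d)))
  expect_lt(mean(diffm[upper.tri(diffm)]), 1e-12)  # identical seeds: exact
})
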