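mk_assoc <- function(z) {
  structure(z, region_ids = seq_len(nrow(z)),
            class = c("assoc_matrix", "matrix", "array"))
}

test_that("connection strength is the signed off-diagonal row sum", {
  z <- matrix(0, 3, 3)
  z[1, 2] <- z[2, 1] <- 0.5
  z[1, 3] <- z[3, 1] <- -0.2
  z[2, 3] <- z[3, 2] <- 0.1
  expect_equal(unname(connection_strength(mk_assoc(z))), c(0.3, 0.6, -0.1))
  expect_equal(unname(connection_strength(mk_assoc(matrix(0, 4, 4)))), rep(0, 4))
  perm <- c(3, 1, 2)
  expect_equal(unname(connection_strength(mk_assoc(z[perm, perm]))),
               unname(connection_strength(mk_assoc(z)))[perm])
})

test_that("hub definition uses mean + k sd with strict inequality", {
  s <- c(1, 1, 1, 1, 10)
  h <- define_hubs(s)
  expect_equal(h$threshold, mean(s) + 1.5 * sd(s))  # ~8.84, n-1 sd
  expect_identical(h$hub_ids, 5L)
  expect_warning(h0 <- define_hubs(rep(2, 6)), "zero strength sd")
  expect_identical(h0$hub_ids, integer(0))
  hk0 <- define_hubs(c(1, 2, 3, 4), k = 0)
  expect_identical(hk0$hub_ids, which(c(1, 2, 3, 4) > 2.5))
  expect_error(define_hubs(c(1, 2)), ">= 3 regions")
})

test_that("proportional loss is normalized by control strength and excludes s<=0", {
  pl <- proportional_loss(c(2, 1, -0.1, 3), c(1.5, 1, 5, 0), "PD")
  expect_equal(unname(pl$loss), c(0.25, 0, 1))
  expect_identical(pl$excluded_regions, 3L)
  expect_equal(unname(proportional_loss(c(2), c(2))$loss), 0)
})

test_that("mean hub strength averages hub rows and ignores non-hub edits", {
  z <- matrix(0.1, 5, 5); diag(z) <- 0
  m <- mk_assoc(z)
  hubs <- list(hub_ids = c(1L, 2L))
  s <- connection_strength(m)
  expect_equal(mean_hub_strength(m, hubs), mean(s[1:2]))
  expect_equal(mean_hub_strength(m, list(hub_ids = 3L)), s[[3]])
  # editing an edge between two non-hub regions leaves hub strengths unchanged
  z2 <- z; z2[4, 5] <- z2[5, 4] <- 0.9
  expect_equal(mean_hub_strength(mk_assoc(z2), hubs), mean_hub_strength(m, hubs))
  expect_error(mean_hub_strength(m, list(hub_ids = integer(0))), "empty hub set")
})

test_that("permutation Pearson p has the add-one form and exact edge cases", {
  set.seed(6)
  x <- rnorm(30)
  res <- pearson_permutation(x, x, n_perm = 200, seed = 1)
  expect_equal(res$p_value, 1 / 201)   # maximal statistic
  expect_equal(res$statistic, 1)
  expect_error(pearson_permutation(x, rep(1, 30)), "zero variance")
  expect_error(pearson_permutation(x[1:4], x[1:4]), ">= 5")
  # reproducible given seed
  y <- rnorm(30)
  expect_identical(pearson_permutation(x, y, 300, seed = 9),
                   pearson_permutation(x, y, 300, seed = 9))
})

test_that("fdr_bh and bonferroni match brute-force oracles", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  set.seed(12)
  for (len in c(1:6, 12)) {
    for (rep in 1:20) {
      p <- runif(len)^sample(c(1, 2, 4), 1)
      expect_equal(fdr_bh(p), oracle_bh(p), tolerance = 1e-14)
      expect_true(all(fdr_bh(p) >= p))
      m <- len + sample(0:3, 1)
      expect_equal(bonferroni(p, m), oracle_bonferroni(p, m), tolerance = 1e-14)
    }
  }
  expect_equal(bonferroni(0.0007, 2), 0.0014)
  expect_equal(bonferroni(0.6, 2), 1)
  expect_equal(bonferroni(c(0.1, 0.5), m = 2), c(0.2, 1.0))
  expect_identical(bonferroni(0.3, 1), 0.3)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), ">=")
})

test_that("groupwise test is antisymmetric and quiet under the null", {
  set.seed(3)
  a <- matrix(rnorm(6 * 20), 6, 20)
  b <- matrix(rnorm(6 * 20), 6, 20)
  r1 <- groupwise_strength_test(a, b, n_perm = 300, seed = 4)
  r2 <- groupwise_strength_test(b, a, n_perm = 300, seed = 4)
  expect_equal(r1$t, -r2$t, tolerance = 1e-12)
  expect_lt(mean(r1$p_fdr < 0.05), 0.05)  # identical distributions: ~no hits
  expect_error(groupwise_strength_test(a[1, , drop = FALSE], b), ">= 2 subjects")
})

test_that("planted attenuation enriches hubs among significant regions", {
  parc <- tiny_parc(); gt <- tiny_gt()
  scen <- scenario(n_regions = 40, n_subjects_per_group = 8, n_timepoints = 256)
  ors <- vapply(1:10, function(rep) {
    sa <- t(vapply(1:8, function(i) connection_strength(build_association_matrix(
      simulate_bold(parc, scen, "control", gt, seed = derive_seed(rep, "c", i),
                    voxelwise = FALSE)$series)), numeric(parc$K)))
    sb <- t(vapply(1:8, function(i) connection_strength(build_association_matrix(
      simulate_bold(parc, scen, "PSP", gt, seed = derive_seed(rep, "p", i),
                    voxelwise = FALSE)$series)), numeric(parc$K)))
    res <- groupwise_strength_test(sa, sb, n_perm = 300, seed = rep)
    sig <- res$p_fdr < 0.05
    hub <- seq_len(parc$K) %in% gt$hub_region_ids
    (sum(sig & hub) + 0.5) * (sum(!sig & !hub) + 0.5) /
      ((sum(sig & !hub) + 0.5) * (sum(!sig & hub) + 0.5))
  }, numeric(1))
  expect_gte(mean(ors > 1), 0.9)
})

test_that("fluency covariance model recovers planted structure and detects degeneracy", {
  set.seed(8)
  n <- 20
  grp <- rep(c("control", "PD", "PSP"), each = n)
  hs <- rnorm(3 * n, mean = rep(c(20, 16, 12), each = n), sd = 2)
  flu <- c(40, 34, 14)[as.integer(factor(grp))] + 1.5 * (hs - rep(c(20, 16, 12), each = n)) +
    rnorm(3 * n, sd = 2)
  res <- fluency_covariance(hs, flu, grp, n_perm = 300, seed = 2)
  expect_lt(res$main$p, 0.05)
  expect_true(all(res$per_group$r > 0))
  expect_equal(res$slope, 1.5, tolerance = 0.3)
  # constant fluency within groups: F ~ 0 for the strength term
  flu0 <- c(40, 34, 14)[as.integer(factor(grp))]
  res0 <- fluency_covariance(hs, flu0, grp, n_perm = 50, seed = 3, posthoc = FALSE)
  expect_lt(res0$main$F, 0.1)
  # collinear strength (constant) is a named rank-deficiency error
  expect_error(fluency_covariance(rep(1, 3 * n), flu, grp, n_perm = 50, seed = 1),
               "rank-deficient")
  expect_error(fluency_covariance(hs[1:10], flu[1:10], grp[1:10]), ">= 2 groups|>= 5")
})
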