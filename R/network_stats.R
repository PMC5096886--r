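# Connection strength, hubs, proportional loss, and the inferential
# statistics: permutation Pearson tests, BH-FDR, Bonferroni, groupwise
# permutation t-tests and the fluency covariance model.

#' Connection strength (weighted degree)
#'
#' `s_i = sum_{j != i} z_ij`, signed: negative weights are retained, the
#' diagonal is excluded.
#'
#' @param matrix an `assoc_matrix` (or plain symmetric matrix, diagonal
#'   ignored).
#' @return named numeric vector over regions.
#' @export
connection_strength <- function(matrix) {
  m <- unclass(matrix)
  diag(m) <- 0
  stats::setNames(rowSums(m), attr(matrix, "region_ids") %||% seq_len(nrow(m)))
}

#' Define hub regions
#'
#' Hubs are regions whose connection strength strictly exceeds
#' `mean(s) + k * sd(s)` (n-1 sd), computed on the reference group's
#' strengths (the control group in the emulated analysis).
#'
#' @param strengths strength vector (reference group).
#' @param k sd multiplier (default 1.5).
#' @param reference_group label recorded on the result.
#' @return list of class `hub_set`: `hub_ids`, `threshold`, `k`,
#'   `reference_group`.
#' @export
define_hubs <- function(strengths, k = 1.5, reference_group = "control") {
  if (length(strengths) < 3L) stop_hv("need >= 3 regions to define hubs")
  s <- sd_n1(strengths)
  if (s == 0) {
    warn_hv("zero strength sd: empty hub set")
    theta <- mean(strengths)
    return(structure(list(hub_ids = integer(0), threshold = theta, k = k,
                          reference_group = reference_group), class = "hub_set"))
  }
  theta <- mean(strengths) + k * s
  ids <- names(strengths) %||% as.character(seq_along(strengths))
  structure(list(hub_ids = which(strengths > theta),
                 threshold = theta, k = k,
                 reference_group = reference_group),
            class = "hub_set")
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("hub_set: %d hubs above threshold %.3f (mean + %.1f sd, %s group)\n",
              length(x$hub_ids), x$threshold, x$k, x$reference_group))
  invisible(x)
}

#' Proportional connectivity loss
#'
#' `L_i = (s_i^ctrl - s_i^dis) / s_i^ctrl`, defined only where the control
#' strength is strictly positive; other regions are excluded (reported, not
#' an error) because the ratio flips sign there.
#'
#' @param ctrl,dis strength vectors on the same regions.
#' @param disease_group label recorded on the result.
#' @return list of class `proportional_loss`: `loss` (named vector over
#'   retained regions), `excluded_regions`, `disease_group`.
#' @export
proportional_loss <- function(ctrl, dis, disease_group = "disease") {
  if (length(ctrl) != length(dis)) stop_hv("strength vectors differ in length")
  ok <- ctrl > 0
  structure(list(loss = (ctrl[ok] - dis[ok]) / ctrl[ok],
                 excluded_regions = which(!ok),
                 disease_group = disease_group),
            class = "proportional_loss")
}

#' Mean strength over hub regions for one subject
#'
#' @param matrix the subject's `assoc_matrix` (same regions as the hub set's
#'   reference matrix).
#' @param hubs a [define_hubs()] result.
#' @return scalar mean of the subject's strengths over the hub ids.
#' @export
mean_hub_strength <- function(matrix, hubs) {
  if (!length(hubs$hub_ids)) stop_hv("empty hub set")
  s <- connection_strength(matrix)
  mean(s[hubs$hub_ids])
}

#' Permutation test for a Pearson correlation
#'
#' Observed `r = cor(x, y)`; the null is built by permuting `y`;
#' `p = (#{|r_perm| >= |r_obs|} + 1) / (n_perm + 1)` (two-sided; the add-one
#' form keeps p in (0, 1]).
#'
#' @param x,y equal-length numeric vectors (n >= 5).
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @return list of class `perm_test`: `statistic` (r), `n_permutations`,
#'   `p_value`, `seed`.
#' @export
pearson_permutation <- function(x, y, n_perm = 5000L, seed = 1L) {
  if (length(x) != length(y)) stop_hv("x and y differ in length")
  if (length(x) < 5L) stop_hv("need >= 5 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_hv("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop_hv("zero variance in x or y")
  r_obs <- stats::cor(x, y)
  xs <- as.numeric(scale(x))
  ys <- as.numeric(scale(y))
  n <- length(x)
  p <- with_seed(seed, {
    b <- 0L
    for (i in seq_len(n_perm)) {
      r_perm <- sum(xs * ys[sample.int(n)]) / (n - 1)
      if (abs(r_perm) >= abs(r_obs) - 1e-12) b <- b + 1L
    }
    (b + 1) / (n_perm + 1)
  })
  structure(list(statistic = r_obs, n_permutations = as.integer(n_perm),
                 p_value = p, seed = as.integer(seed)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: statistic = %.4f, p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `p_(i) * m / i`, cumulative minimum from the
#' largest rank down, capped at 1.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return adjusted p-values in the original order.
#' @export
fdr_bh <- function(p_values) {
  m <- length(p_values)
  if (!m) return(numeric(0))
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
}

#' Bonferroni adjustment
#'
#' @param p_values vector of p-values.
#' @param m number of comparisons (>= number of tests; default the length).
#' @return `min(1, p * m)` elementwise.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stop_hv("m must be >= number of tests")
  pmin(1, p_values * m)
}

#' Groupwise per-region strength difference test
#'
#' Per region, a Welch t statistic between the two groups' per-subject
#' strengths; p-values from group-label permutation (two-sided, add-one
#' form); BH-FDR across regions. Regions with degenerate variance in both
#' groups are skipped and logged.
#'
#' @param strengths_a,strengths_b subjects x regions matrices of per-subject
#'   strengths for the two groups.
#' @param n_perm permutations (default 5000).
#' @param seed integer seed.
#' @return data.frame: `region`, `t`, `p_value`, `p_fdr`; attribute
#'   `skipped_regions`.
#' @export
groupwise_strength_test <- function(strengths_a, strengths_b,
                                    n_perm = 5000L, seed = 1L) {
  strengths_a <- as.matrix(strengths_a); strengths_b <- as.matrix(strengths_b)
  if (ncol(strengths_a) != ncol(strengths_b)) stop_hv("region counts differ")
  if (nrow(strengths_a) < 2L || nrow(strengths_b) < 2L) stop_hv("need >= 2 subjects per group")
  R <- ncol(strengths_a)
  na <- nrow(strengths_a); nb <- nrow(strengths_b)
  welch_t <- function(xa, xb) {
    va <- apply(xa, 2, stats::var) / nrow(xa)
    vb <- apply(xb, 2, stats::var) / nrow(xb)
    (colMeans(xa) - colMeans(xb)) / sqrt(va + vb)
  }
  t_obs <- welch_t(strengths_a, strengths_b)
  skipped <- which(!is.finite(t_obs))
  pooled <- rbind(strengths_a, strengths_b)
  exceed <- integer(R)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      idx <- sample.int(na + nb)
      t_perm <- welch_t(pooled[idx[seq_len(na)], , drop = FALSE],
                        pooled[idx[na + seq_len(nb)], , drop = FALSE])
      exceed <- exceed + (abs(t_perm) >= abs(t_obs) - 1e-12)
    }
  })
  p <- (exceed + 1) / (n_perm + 1)
  p[skipped] <- NA_real_
  keep <- setdiff(seq_len(R), skipped)
  p_fdr <- rep(NA_real_, R)
  p_fdr[keep] <- fdr_bh(p[keep])
  structure(data.frame(region = seq_len(R), t = t_obs, p_value = p, p_fdr = p_fdr),
            skipped_regions = skipped)
}

#' Fluency covariance analysis
#'
#' Linear model `fluency ~ group + hub_strength` tested against
#' `fluency ~ group` (main effect of strength, type-II F), and
#' `fluency ~ group * hub_strength` against the additive model (interaction
#' F); per-group Pearson r with permutation p as post hoc.
#'
#' @param hub_strength per-subject mean hub strength.
#' @param fluency per-subject verbal fluency score.
#' @param groups per-subject group labels.
#' @param n_perm permutations for the post hoc tests.
#' @param seed integer seed.
#' @param posthoc compute the per-group permutation correlations (default
#'   `TRUE`; disable inside calibration loops).
#' @return list of class `fluency_anova`: `main` (F, df, p), `interaction`
#'   (F, df, p), `per_group` (data.frame of r and permutation p),
#'   `slope` (fitted common slope).
#' @export
fluency_covariance <- function(hub_strength, fluency, groups,
                               n_perm = 5000L, seed = 1L, posthoc = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_hv("need >= 2 groups")
  if (any(table(groups) < 5L)) stop_hv("need >= 5 subjects per group")
  dat <- data.frame(fluency = fluency, s = hub_strength, group = groups)
  f0 <- stats::lm(fluency ~ group, dat)
  f1 <- stats::lm(fluency ~ group + s, dat)
  f2 <- stats::lm(fluency ~ group * s, dat)
  if (any(is.na(stats::coef(f2)))) {
    bad <- names(which(is.na(stats::coef(f2))))
    stop_hv("rank-deficient model; collinear term(s): %s", paste(bad, collapse = ","))
  }
  a_main <- stats::anova(f0, f1)
  a_int <- stats::anova(f1, f2)
  per_group <- if (!posthoc) NULL else do.call(rbind, lapply(levels(groups), function(g) {
    idx <- groups == g
    pt <- pearson_permutation(hub_strength[idx], fluency[idx],
                              n_perm = n_perm, seed = derive_seed(seed, "posthoc", g))
    data.frame(group = g, r = pt$statistic, p_value = pt$p_value,
               df = sum(idx) - 2L)
  }))
  structure(list(main = list(F = a_main$F[2], df = a_main$Df[2],
                             p = a_main$`Pr(>F)`[2]),
                 interaction = list(F = a_int$F[2], df = a_int$Df[2],
                                    p = a_int$`Pr(>F)`[2]),
                 per_group = per_group,
                 slope = unname(stats::coef(f1)["s"])),
            class = "fluency_anova")
}

#' @export
print.fluency_anova <- function(x, ...) {
  cat(sprintf("fluency ~ group + hub strength: F = %.2f, df = %d, p = %.4g\n",
              x$main$F, x$main$df, x$main$p))
  cat(sprintf("interaction: F = %.2f, df = %d, p = %.4g\n",
              x$interaction$F, x$interaction$df, x$interaction$p))
  print(x$per_group, row.names = FALSE)
  invisible(x)
}
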