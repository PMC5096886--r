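# Synthetic-data generator: emulates the statistical structure the analysis
# assumes (hub-structured band-limited connectivity, expression-coupled
# attenuation in disease, donor expression sampling with hemispheric
# asymmetry of coverage) and records the planted ground truth for recovery
# tests.

#' Scenario settings for the synthetic study
#'
#' Defaults emulate the source study's stated conditions: 3 diagnostic
#' groups, TR = 2 s, at least 145 analyzed volumes (150 acquired, 5
#' discarded), 6 expression donors of which 4 carry left-hemisphere samples
#' only, and multiple probes per gene (4 for the tau-like gene, one of which
#' fails probe QC, leaving 3; 2 for the synuclein-like gene).
#'
#' @param n_regions regions in the parcellation.
#' @param n_subjects_per_group subjects per diagnostic group.
#' @param n_timepoints acquired volumes (>= 64).
#' @param repetition_time TR, seconds.
#' @param n_donors expression donors.
#' @param single_hemisphere_donors donors with left-hemisphere-only samples.
#' @param genes named integer vector: probes per gene.
#' @param qc_fail named integer vector: probes per gene flagged as failing
#'   probe QC (consumed, not computed, by the pipeline).
#' @param noise_sd list of noise scales: `signal` (white voxel/region noise
#'   sd, so in-band variance at level 2 is `signal^2/4`), `voxel` (extra
#'   voxel-level sd), `expression` (per-sample expression sd),
#'   `donor_offset`, `probe_offset` (additive offset sds).
#' @return object of class `scenario`.
#' @export
scenario <- function(n_regions = 100L,
                     n_subjects_per_group = 20L,
                     n_timepoints = 150L,
                     repetition_time = 2,
                     n_donors = 6L,
                     single_hemisphere_donors = 4L,
                     genes = c(MAPT = 4L, SNCA = 2L),
                     qc_fail = c(MAPT = 1L, SNCA = 0L),
                     noise_sd = list(signal = 2, voxel = 1, expression = 0.3,
                                     donor_offset = 0.5, probe_offset = 0.3)) {
  if (n_timepoints < 64L) stop_hv("n_timepoints must be >= 64")
  if (repetition_time <= 0) stop_hv("repetition_time must be > 0")
  if (single_hemisphere_donors > n_donors) stop_hv("single_hemisphere_donors exceeds n_donors")
  if (any(genes < 2L)) stop_hv("each gene needs >= 2 probes")
  structure(list(n_regions = as.integer(n_regions),
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_timepoints = as.integer(n_timepoints),
                 repetition_time = repetition_time,
                 n_donors = as.integer(n_donors),
                 single_hemisphere_donors = as.integer(single_hemisphere_donors),
                 genes = genes, qc_fail = qc_fail,
                 noise_sd = noise_sd),
            class = "scenario")
}

# Pair each left-hemisphere region with the right-hemisphere region whose
# centroid is nearest the mirrored position; paired regions share a
# structure label (greedy, left regions in centroid order).
.mirror_pairs <- function(parc) {
  mm <- voxel_to_mm(parc$grid, parc$centroids_vox)
  side <- ifelse(mm[, 1] < 0, "L", "R")
  left <- which(side == "L"); right <- which(side == "R")
  pair <- rep(NA_integer_, parc$K)
  used <- logical(length(right))
  for (i in left) {
    if (!length(right)) break
    tgt <- c(-mm[i, 1], mm[i, 2], mm[i, 3])
    d2 <- colSums((t(mm[right, , drop = FALSE]) - tgt)^2)
    d2[used] <- Inf
    j <- which.min(d2)
    if (is.finite(d2[j])) {
      pair[i] <- right[j]; pair[right[j]] <- i
      used[j] <- TRUE
    }
  }
  struct <- integer(parc$K); nxt <- 0L
  for (i in seq_len(parc$K)) {
    if (struct[i] > 0L) next
    nxt <- nxt + 1L
    struct[i] <- nxt
    if (!is.na(pair[i])) struct[pair[i]] <- nxt
  }
  list(pair = pair, structure = sprintf("struct_%03d", struct),
       structure_id = struct, hemisphere = side)
}

#' Plant the ground truth for a synthetic study
#'
#' Connectivity follows a low-rank factor model (chosen because it
#' guarantees a positive semidefinite covariance): regions are grouped into
#' `n_modules` modules, each non-hub region loading `module_loading` on its
#' module's band-limited factor; hub regions load `hub_loading` on every
#' factor, which concentrates their expected connection strength well above
#' the mean + 1.5 sd hub threshold. Hub status and module membership are
#' assigned at the level of mirror-paired regions so expected strength, and
#' the planted expression profile, are hemispherically symmetric. Disease
#' groups attenuate each region's loadings by `1 - attenuation`, with
#' attenuation proportional to control strength (min-max scaled by default,
#' rank-scaled via `attenuation_mode`), so proportional loss is coupled to
#' control strength — the planted analogue of selective hub vulnerability. The first gene's latent regional profile is built to
#' correlate with planted control strength at `expression_strength_corr`;
#' remaining genes get independent profiles.
#'
#' @param parc a [tessellate()] parcellation (defines regions and pairing).
#' @param scen a [scenario()].
#' @param seed integer seed.
#' @param expression_strength_corr target population Pearson r between the
#'   first gene's profile and control strength (default 0.3).
#' @param attenuation_max named vector: maximum per-region attenuation per
#'   disease group (defaults PD 0.35, PSP 0.5 — the source data provide no
#'   effect size; documented choices).
#' @param fluency_slope behavioral score units per unit mean hub strength.
#' @param hub_fraction fraction of regions planted as hubs.
#' @param n_modules factor-model modules.
#' @param hub_loading,module_loading factor loadings.
#' @param attenuation_mode `"strength"` (default): attenuation proportional
#'   to min-max-scaled control strength; `"rank"`: proportional to strength
#'   rank.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(parc, scen, seed,
                         expression_strength_corr = 0.3,
                         attenuation_max = c(PD = 0.35, PSP = 0.5),
                         fluency_slope = 5,
                         hub_fraction = 0.1,
                         n_modules = 10L,
                         hub_loading = 0.7,
                         module_loading = 1,
                         attenuation_mode = c("strength", "rank")) {
  attenuation_mode <- match.arg(attenuation_mode)
  stopifnot(inherits(parc, "parcellation"), inherits(scen, "scenario"))
  if (any(attenuation_max < 0 | attenuation_max > 1)) stop_hv("attenuation must lie in [0,1]")
  R <- parc$K
  pairs <- .mirror_pairs(parc)
  n_struct <- max(pairs$structure_id)
  m <- min(as.integer(n_modules), n_struct)

  with_seed(seed, {
    # pair-level assignments
    n_hub_struct <- max(1L, round(hub_fraction * R / 2))
    hub_struct <- sample.int(n_struct, n_hub_struct)
    module_of_struct <- sample(rep_len(seq_len(m), n_struct))
    is_hub <- pairs$structure_id %in% hub_struct
    module <- module_of_struct[pairs$structure_id]

    loadings <- matrix(0, R, m)
    loadings[cbind(which(!is_hub), module[!is_hub])] <- module_loading
    loadings[is_hub, ] <- hub_loading

    v_band <- (scen$noise_sd$signal^2) / 4  # in-band white-noise variance at level 2
    strength_of <- function(lam) {
      C <- tcrossprod(lam) + diag(v_band, R)
      r <- stats::cov2cor(C); diag(r) <- 0
      rowSums(atanh(pmin(pmax(r, -0.999999), 0.999999)))
    }
    s_ctrl <- strength_of(loadings)

    att <- sapply(names(attenuation_max), function(g) {
      prop <- switch(attenuation_mode,
        strength = (s_ctrl - min(s_ctrl)) / (max(s_ctrl) - min(s_ctrl)),
        rank = (rank(s_ctrl, ties.method = "average") - 1) / (R - 1),
        stop_hv("unknown attenuation_mode '%s'", attenuation_mode))
      attenuation_max[[g]] * prop
    })
    expected_strength <- cbind(control = s_ctrl,
                               sapply(names(attenuation_max), function(g) {
                                 strength_of(loadings * (1 - att[, g]))
                               }))

    # latent expression: drawn per structure (so profiles are symmetric
    # across mirror pairs), then the first gene's profile is rotated to hit
    # the target correlation with control strength exactly at the region
    # level (expected strength is itself pair-symmetric, so symmetry holds)
    genes <- names(scen$genes)
    s_std <- as.numeric(scale(s_ctrl))
    profiles <- sapply(seq_along(genes), function(gi) {
      eta <- stats::rnorm(n_struct)[pairs$structure_id]
      if (gi == 1L) {
        rho <- expression_strength_corr
        res <- stats::residuals(stats::lm(eta ~ s_std))
        rho * s_std + sqrt(1 - rho^2) * as.numeric(scale(res))
      } else as.numeric(scale(eta))
    })
    colnames(profiles) <- genes

    structure(list(hub_region_ids = which(is_hub),
                   expression_strength_corr = expression_strength_corr,
                   attenuation_map = att,
                   fluency_slope = fluency_slope,
                   loadings = loadings,
                   module = module,
                   v_band = v_band,
                   expected_strength = expected_strength,
                   expression_profiles = profiles,
                   structure_labels = pairs$structure,
                   hemisphere = pairs$hemisphere,
                   mirror_pair = pairs$pair,
                   seeds = list(ground_truth = as.integer(seed)),
                   params = list(hub_fraction = hub_fraction, n_modules = m,
                                 hub_loading = hub_loading,
                                 module_loading = module_loading,
                                 attenuation_max = attenuation_max,
                                 attenuation_mode = attenuation_mode)),
              class = "ground_truth")
  })
}

#' Band-limited Gaussian noise
#'
#' White Gaussian series filtered in the Fourier domain to the closed band
#' `[f_low, f_high]` Hz and rescaled to unit sample sd per column. Used so
#' planted correlations live in the analyzed wavelet band.
#'
#' @param n_timepoints series length.
#' @param n_series number of independent columns.
#' @param f_low,f_high band edges in Hz.
#' @param repetition_time sampling interval, seconds.
#' @return `n_timepoints x n_series` matrix.
#' @export
band_limited_noise <- function(n_timepoints, n_series, f_low, f_high,
                               repetition_time) {
  x <- matrix(stats::rnorm(n_timepoints * n_series), n_timepoints, n_series)
  fr <- stats::mvfft(x)
  freq <- seq(0, n_timepoints - 1) / (n_timepoints * repetition_time)
  nyq <- 1 / (2 * repetition_time)
  f2 <- pmin(freq, 2 * nyq - freq)  # fold to [0, nyquist]
  keep <- f2 >= f_low & f2 <= f_high
  fr[!keep, ] <- 0
  y <- Re(stats::mvfft(fr, inverse = TRUE)) / n_timepoints
  sweep(y, 2, apply(y, 2, stats::sd), "/")
}

#' Simulate BOLD data for one subject
#'
#' Region signals are mixtures of band-limited latent factors (within the
#' level-2 band for the scenario TR) with the ground-truth loadings,
#' attenuated by `1 - attenuation` for disease groups, plus white region
#' noise. With `voxelwise = TRUE` a 4D volume is assembled (voxel value =
#' region signal + voxel noise); otherwise the region-level series is
#' returned directly (fast path for simulation studies). A 6-parameter
#' motion trace with Poisson-placed translation spikes is generated either
#' way.
#'
#' @param parc parcellation.
#' @param scen [scenario()].
#' @param group `"control"`, or a disease group named in the ground truth
#'   attenuation map (`"PD"`, `"PSP"`).
#' @param gt [ground_truth()].
#' @param seed integer seed.
#' @param voxelwise assemble the full 4D volume (default `TRUE`).
#' @param motion_spike_rate per-frame probability of a translation spike.
#' @param motion_spike_mag spike magnitude, mm.
#' @param motion_artifact if `TRUE`, motion spikes also inject a
#'   signal artifact into every region (to exercise the delta-BOLD check).
#' @return list with `series` ([region_ts()], full length, no discards
#'   applied), `motion` ([motion_trace()]), and (if `voxelwise`) `bold`
#'   (4D array with `repetition_time` attribute).
#' @export
simulate_bold <- function(parc, scen, group, gt, seed, voxelwise = TRUE,
                          motion_spike_rate = 0.01, motion_spike_mag = 0.3,
                          motion_artifact = FALSE) {
  stopifnot(inherits(gt, "ground_truth"))
  groups_ok <- c("control", colnames(gt$attenuation_map))
  if (!group %in% groups_ok) {
    stop_hv("unknown group '%s' (expected one of: %s)", group,
            paste(groups_ok, collapse = ", "))
  }
  att <- if (group == "control") rep(0, parc$K) else gt$attenuation_map[, group]
  lam <- gt$loadings * (1 - att)
  TT <- scen$n_timepoints
  band <- scale_band(scen$repetition_time, 2L)

  with_seed(seed, {
    f <- band_limited_noise(TT, ncol(lam), band["f_low"], band["f_high"],
                            scen$repetition_time)
    y <- f %*% t(lam) + scen$noise_sd$signal *
      matrix(stats::rnorm(TT * parc$K), TT, parc$K)

    # slow drifts: ~0.02 mm and ~0.0004 rad (0.02 mm arc) per frame
    drift <- cbind(apply(matrix(stats::rnorm(TT * 3, sd = 0.02), TT, 3), 2, cumsum),
                   apply(matrix(stats::rnorm(TT * 3, sd = 4e-4), TT, 3), 2, cumsum))
    spikes <- which(stats::runif(TT - 1) < motion_spike_rate) + 1L
    if (length(spikes)) drift[spikes, 1] <- drift[spikes, 1] + motion_spike_mag
    mot <- motion_trace(drift[, 1:3], drift[, 4:6],
                        repetition_time = scen$repetition_time)
    if (motion_artifact && length(spikes)) {
      y[spikes, ] <- y[spikes, ] + motion_spike_mag * 10
    }

    ts <- region_ts(y, repetition_time = scen$repetition_time,
                    region_ids = parc$region_ids)
    out <- list(series = ts, motion = mot, group = group,
                seed = as.integer(seed))
    if (voxelwise) {
      dims <- parc$grid$dims
      lab <- as.integer(parc$labels)
      vol <- matrix(stats::rnorm(prod(dims) * TT, sd = scen$noise_sd$voxel),
                    prod(dims), TT)
      inreg <- lab > 0L
      vol[inreg, ] <- vol[inreg, ] + t(y)[lab[inreg], ]
      bold <- array(vol, dim = c(dims, TT))
      attr(bold, "repetition_time") <- scen$repetition_time
      out$bold <- bold
    }
    out
  })
}

#' Simulate donor expression samples and probe annotation
#'
#' Per donor, samples are placed at jittered region centroids with the
#' region's structure label and hemisphere; per-probe values are
#' `latent regional profile + donor offset + probe offset + noise`. Exactly
#' `scen$single_hemisphere_donors` donors carry samples from the left
#' hemisphere only (emulating donors lacking right-hemisphere data). One or
#' more probes per gene can be flagged `qc_pass = FALSE` (probe QC is an
#' input to the pipeline, not computed by it). Optional background probes
#' of dummy genes give the interhemispheric symmetry test a many-probe
#' substrate: their latent profiles are shared across mirror pairs when
#' `symmetric_background` (symmetric truth) or drawn independently per
#' region otherwise (null).
#'
#' @param parc parcellation.
#' @param scen [scenario()].
#' @param gt [ground_truth()].
#' @param seed integer seed.
#' @param sample_fraction fraction of eligible regions sampled per donor.
#' @param jitter_sd positional jitter sd, mm.
#' @param n_background_probes extra dummy-gene probes (default 0).
#' @param symmetric_background background latent profiles symmetric across
#'   hemispheres (default `TRUE`).
#' @return list with `samples` (data.frame: donor_id, structure_label,
#'   hemisphere, x_mm, y_mm, z_mm, then one column per probe) and `probes`
#'   (data.frame: probe_id, gene, qc_pass).
#' @export
simulate_expression <- function(parc, scen, gt, seed,
                                sample_fraction = 0.7, jitter_sd = 0.5,
                                n_background_probes = 0L,
                                symmetric_background = TRUE) {
  stopifnot(inherits(gt, "ground_truth"))
  R <- parc$K
  mm <- voxel_to_mm(parc$grid, parc$centroids_vox)
  hemi <- gt$hemisphere
  genes <- names(scen$genes)

  probes <- do.call(rbind, lapply(seq_along(genes), function(gi) {
    np <- scen$genes[[gi]]
    nf <- scen$qc_fail[[genes[gi]]] %||% 0L
    data.frame(probe_id = sprintf("%s_probe_%d", genes[gi], seq_len(np)),
               gene = genes[gi],
               qc_pass = c(rep(TRUE, np - nf), rep(FALSE, nf)))
  }))

  with_seed(seed, {
    prof <- gt$expression_profiles
    if (n_background_probes > 0L) {
      sid <- match(gt$structure_labels, unique(gt$structure_labels))
      bg_prof <- sapply(seq_len(n_background_probes), function(i) {
        if (symmetric_background) {
          stats::rnorm(max(sid))[sid]
        } else {
          stats::rnorm(R)
        }
      })
      colnames(bg_prof) <- sprintf("BG%04d", seq_len(n_background_probes))
      bg_probes <- data.frame(probe_id = sprintf("BG%04d_probe_1", seq_len(n_background_probes)),
                              gene = colnames(bg_prof), qc_pass = TRUE)
      probes <- rbind(probes, bg_probes)
      prof <- cbind(prof, bg_prof)
    }
    probe_gene <- probes$gene
    n_probe <- nrow(probes)
    probe_offset <- stats::rnorm(n_probe, sd = scen$noise_sd$probe_offset)

    single_left <- seq_len(scen$single_hemisphere_donors)
    rows <- vector("list", scen$n_donors)
    for (d in seq_len(scen$n_donors)) {
      elig <- if (d %in% single_left) which(hemi == "L") else seq_len(R)
      if (!length(elig)) stop_hv("donor %d: no regions on the sampled hemisphere", d)
      take <- sort(sample(elig, max(1L, round(sample_fraction * length(elig)))))
      donor_offset <- stats::rnorm(1, sd = scen$noise_sd$donor_offset)
      pos <- mm[take, , drop = FALSE] +
        matrix(stats::rnorm(3 * length(take), sd = jitter_sd), ncol = 3)
      vals <- prof[take, probe_gene, drop = FALSE] +
        matrix(probe_offset, length(take), n_probe, byrow = TRUE) +
        donor_offset +
        matrix(stats::rnorm(length(take) * n_probe, sd = scen$noise_sd$expression),
               length(take), n_probe)
      colnames(vals) <- probes$probe_id
      rows[[d]] <- data.frame(donor_id = sprintf("donor_%02d", d),
                              structure_label = gt$structure_labels[take],
                              hemisphere = hemi[take],
                              x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
                              vals, check.names = FALSE)
    }
    list(samples = do.call(rbind, rows), probes = probes)
  })
}

#' Simulate behavioral scores from hub strength
#'
#' Verbal fluency follows `group intercept + slope * (hub strength -
#' expected group hub strength) + noise`; centering on the expected group
#' hub strength keeps group means at their intercepts (defaults are the
#' emulated study means 40.3 / 34.3 / 14.1 with sds 10.4 / 7.3 / 8.6). The
#' motor score (UPDRS-like) is independent of hub strength by construction.
#'
#' @param subject_hub_strength numeric vector, mean hub strength per subject.
#' @param groups character vector of group labels, aligned with strengths.
#' @param gt [ground_truth()] (provides slope and expected hub strengths).
#' @param seed integer seed.
#' @param intercepts,noise_sd named per-group fluency intercepts / noise sds.
#' @param slope override of `gt$fluency_slope`.
#' @param updrs_mean,updrs_sd named per-group motor-score parameters.
#' @return data.frame: group, fluency, updrs, mmse.
#' @export
simulate_behaviour <- function(subject_hub_strength, groups, gt, seed,
                               intercepts = c(control = 40.3, PD = 34.3, PSP = 14.1),
                               noise_sd = c(control = 10.4, PD = 7.3, PSP = 8.6),
                               slope = NULL,
                               updrs_mean = c(control = 2, PD = 25, PSP = 35),
                               updrs_sd = c(control = 2, PD = 8, PSP = 10)) {
  stopifnot(all(is.finite(subject_hub_strength)),
            length(groups) == length(subject_hub_strength))
  if (!all(groups %in% names(intercepts))) stop_hv("group labels missing from intercepts")
  slope <- slope %||% gt$fluency_slope
  centers <- vapply(groups, function(g) {
    mean(gt$expected_strength[gt$hub_region_ids, g])
  }, numeric(1))
  with_seed(seed, {
    n <- length(groups)
    fluency <- intercepts[groups] + slope * (subject_hub_strength - centers) +
      stats::rnorm(n, sd = noise_sd[groups])
    updrs <- updrs_mean[groups] + stats::rnorm(n, sd = updrs_sd[groups])
    mmse <- pmin(30, round(c(control = 29, PD = 28, PSP = 26)[groups] +
                             stats::rnorm(n, sd = 1)))
    data.frame(group = groups, fluency = as.numeric(fluency),
               updrs = as.numeric(updrs), mmse = as.numeric(mmse))
  })
}
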