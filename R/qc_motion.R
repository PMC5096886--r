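#' Construct a motion trace
#'
#' @param translations timepoints x 3 matrix, mm.
#' @param rotations timepoints x 3 matrix, radians.
#' @param repetition_time seconds.
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations, repetition_time = 2) {
  translations <- as.matrix(translations); rotations <- as.matrix(rotations)
  stopifnot(ncol(translations) == 3L, ncol(rotations) == 3L,
            nrow(translations) == nrow(rotations),
            all(is.finite(translations)), all(is.finite(rotations)))
  dimnames(translations) <- NULL
  dimnames(rotations) <- NULL
  structure(list(translations = translations, rotations = rotations,
                 repetition_time = repetition_time),
            class = "motion_trace")
}

#' Framewise displacement
#'
#' Power-convention summary of head motion per timepoint:
#' `FD_t = sum |d translations| + 50 mm * sum |d rotations|`, with
#' `FD_1 = 0`. Rotations are converted to arc length at an assumed 50 mm
#' head radius.
#'
#' @param trace a [motion_trace()].
#' @param head_radius_mm assumed head radius (default 50).
#' @return numeric FD series in mm, same length as the trace.
#' @export
framewise_displacement <- function(trace, head_radius_mm = 50) {
  stopifnot(inherits(trace, "motion_trace"))
  n <- nrow(trace$translations)
  if (n < 2L) stop_hv("need >= 2 timepoints for framewise displacement")
  dtr <- abs(diff(trace$translations))
  dro <- abs(diff(trace$rotations))
  c(0, rowSums(dtr) + head_radius_mm * rowSums(dro))
}

#' Subject exclusion by maximum framewise displacement
#'
#' Excluded iff `max(FD)` strictly exceeds the limit (default 5 mm between
#' any two TR intervals).
#'
#' @param fd FD series from [framewise_displacement()].
#' @param limit mm threshold (default 5).
#' @return list with `excluded` (logical) and `max_fd`.
#' @export
exclude_by_fd <- function(fd, limit = 5) {
  list(excluded = max(fd) > limit, max_fd = max(fd))
}

#' Scrub high-motion frames from a region time series
#'
#' Frames with `FD > fd_threshold`, plus the one following frame, are
#' removed and the remaining frames concatenated.
#'
#' @param ts a [region_ts()] or timepoints x regions matrix.
#' @param fd FD series aligned with the rows of `ts`.
#' @param fd_threshold mm (default 0.5; distinct from the 5-mm
#'   subject-exclusion limit).
#' @param min_frames minimum surviving frames (default 64).
#' @return list with `series` (censored [region_ts()]) and `censored`
#'   (removed frame indices).
#' @export
scrub <- function(ts, fd, fd_threshold = 0.5, min_frames = 64L) {
  x <- unclass(ts)
  if (length(fd) != nrow(x)) stop_hv("FD length (%d) does not match series length (%d)", length(fd), nrow(x))
  spikes <- which(fd > fd_threshold)
  censored <- sort(unique(c(spikes, spikes + 1L)))
  censored <- censored[censored <= nrow(x)]
  keep <- setdiff(seq_len(nrow(x)), censored)
  if (length(keep) < min_frames) {
    stop_hv("only %d frames survive scrubbing (minimum %d); series unusable",
            length(keep), min_frames)
  }
  out <- region_ts(x[keep, , drop = FALSE],
                   repetition_time = attr(ts, "repetition_time"),
                   region_ids = attr(ts, "region_ids"),
                   n_discarded = attr(ts, "n_discarded") %||% 0L)
  list(series = out, censored = censored)
}

#' Motion-contamination check (delta-BOLD)
#'
#' Detects subjects whose connectivity estimates are driven by motion. Two
#' quantities are computed: (1) the edge-level change in the association
#' matrix before vs after scrubbing, `mean |z_raw - z_scrubbed|`; (2) a
#' frame-level statistic, the Pearson correlation between the frame-to-frame
#' root-mean-square signal change across regions (DVARS-style) and FD, with
#' a permutation p-value. The subject is excluded iff scrubbing actually
#' removed frames AND the motion-signal correlation is significant at
#' `alpha`. (If scrubbing removes nothing the deltas are identically zero,
#' so motion cannot have altered connectivity, and the subject is retained.)
#' This concrete statistic is this package's definition of the check; the
#' procedure it emulates is described in its source lineage only as a
#' modified protocol.
#'
#' @param ts_raw a [region_ts()].
#' @param fd FD series aligned with `ts_raw`.
#' @param fd_threshold scrub threshold, mm (default 0.5).
#' @param alpha significance level (default 0.05).
#' @param n_perm permutations for the p-value (default 1000).
#' @param level,filter_name wavelet settings for the association matrices.
#' @param seed RNG seed for the permutation null.
#' @return list: `excluded`, `p_value`, `statistic` (FD-DVARS correlation),
#'   `mean_delta_z`, `n_censored`.
#' @export
delta_bold_check <- function(ts_raw, fd, fd_threshold = 0.5, alpha = 0.05,
                             n_perm = 1000L, level = 2L, filter_name = "d4",
                             seed = 1L) {
  x <- unclass(ts_raw)
  sc <- tryCatch(scrub(ts_raw, fd, fd_threshold), error = function(e) NULL)
  if (is.null(sc)) {
    warn_hv("scrubbing left too few frames; subject flagged excluded")
    return(list(excluded = TRUE, p_value = NA_real_, statistic = NA_real_,
                mean_delta_z = NA_real_, n_censored = nrow(x)))
  }
  if (!length(sc$censored)) {
    return(list(excluded = FALSE, p_value = NA_real_, statistic = NA_real_,
                mean_delta_z = 0, n_censored = 0L))
  }
  z_raw <- build_association_matrix(ts_raw, level = level, filter_name = filter_name)
  z_scr <- build_association_matrix(sc$series, level = level, filter_name = filter_name)
  delta <- abs(unclass(z_raw) - unclass(z_scr))
  mean_delta <- mean(delta[upper.tri(delta)])

  dvars <- c(0, sqrt(rowMeans(diff(x)^2)))
  if (stats::var(dvars) == 0 || stats::var(fd) == 0) {
    warn_hv("degenerate variance in motion check; subject retained")
    return(list(excluded = FALSE, p_value = NA_real_, statistic = NA_real_,
                mean_delta_z = mean_delta, n_censored = length(sc$censored)))
  }
  r_obs <- stats::cor(dvars, fd)
  p <- with_seed(seed, {
    n_ge <- 0L
    for (b in seq_len(n_perm)) {
      r_b <- stats::cor(dvars[sample.int(length(dvars))], fd)
      if (abs(r_b) >= abs(r_obs)) n_ge <- n_ge + 1L
    }
    (n_ge + 1) / (n_perm + 1)
  })
  list(excluded = p < alpha, p_value = p, statistic = r_obs,
       mean_delta_z = mean_delta, n_censored = length(sc$censored))
}
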