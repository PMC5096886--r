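#' Construct a region time-series container
#'
#' @param values timepoints x regions numeric matrix.
#' @param repetition_time sampling interval in seconds.
#' @param region_ids ordered region ids (default column count sequence).
#' @param n_discarded leading volumes already dropped.
#' @return object of class `region_ts` (a matrix with metadata attributes).
#' @export
region_ts <- function(values, repetition_time, region_ids = NULL, n_discarded = 0L) {
  values <- as.matrix(values)
  if (anyNA(values)) stop_hv("region time series contain missing values")
  structure(values,
            repetition_time = repetition_time,
            region_ids = region_ids %||% seq_len(ncol(values)),
            n_discarded = as.integer(n_discarded),
            class = c("region_ts", "matrix", "array"))
}

#' Extract per-region mean time series from a 4D volume
#'
#' After discarding the first `n_discard` volumes, each region's series is
#' the unweighted mean over its voxels at each timepoint. Regions of the
#' parcellation that contain no in-scan voxels are flagged in the
#' `empty_regions` attribute rather than silently dropped.
#'
#' @param volume4d 4D array (x, y, z, t) on the parcellation grid.
#' @param parc a [tessellate()] (possibly coverage-excluded) parcellation.
#' @param n_discard leading volumes to drop (default 5).
#' @return a [region_ts()]; columns ordered by region id.
#' @export
extract_timeseries <- function(volume4d, parc, n_discard = 5L) {
  stopifnot(inherits(parc, "parcellation"))
  d <- dim(volume4d)
  if (length(d) != 4L || !identical(d[1:3], parc$grid$dims)) {
    stop_hv("volume grid (%s) does not match parcellation grid (%s)",
            paste(d[1:3], collapse = "x"), paste(parc$grid$dims, collapse = "x"))
  }
  tt <- seq.int(n_discard + 1L, d[4])
  if (length(tt) < 1L) stop_hv("n_discard >= number of volumes")
  lab <- as.integer(parc$labels)
  inmask <- lab > 0L
  lab_in <- lab[inmask]
  counts <- tabulate(lab_in, nbins = parc$K)
  empty <- which(counts == 0L)
  if (length(empty)) warn_hv("%d region(s) contain no in-scan voxels: %s",
                             length(empty), paste(empty, collapse = ","))
  nvox <- prod(d[1:3])
  mat <- matrix(volume4d, nvox, d[4])[inmask, tt, drop = FALSE]
  # rowsum over region labels, then divide by voxel counts
  sums <- rowsum(mat, group = lab_in, reorder = TRUE)
  vals <- sums / counts[as.integer(rownames(sums))]
  out <- matrix(NA_real_, length(tt), parc$K)
  out[, as.integer(rownames(sums))] <- t(vals)
  keep <- setdiff(seq_len(parc$K), empty)
  ts <- region_ts(out[, keep, drop = FALSE],
                  repetition_time = attr(volume4d, "repetition_time") %||% NA_real_,
                  region_ids = parc$region_ids[keep],
                  n_discarded = as.integer(n_discard))
  attr(ts, "empty_regions") <- empty
  ts
}

#' Build a signed Fisher-z wavelet association matrix
#'
#' All pairwise wavelet correlations at the chosen level, Fisher
#' z-transformed; nothing is thresholded or rectified (negative weights are
#' retained) and the diagonal is 0.
#'
#' @param ts a [region_ts()] (or plain timepoints x regions matrix).
#' @param level wavelet level (default 2).
#' @param filter_name wavelet filter (default `"d4"`).
#' @param clip clip perfect correlations at `1 - 1e-6` before the z
#'   transform (default `TRUE`; recorded on the result).
#' @return regions x regions matrix of class `assoc_matrix` with attributes
#'   `scale`, `filter_name`, `region_ids`, `clip`.
#' @export
build_association_matrix <- function(ts, level = 2L, filter_name = "d4", clip = TRUE) {
  x <- unclass(ts)
  attrs <- attributes(ts)
  if (ncol(x) < 2L) stop_hv("need >= 2 regions to build an association matrix")
  dec <- modwt(x, filter_name = filter_name, n_levels = level)
  w <- dec$W[[level]]
  nb <- dec$n_boundary[level]
  w <- w[(nb + 1):nrow(w), , drop = FALSE]
  mu <- colMeans(w)
  wc <- sweep(w, 2, mu)
  ss <- sqrt(colSums(wc^2))
  if (any(ss == 0)) {
    warn_hv("zero-variance wavelet coefficients for region(s) %s",
            paste(which(ss == 0), collapse = ","))
    ss[ss == 0] <- NA_real_
  }
  r <- crossprod(sweep(wc, 2, ss, "/"))
  r[r > 1] <- 1; r[r < -1] <- -1   # guard fp overshoot
  diag(r) <- 0
  z <- fisher_z(r, clip = clip)
  zmat <- matrix(as.numeric(z), ncol(x), ncol(x))
  diag(zmat) <- 0
  structure(zmat,
            scale = as.integer(level),
            filter_name = filter_name,
            region_ids = attrs$region_ids %||% seq_len(ncol(x)),
            clip = clip,
            n_clipped = attr(z, "clipped"),
            class = c("assoc_matrix", "matrix", "array"))
}

#' Edgewise mean association matrix for a group
#'
#' Arithmetic mean of the subjects' z matrices. By linearity the region
#' strengths of the result equal the mean of the per-subject strengths,
#' while also defining a full group matrix.
#'
#' @param matrices list of `assoc_matrix` objects sharing region ids.
#' @return an `assoc_matrix`.
#' @export
group_mean_matrix <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  ids <- attr(matrices[[1]], "region_ids")
  for (m in matrices) {
    if (!identical(attr(m, "region_ids"), ids)) stop_hv("region ids differ across subjects")
  }
  acc <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  structure(acc,
            scale = attr(matrices[[1]], "scale"),
            filter_name = attr(matrices[[1]], "filter_name"),
            region_ids = ids,
            clip = attr(matrices[[1]], "clip"),
            class = c("assoc_matrix", "matrix", "array"))
}
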