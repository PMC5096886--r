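# MODWT (maximal overlap discrete wavelet transform) with circular boundary,
# pyramid algorithm. Implemented in-package: the wavelet correlation at a
# chosen dyadic scale is the core primitive of the whole analysis.

.wavelet_filters <- function(filter_name) {
  g <- switch(filter_name,
    d4 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    la8 = c(-0.0757657147893407, -0.0296355276459541, 0.4976186676324578,
             0.8037387518052163, 0.2978577956055422, -0.0992195435769354,
            -0.0126039672622612, 0.0322231006040713),
    stop_hv("unknown wavelet filter '%s' (available: d4, la8)", filter_name))
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)  # QMF wavelet filter
  list(g = g / sqrt(2), h = h / sqrt(2), L = L)  # MODWT rescaling
}

# circular filter of each column of x with filter f upsampled by 2^(j-1)
.modwt_filter <- function(x, f, j) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  shift_unit <- 2^(j - 1)
  idx0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    src <- ((idx0 - (l - 1L) * shift_unit) %% n) + 1L
    out <- out + f[l] * x[src, , drop = FALSE]
  }
  out
}

#' Number of boundary-affected MODWT coefficients at a level
#'
#' With circular filtering, the first `L_j - 1` coefficients at level `j`
#' mix the two ends of the series, where `L_j = (2^j - 1)(L - 1) + 1` is the
#' equivalent filter width for a base filter of `L` taps.
#'
#' @param level decomposition level.
#' @param filter_name `"d4"` or `"la8"`.
#' @return integer count.
#' @export
modwt_n_boundary <- function(level, filter_name = "d4") {
  L <- .wavelet_filters(filter_name)$L
  as.integer((2^level - 1) * (L - 1))
}

#' MODWT decomposition
#'
#' Non-decimated wavelet transform: one detail series per level, same length
#' as the input, plus the final smooth. Energy is preserved:
#' `sum_j ||W_j||^2 + ||V_J||^2 = ||x||^2`.
#'
#' @param series numeric vector, or a matrix with one series per column
#'   (all columns transformed together).
#' @param filter_name `"d4"` (default) or `"la8"`.
#' @param n_levels decomposition depth (default 4).
#' @return list of class `modwt`: `W` (list of detail matrices, level 1..J),
#'   `V` (smooth at level J), `filter_name`, `n_levels`, `n_boundary`
#'   (per level).
#' @export
modwt <- function(series, filter_name = "d4", n_levels = 4L) {
  x <- if (is.matrix(series)) series else matrix(series, ncol = 1L)
  if (anyNA(x)) stop_hv("series contains missing values")
  flt <- .wavelet_filters(filter_name)
  n <- nrow(x)
  min_len <- (2^n_levels - 1) * (flt$L - 1) + 1
  if (n < min_len) {
    stop_hv("series length %d too short for %d MODWT levels with %s (minimum %d)",
            n, n_levels, filter_name, min_len)
  }
  W <- vector("list", n_levels)
  V <- x
  for (j in seq_len(n_levels)) {
    W[[j]] <- .modwt_filter(V, flt$h, j)
    V <- .modwt_filter(V, flt$g, j)
  }
  structure(list(W = W, V = V, filter_name = filter_name,
                 n_levels = as.integer(n_levels),
                 n_boundary = vapply(seq_len(n_levels), modwt_n_boundary,
                                     integer(1), filter_name = filter_name)),
            class = "modwt")
}

#' Frequency band isolated by a wavelet level
#'
#' Dyadic band for level `j` at sampling interval `tr`:
#' `(1 / (2^(j+1) tr), 1 / (2^j tr))` Hz. For a repetition time of 2 s the
#' second of four bands is 0.0625-0.125 Hz.
#'
#' @param repetition_time sampling interval in seconds.
#' @param level wavelet level `j >= 1`.
#' @return named numeric vector `c(f_low, f_high)` in Hz.
#' @export
scale_band <- function(repetition_time, level) {
  stopifnot(repetition_time > 0, level >= 1)
  c(f_low = 1 / (2^(level + 1) * repetition_time),
    f_high = 1 / (2^level * repetition_time))
}

#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)`. Out-of-domain values (`|r| >= 1`) are an error unless
#' `clip = TRUE`, in which case any magnitude above `1 - 1e-6` is clipped to
#' that limit (the clip count is recorded via the `"clipped"` attribute).
#'
#' @param r correlation value(s).
#' @param clip clip `|r| >= 1` instead of erroring.
#' @return z value(s); attribute `clipped` gives the number of clips applied.
#' @export
fisher_z <- function(r, clip = FALSE) {
  lim <- 1 - 1e-6
  if (!clip && any(abs(r) >= 1, na.rm = TRUE)) {
    stop_hv("|r| >= 1 passed to fisher_z without clip flag")
  }
  n_clip <- 0L
  if (clip) {
    n_clip <- sum(abs(r) > lim, na.rm = TRUE)
    r <- pmin(pmax(r, -lim), lim)
  }
  structure(atanh(r), clipped = n_clip)
}

#' Wavelet correlation between two series
#'
#' Pearson correlation of the level-`level` MODWT detail coefficients of the
#' two series, after dropping the boundary-affected coefficients.
#'
#' @param tsA,tsB numeric vectors of equal length.
#' @param level wavelet level (default 2).
#' @param filter_name wavelet filter.
#' @return correlation in `[-1, 1]`; `NA` with a warning if either detail
#'   series has zero variance.
#' @export
wavelet_correlation <- function(tsA, tsB, level = 2L, filter_name = "d4") {
  if (length(tsA) != length(tsB)) stop_hv("series lengths differ (%d vs %d)", length(tsA), length(tsB))
  dec <- modwt(cbind(tsA, tsB), filter_name = filter_name, n_levels = level)
  w <- dec$W[[level]]
  nb <- dec$n_boundary[level]
  w <- w[(nb + 1):nrow(w), , drop = FALSE]
  if (stats::var(w[, 1]) == 0 || stats::var(w[, 2]) == 0) {
    warn_hv("zero-variance wavelet coefficients at level %d; correlation undefined", level)
    return(NA_real_)
  }
  stats::cor(w[, 1], w[, 2])
}
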