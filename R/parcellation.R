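#' Random-centroid Voronoi parcellation of a voxel mask
#'
#' Divides the masked voxels into `K` regions: `K` centroid voxels are drawn
#' uniformly without replacement from the mask, then every masked voxel is
#' assigned to its nearest centroid by Euclidean distance in mm (voxel
#' indices scaled by voxel size). Exact distance ties are broken by a seeded
#' uniform choice among the tied centroids. One-shot assignment is the
#' default; `lloyd_iter > 0` additionally runs that many Lloyd iterations
#' (recompute centroids as region means snapped to the nearest member voxel,
#' then reassign), which moves the tessellation toward a centroidal one.
#'
#' @param grid a [volume_grid()].
#' @param K number of regions; `0 < K <=` number of masked voxels.
#' @param seed integer seed controlling centroid draw and tie-breaks.
#' @param lloyd_iter number of Lloyd relaxation iterations (default 0).
#' @return object of class `parcellation`: `labels` (integer array over the
#'   grid, 0 = background), `centroids_vox` (K x 3, 1-based voxel indices),
#'   `K`, `region_ids`, `sizes`, `excluded_ids`, `grid`, `seed`.
#' @export
tessellate <- function(grid, K, seed, lloyd_iter = 0L) {
  stopifnot(inherits(grid, "volume_grid"))
  vox <- mask_voxels(grid)
  n <- nrow(vox)
  if (!is.numeric(K) || length(K) != 1L || K <= 0) stop_hv("K must be a positive count")
  K <- as.integer(K)
  if (K > n) stop_hv("K = %d exceeds the %d masked voxels", K, n)

  with_seed(seed, {
    cent_idx <- sample.int(n, K)
    cent <- vox[cent_idx, , drop = FALSE]
    labels_vec <- .assign_nearest(vox, cent, grid$voxel_size, tie_rng = TRUE)
    iter <- 0L
    while (iter < lloyd_iter) {
      for (k in seq_len(K)) {
        members <- vox[labels_vec == k, , drop = FALSE]
        if (!nrow(members)) next
        mu <- colMeans(members)
        d2 <- colSums((t(members) - mu)^2)
        cent[k, ] <- members[which.min(d2), ]
      }
      labels_vec <- .assign_nearest(vox, cent, grid$voxel_size, tie_rng = TRUE)
      iter <- iter + 1L
    }

    labels <- array(0L, dim = grid$dims)
    labels[vox] <- labels_vec
    structure(list(labels = labels,
                   centroids_vox = cent,
                   K = K,
                   region_ids = seq_len(K),
                   sizes = tabulate(labels_vec, nbins = K),
                   excluded_ids = integer(0),
                   old_to_new = stats::setNames(seq_len(K), seq_len(K)),
                   grid = grid,
                   seed = as.integer(seed),
                   lloyd_iter = as.integer(lloyd_iter)),
              class = "parcellation")
  })
}

# Nearest-centroid assignment in mm with exact-tie handling.
# Distances are accumulated per centroid (memory O(n)); exact ties are
# collected and resolved by a uniform draw per tied voxel, in voxel order,
# from the current RNG stream.
.assign_nearest <- function(vox, cent, voxel_size, tie_rng = TRUE) {
  n <- nrow(vox)
  K <- nrow(cent)
  vs2 <- voxel_size^2
  best <- rep(Inf, n)
  for (k in seq_len(K)) {
    d2 <- (vox[, 1] - cent[k, 1])^2 * vs2[1] +
          (vox[, 2] - cent[k, 2])^2 * vs2[2] +
          (vox[, 3] - cent[k, 3])^2 * vs2[3]
    best <- pmin(best, d2)
  }
  # second pass: candidates at the exact minimum
  lab <- integer(n)
  n_cand <- integer(n)
  for (k in seq_len(K)) {
    d2 <- (vox[, 1] - cent[k, 1])^2 * vs2[1] +
          (vox[, 2] - cent[k, 2])^2 * vs2[2] +
          (vox[, 3] - cent[k, 3])^2 * vs2[3]
    hit <- d2 == best
    n_cand[hit] <- n_cand[hit] + 1L
    # keep-with-prob-1/count reservoir: uniform over tied centroids, but a
    # per-voxel RNG draw order would depend on K; defer random ties below
    lab[hit & n_cand == 1L] <- k
  }
  tied <- which(n_cand > 1L)
  if (length(tied)) {
    for (v in tied) {  # voxel order => reproducible draws
      d2v <- (cent[, 1] - vox[v, 1])^2 * vs2[1] +
             (cent[, 2] - vox[v, 2])^2 * vs2[2] +
             (cent[, 3] - vox[v, 3])^2 * vs2[3]
      cand <- which(d2v == best[v])
      lab[v] <- if (tie_rng) cand[sample.int(length(cand), 1L)] else cand[1L]
    }
  }
  lab
}

#' @export
print.parcellation <- function(x, ...) {
  st <- region_size_stats(x)
  cat(sprintf("parcellation: K = %d (%d excluded), mean region size %.1f voxels (sd %.1f)\n",
              x$K, length(x$excluded_ids), st$mean, st$sd))
  invisible(x)
}

#' Exclude regions with insufficient scan coverage
#'
#' A region is excluded when, in any subject, the fraction of its voxels
#' covered by that subject's scan falls below `min_fraction` (strict `<`).
#' Surviving regions are re-indexed contiguously; the old-to-new map is
#' persisted on the returned object.
#'
#' @param parc a [tessellate()] result.
#' @param coverage list of logical arrays (one per subject) on the same grid;
#'   `TRUE` = voxel covered.
#' @param min_fraction minimum covered fraction (default 0.5).
#' @return a new `parcellation` with `excluded_ids` (original ids),
#'   `old_to_new` and relabelled `labels`.
#' @export
apply_coverage_exclusion <- function(parc, coverage, min_fraction = 0.5) {
  stopifnot(inherits(parc, "parcellation"))
  if (!is.list(coverage) || !length(coverage)) stop_hv("coverage must be a nonempty list of voxel maps")
  lab_vec <- parc$labels[parc$labels > 0L]
  vox <- which(parc$labels > 0L)   # linear indices, fixed order
  sizes <- tabulate(lab_vec, nbins = parc$K)
  bad <- rep(FALSE, parc$K)
  for (cov in coverage) {
    if (!identical(dim(cov), parc$grid$dims)) stop_hv("coverage map dims do not match parcellation grid")
    covered <- as.logical(cov)[vox]
    frac <- tabulate(lab_vec[covered], nbins = parc$K) / sizes
    bad <- bad | (frac < min_fraction)
  }
  excluded <- which(bad)
  keep <- which(!bad)
  old_to_new <- integer(parc$K)
  old_to_new[keep] <- seq_along(keep)
  labels <- array(0L, dim = parc$grid$dims)
  labels[parc$labels > 0L] <- old_to_new[lab_vec]

  out <- parc
  out$labels <- labels
  out$centroids_vox <- parc$centroids_vox[keep, , drop = FALSE]
  out$K <- length(keep)
  out$region_ids <- seq_along(keep)
  out$sizes <- sizes[keep]
  out$excluded_ids <- excluded
  out$old_to_new <- stats::setNames(old_to_new, seq_len(parc$K))
  out
}

#' Region size summary
#'
#' Mean and standard deviation (n-1 denominator) of voxel counts over
#' non-excluded regions.
#'
#' @param parc a `parcellation`.
#' @return list with `mean`, `sd`, `sizes`.
#' @export
region_size_stats <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  s <- parc$sizes
  list(mean = mean(s), sd = if (length(s) > 1) sd_n1(s) else NA_real_, sizes = s)
}

#' Per-region contiguity fraction
#'
#' Voronoi cells restricted to a non-convex mask can be disconnected, so
#' contiguity is reported rather than guaranteed: for each region, the
#' fraction of its voxels in the largest 6-connected component.
#'
#' @param parc a `parcellation`.
#' @return numeric vector over regions.
#' @export
region_contiguity <- function(parc) {
  dims <- parc$grid$dims
  out <- numeric(parc$K)
  for (k in seq_len(parc$K)) {
    vox <- which(parc$labels == k, arr.ind = TRUE)
    n <- nrow(vox)
    if (!n) { out[k] <- NA_real_; next }
    key <- function(v) (v[, 1] - 1) + dims[1] * ((v[, 2] - 1) + dims[2] * (v[, 3] - 1))
    keys <- key(vox)
    comp <- integer(n); ncomp <- 0L
    lookup <- stats::setNames(seq_len(n), keys)
    for (s in seq_len(n)) {
      if (comp[s]) next
      ncomp <- ncomp + 1L
      queue <- s
      comp[s] <- ncomp
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        for (ax in 1:3) for (dd in c(-1L, 1L)) {
          nb <- vox[v, ]; nb[ax] <- nb[ax] + dd
          j <- lookup[as.character((nb[1] - 1) + dims[1] * ((nb[2] - 1) + dims[2] * (nb[3] - 1)))]
          if (!is.na(j) && !comp[j]) { comp[j] <- ncomp; queue <- c(queue, j) }
        }
      }
    }
    out[k] <- max(tabulate(comp, ncomp)) / n
  }
  out
}
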