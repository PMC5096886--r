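# Donor expression handling: within-donor normalization, interhemispheric
# symmetry testing, sample mirroring, nearest-neighbor region matching and
# per-region per-gene aggregation.

.probe_cols <- function(samples, probes) {
  miss <- setdiff(probes$probe_id, names(samples))
  if (length(miss)) stop_hv("sample table lacks probe column(s): %s", paste(miss, collapse = ","))
  probes$probe_id
}

#' Normalize expression within donor
#'
#' Per donor and per probe, values are centered and scaled to unit sd (n-1
#' denominator) across that donor's samples, so additive donor offsets and
#' probe offsets vanish and donors become comparable.
#'
#' @param samples sample table (see [simulate_expression()]).
#' @param probes probe annotation table.
#' @return the sample table with probe columns normalized; constant probes
#'   within a donor become `NA` with a warning.
#' @export
normalize_within_donor <- function(samples, probes) {
  cols <- .probe_cols(samples, probes)
  counts <- table(samples$donor_id)
  if (any(counts < 2L)) stop_hv("donor(s) with < 2 samples: %s",
                                paste(names(counts)[counts < 2], collapse = ","))
  out <- samples
  for (d in unique(samples$donor_id)) {
    idx <- samples$donor_id == d
    x <- as.matrix(samples[idx, cols, drop = FALSE])
    mu <- colMeans(x)
    s <- apply(x, 2, sd_n1)
    zero <- s == 0
    if (any(zero)) {
      warn_hv("donor %s: %d constant probe(s) set to missing", d, sum(zero))
      s[zero] <- NA_real_
    }
    out[idx, cols] <- sweep(sweep(x, 2, mu), 2, s, "/")
  }
  out
}

# per (structure x probe) mean expression matrix for one donor/hemisphere
.structure_profile <- function(samples, cols, hemi) {
  sub <- samples[samples$hemisphere == hemi, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  agg <- rowsum(as.matrix(sub[, cols, drop = FALSE]), group = sub$structure_label)
  n <- as.vector(table(sub$structure_label)[rownames(agg)])
  agg / n
}

#' Interhemispheric symmetry test
#'
#' For each donor with samples in both hemispheres: every structure labeled
#' on both sides contributes the Pearson correlation, across probes, between
#' its left and right mean expression vectors (Fisher z, clipped at
#' `1 - 1e-6`). The observed statistic is the mean z over homologous pairs.
#' The null permutes the pairing: each null draw matches the same number of
#' left structures with mismatched right structures and records the mean z;
#' `n_random_pairs` total random pairs are drawn (so `n_random_pairs /
#' n_pairs` null means). `p = (count(null >= observed) + 1) / (n_null + 1)`.
#'
#' @param samples normalized sample table.
#' @param probes probe table (all supplied probes are used; configurable by
#'   subsetting `probes`).
#' @param n_random_pairs total randomly mismatched pairs for the null
#'   (default 10000).
#' @param seed integer seed.
#' @param min_probes minimum probes required (default 100).
#' @return named list (one element per two-hemisphere donor) of
#'   `symmetry_test` results: `per_pair_z`, `observed_mean_z`,
#'   `null_mean_zs`, `p_value`, `n_pairs_permuted`.
#' @export
interhemispheric_symmetry_test <- function(samples, probes,
                                           n_random_pairs = 10000L, seed = 1L,
                                           min_probes = 100L) {
  cols <- .probe_cols(samples, probes)
  if (length(cols) < min_probes) {
    stop_hv("symmetry test needs >= %d probes, got %d", min_probes, length(cols))
  }
  donors <- unique(samples$donor_id)
  out <- list()
  for (d in donors) {
    sub <- samples[samples$donor_id == d, , drop = FALSE]
    if (length(unique(sub$hemisphere)) < 2L) next
    L <- .structure_profile(sub, cols, "L")
    R <- .structure_profile(sub, cols, "R")
    common <- intersect(rownames(L), rownames(R))
    if (!length(common)) stop_hv("donor %s: no homologous structure pairs", d)
    zmat <- fisher_z(stats::cor(t(L), t(R), use = "pairwise.complete.obs"), clip = TRUE)
    zmat <- matrix(as.numeric(zmat), nrow(L), nrow(R),
                   dimnames = list(rownames(L), rownames(R)))
    per_pair <- zmat[cbind(common, common)]
    obs <- mean(per_pair)
    P <- length(common)
    n_null <- max(1L, as.integer(round(n_random_pairs / P)))
    null_means <- with_seed(derive_seed(seed, "symmetry", d), {
      vapply(seq_len(n_null), function(b) {
        li <- sample(rownames(L), P, replace = TRUE)
        ri <- vapply(li, function(l) {
          cand <- setdiff(rownames(R), l)
          cand[sample.int(length(cand), 1L)]
        }, character(1))
        mean(zmat[cbind(li, ri)])
      }, numeric(1))
    })
    p <- (sum(null_means >= obs) + 1) / (n_null + 1)
    out[[d]] <- structure(list(per_pair_z = stats::setNames(per_pair, common),
                               observed_mean_z = obs,
                               null_mean_zs = null_means,
                               p_value = p,
                               n_pairs_permuted = n_null * P),
                          class = "symmetry_test")
  }
  if (!length(out)) stop_hv("no donor has samples in both hemispheres")
  out
}

#' @export
print.symmetry_test <- function(x, ...) {
  cat(sprintf("interhemispheric symmetry: mean z = %.3f over %d pairs, p = %.3g\n",
              x$observed_mean_z, length(x$per_pair_z), x$p_value))
  invisible(x)
}

#' Mirror samples across the midsagittal plane
#'
#' Under the symmetry assumption, each sample is duplicated with the sign of
#' its x coordinate flipped and the hemisphere label swapped; mirrored rows
#' carry `mirrored = TRUE`, and are never re-mirrored, so the operation is
#' idempotent up to the single mirror set.
#'
#' @param samples sample table.
#' @param donors restrict mirroring to these donor ids (default all; donors
#'   that already cover both hemispheres can be left unmirrored).
#' @return augmented sample table with a `mirrored` column.
#' @export
mirror_samples <- function(samples, donors = NULL) {
  if (is.null(samples$mirrored)) samples$mirrored <- FALSE
  src <- samples[!samples$mirrored, , drop = FALSE]
  if (!is.null(donors)) src <- src[src$donor_id %in% donors, , drop = FALSE]
  mir <- src
  mir$x_mm <- -mir$x_mm
  mir$hemisphere <- ifelse(mir$hemisphere == "L", "R", "L")
  mir$mirrored <- TRUE
  rbind(samples[!samples$mirrored, , drop = FALSE], mir)
}

#' Match imaging regions to expression samples
#'
#' Each imaging region takes the structure label of the nearest sample
#' (Euclidean distance in mm, pooled across donors, after any mirroring).
#' Exact distance ties go to the lowest sample row index and are logged in
#' the `ties` attribute.
#'
#' @param parc parcellation (centroids in the same mm space as samples).
#' @param samples sample table.
#' @return data.frame: `region_id`, `structure_label`, `distance_mm`,
#'   `sample_row`; attribute `ties` lists regions whose match was tied.
#' @export
match_regions <- function(parc, samples) {
  if (!nrow(samples)) stop_hv("empty sample set")
  cent <- voxel_to_mm(parc$grid, parc$centroids_vox)
  pos <- as.matrix(samples[, c("x_mm", "y_mm", "z_mm")])
  tie_regions <- integer(0)
  best_row <- integer(parc$K)
  best_d <- numeric(parc$K)
  for (i in seq_len(parc$K)) {
    d2 <- (pos[, 1] - cent[i, 1])^2 + (pos[, 2] - cent[i, 2])^2 +
          (pos[, 3] - cent[i, 3])^2
    mn <- min(d2)
    hits <- which(d2 == mn)
    if (length(hits) > 1L) tie_regions <- c(tie_regions, i)
    best_row[i] <- hits[1L]
    best_d[i] <- sqrt(mn)
  }
  structure(data.frame(region_id = parc$region_ids,
                       structure_label = samples$structure_label[best_row],
                       distance_mm = best_d,
                       sample_row = best_row),
            ties = tie_regions)
}

#' Aggregate normalized expression per region for one gene
#'
#' The region's value is the mean of normalized values over all QC-passing
#' probes of the gene and all samples whose structure label matches the
#' region's matched label, pooled across donors. Mirrored duplicates are
#' dropped first (they repeat the same measurements and would only inflate
#' `n_samples`). Regions with no matching samples get `NA`, flagged — never
#' zero.
#'
#' @param region_map result of [match_regions()].
#' @param samples normalized sample table.
#' @param probes probe table.
#' @param gene gene symbol.
#' @return data.frame of class `region_expression`: `region_id`, `gene`,
#'   `value`, `n_samples`; attributes `donor_breakdown` (per-region,
#'   per-donor sample counts), `per_probe` (region x probe value matrix,
#'   retained for probe-level analyses) and `missing_regions`.
#' @export
aggregate_expression <- function(region_map, samples, probes, gene) {
  use <- probes$gene == gene & probes$qc_pass
  if (!any(use)) stop_hv("no QC-passing probes for gene %s", gene)
  cols <- probes$probe_id[use]
  if (!is.null(samples$mirrored)) samples <- samples[!samples$mirrored, , drop = FALSE]
  vals <- as.matrix(samples[, cols, drop = FALSE])
  sample_mean <- rowMeans(vals, na.rm = TRUE)

  value <- rep(NA_real_, nrow(region_map))
  n_samples <- integer(nrow(region_map))
  breakdown <- vector("list", nrow(region_map))
  per_probe <- matrix(NA_real_, nrow(region_map), length(cols),
                      dimnames = list(NULL, cols))
  for (i in seq_len(nrow(region_map))) {
    hit <- samples$structure_label == region_map$structure_label[i]
    n_samples[i] <- sum(hit)
    if (n_samples[i] > 0L) {
      value[i] <- mean(vals[hit, , drop = FALSE], na.rm = TRUE)
      per_probe[i, ] <- colMeans(vals[hit, , drop = FALSE], na.rm = TRUE)
      breakdown[[i]] <- table(samples$donor_id[hit])
    }
  }
  missing <- region_map$region_id[n_samples == 0L]
  if (length(missing)) warn_hv("%d region(s) have no matching samples for %s",
                               length(missing), gene)
  structure(data.frame(region_id = region_map$region_id, gene = gene,
                       value = value, n_samples = n_samples),
            donor_breakdown = breakdown,
            missing_regions = missing,
            per_probe = per_probe,
            sample_mean = sample_mean,
            class = c("region_expression", "data.frame"))
}

#' Inter-donor variability of regional expression
#'
#' Per region, the sd (n-1) across donors of the donor-mean normalized
#' expression for the gene; regions with fewer than two contributing donors
#' are flagged `NA`.
#'
#' @param region_map result of [match_regions()].
#' @param samples normalized sample table.
#' @param probes probe table.
#' @param gene gene symbol.
#' @return data.frame: `region_id`, `sd_across_donors`, `n_donors`.
#' @export
interdonor_variability <- function(region_map, samples, probes, gene) {
  use <- probes$gene == gene & probes$qc_pass
  cols <- probes$probe_id[use]
  if (!is.null(samples$mirrored)) samples <- samples[!samples$mirrored, , drop = FALSE]
  vals <- rowMeans(as.matrix(samples[, cols, drop = FALSE]), na.rm = TRUE)
  out <- data.frame(region_id = region_map$region_id,
                    sd_across_donors = NA_real_, n_donors = 0L)
  for (i in seq_len(nrow(region_map))) {
    hit <- samples$structure_label == region_map$structure_label[i]
    if (!any(hit)) next
    dm <- tapply(vals[hit], samples$donor_id[hit], mean)
    out$n_donors[i] <- length(dm)
    if (length(dm) >= 2L) out$sd_across_donors[i] <- sd_n1(as.numeric(dm))
  }
  out
}
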