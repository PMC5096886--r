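# Readers/writers for the pipeline's plain formats, study simulation to
# disk, end-to-end orchestration and reporting.

#' Write / read a TSV table
#'
#' Doubles are serialized with 17 significant digits so numeric round trips
#' are bit-exact.
#'
#' @param df data.frame.
#' @param path TSV path.
#' @rdname tsv_io
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tsv_io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write / read a motion trace as 6-column TSV
#'
#' Columns: trans_x/y/z (mm), rot_x/y/z (radians), one row per timepoint.
#'
#' @param trace a [motion_trace()].
#' @param path TSV path.
#' @rdname motion_io
#' @export
write_motion <- function(trace, path) {
  df <- data.frame(trace$translations, trace$rotations)
  names(df) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  write_tsv(df, path)
}

#' @param repetition_time TR in seconds for the reconstructed trace.
#' @rdname motion_io
#' @export
read_motion <- function(path, repetition_time = 2) {
  df <- read_tsv(path)
  motion_trace(as.matrix(df[, 1:3]), as.matrix(df[, 4:6]), repetition_time)
}

#' Write / read an association matrix as TSV with region-id header
#'
#' @param mat an `assoc_matrix`.
#' @param path TSV path.
#' @rdname assoc_io
#' @export
write_assoc_tsv <- function(mat, path) {
  df <- as.data.frame(unclass(mat))
  names(df) <- as.character(attr(mat, "region_ids"))
  write_tsv(df, path)
}

#' @param scale,filter_name metadata restored on the object.
#' @rdname assoc_io
#' @export
read_assoc_tsv <- function(path, scale = 2L, filter_name = "d4") {
  df <- read_tsv(path)
  structure(as.matrix(df),
            dimnames = NULL,
            scale = scale, filter_name = filter_name,
            region_ids = as.integer(names(df)),
            class = c("assoc_matrix", "matrix", "array"))
}

#' Write a parcellation as NIfTI labels plus JSON sidecar
#'
#' @param parc a `parcellation`.
#' @param prefix output path prefix; writes `<prefix>.nii.gz` (int32 labels,
#'   0 = background/excluded) and `<prefix>.json` (centroids, seed,
#'   exclusions, old-to-new map).
#' @rdname parcellation_io
#' @export
write_parcellation <- function(parc, prefix) {
  write_nifti(parc$labels, paste0(prefix, ".nii.gz"),
              affine = parc$grid$affine, voxel_size = parc$grid$voxel_size,
              dtype = "int32")
  jsonlite::write_json(
    list(K = parc$K, seed = parc$seed, lloyd_iter = parc$lloyd_iter,
         centroids_vox = parc$centroids_vox,
         sizes = parc$sizes,
         excluded_ids = parc$excluded_ids,
         old_to_new = as.list(parc$old_to_new),
         voxel_size = parc$grid$voxel_size),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @param mask_path NIfTI mask defining the grid (labels > 0 also work).
#' @rdname parcellation_io
#' @export
read_parcellation <- function(prefix, mask_path = NULL) {
  nii <- read_nifti(paste0(prefix, ".nii.gz"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  labels <- array(as.integer(nii$data), dim = dim(nii$data))
  mask <- if (is.null(mask_path)) labels > 0L else {
    m <- read_nifti(mask_path)
    check_affines(m$affine, nii$affine)
    m$data > 0
  }
  grid <- volume_grid(array(mask, dim = dim(labels)),
                      voxel_size = meta$voxel_size, affine = nii$affine)
  structure(list(labels = labels,
                 centroids_vox = matrix(meta$centroids_vox, ncol = 3),
                 K = meta$K,
                 region_ids = seq_len(meta$K),
                 sizes = meta$sizes,
                 excluded_ids = as.integer(meta$excluded_ids),
                 old_to_new = unlist(meta$old_to_new),
                 grid = grid,
                 seed = meta$seed,
                 lloyd_iter = meta$lloyd_iter),
            class = "parcellation")
}

#' Serialize / regenerate the ground truth
#'
#' The JSON stores the seeds and generator parameters (not the derived
#' arrays), so the file fully determines regeneration: reading it back
#' re-runs [ground_truth()] and returns a bit-identical object.
#'
#' @param gt a `ground_truth`.
#' @param scen the [scenario()] it was built under.
#' @param path JSON path.
#' @rdname ground_truth_io
#' @export
write_ground_truth <- function(gt, scen, path) {
  params <- gt$params
  params$attenuation_max <- as.list(params$attenuation_max)
  scen_l <- unclass(scen)
  scen_l$genes <- as.list(scen_l$genes)
  scen_l$qc_fail <- as.list(scen_l$qc_fail)
  jsonlite::write_json(
    list(seed = gt$seeds$ground_truth,
         expression_strength_corr = gt$expression_strength_corr,
         fluency_slope = gt$fluency_slope,
         params = params,
         scenario = scen_l),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param parc the parcellation the study used.
#' @rdname ground_truth_io
#' @export
read_ground_truth <- function(path, parc) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  scen <- do.call(scenario, c(
    j$scenario[setdiff(names(j$scenario), c("genes", "qc_fail", "noise_sd"))],
    list(genes = vapply(j$scenario$genes, as.integer, integer(1)),
         qc_fail = vapply(j$scenario$qc_fail, as.integer, integer(1)),
         noise_sd = lapply(j$scenario$noise_sd, as.numeric))))
  gt <- ground_truth(parc, scen, seed = as.integer(j$seed),
                     expression_strength_corr = as.numeric(j$expression_strength_corr),
                     attenuation_max = vapply(j$params$attenuation_max,
                                              as.numeric, numeric(1)),
                     fluency_slope = as.numeric(j$fluency_slope),
                     hub_fraction = as.numeric(j$params$hub_fraction),
                     n_modules = as.integer(j$params$n_modules),
                     hub_loading = as.numeric(j$params$hub_loading),
                     module_loading = as.numeric(j$params$module_loading),
                     attenuation_mode = j$params$attenuation_mode %||% "strength")
  list(gt = gt, scenario = scen)
}

#' Simulate a complete study to disk
#'
#' Writes every pipeline input: gray-matter mask and parcellation (NIfTI +
#' JSON), per-subject 4D BOLD (NIfTI) and motion traces (TSV), subject
#' metadata (TSV), expression samples and probes (TSV), and the ground-truth
#' record (JSON).
#'
#' @param dir output directory (created).
#' @param scen a [scenario()].
#' @param seed master seed; all stage seeds are derived from it.
#' @param mask_shape voxel dims of the synthetic mask.
#' @param K parcellation size (default `scen$n_regions`).
#' @param ... passed to [ground_truth()].
#' @return invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_study <- function(dir, scen, seed, mask_shape = c(16, 16, 12),
                           K = scen$n_regions, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- make_mask(mask_shape, "two_lobes")
  parc <- tessellate(grid, K, seed = derive_seed(seed, "parc"))
  gt <- ground_truth(parc, scen, seed = derive_seed(seed, "gt"), ...)

  write_nifti(grid$mask, file.path(dir, "mask.nii.gz"), affine = grid$affine,
              voxel_size = grid$voxel_size, dtype = "uint8")
  write_parcellation(parc, file.path(dir, "parcellation"))
  write_ground_truth(gt, scen, file.path(dir, "ground_truth.json"))

  groups <- c("control", colnames(gt$attenuation_map))
  subj <- list(); hubstr <- numeric(0); glab <- character(0)
  sid <- 0L
  for (g in groups) {
    for (i in seq_len(scen$n_subjects_per_group)) {
      sid <- sid + 1L
      id <- sprintf("sub-%03d", sid)
      sim <- simulate_bold(parc, scen, g, gt,
                           seed = derive_seed(seed, "bold", g, i),
                           voxelwise = TRUE)
      write_nifti(sim$bold, file.path(dir, paste0(id, "_bold.nii.gz")),
                  affine = grid$affine, voxel_size = grid$voxel_size,
                  dtype = "float32", tr = scen$repetition_time)
      write_motion(sim$motion, file.path(dir, paste0(id, "_motion.tsv")))
      # latent (voxel-noise-free) hub strength drives behavior
      amat <- build_association_matrix(sim$series)
      hubs_gt <- list(hub_ids = gt$hub_region_ids)
      hubstr <- c(hubstr, mean(connection_strength(amat)[gt$hub_region_ids]))
      glab <- c(glab, g)
      subj[[sid]] <- id
    }
  }
  beh <- simulate_behaviour(hubstr, glab, gt, seed = derive_seed(seed, "beh"))
  subjects <- data.frame(subject_id = unlist(subj), beh)
  write_tsv(subjects, file.path(dir, "subjects.tsv"))

  expr <- simulate_expression(parc, scen, gt, seed = derive_seed(seed, "expr"))
  write_tsv(expr$samples, file.path(dir, "samples.tsv"))
  write_tsv(expr$probes, file.path(dir, "probes.tsv"))

  invisible(list(dir = dir, grid = grid, parc = parc, gt = gt,
                 subjects = subjects, samples = expr$samples,
                 probes = expr$probes))
}

#' Build a pipeline configuration
#'
#' Every analysis-relevant setting lives here and is serialized into output
#' provenance; [run_pipeline()] reads only files declared in the config.
#'
#' @param input_dir directory produced by [simulate_study()] (or laid out
#'   the same way).
#' @param out_dir results directory.
#' @param seed master seed for all permutation nulls.
#' @param level,filter_name wavelet settings.
#' @param n_discard leading volumes to drop.
#' @param fd_limit subject-exclusion FD limit, mm.
#' @param scrub_threshold frame-scrub FD threshold, mm.
#' @param qc_n_perm permutations in the delta-BOLD check.
#' @param min_coverage region coverage fraction threshold.
#' @param hub_k hub threshold sd multiplier.
#' @param n_perm permutations for the analysis tests.
#' @param genes genes to analyze (must exist in the probe table).
#' @param correction multiple-comparison correction across genes.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir, seed = 1L,
                            level = 2L, filter_name = "d4", n_discard = 5L,
                            fd_limit = 5, scrub_threshold = 0.5,
                            qc_n_perm = 200L, min_coverage = 0.5,
                            hub_k = 1.5, n_perm = 5000L,
                            genes = c("MAPT", "SNCA"),
                            correction = "bonferroni") {
  cfg <- as.list(environment())
  for (f in c("seed", "level", "n_discard", "qc_n_perm", "n_perm")) {
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  for (f in c("fd_limit", "scrub_threshold", "min_coverage", "hub_k")) {
    cfg[[f]] <- as.numeric(cfg[[f]])
  }
  structure(cfg, class = "pipeline_config")
}

.cfg_paths <- function(cfg, subjects) {
  list(mask = file.path(cfg$input_dir, "mask.nii.gz"),
       parc = file.path(cfg$input_dir, "parcellation"),
       subjects = file.path(cfg$input_dir, "subjects.tsv"),
       samples = file.path(cfg$input_dir, "samples.tsv"),
       probes = file.path(cfg$input_dir, "probes.tsv"),
       bold = file.path(cfg$input_dir, paste0(subjects, "_bold.nii.gz")),
       motion = file.path(cfg$input_dir, paste0(subjects, "_motion.tsv")))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: motion QC (FD limit + delta-BOLD) -> coverage-based
#' region exclusion -> time-series extraction and per-subject wavelet
#' association matrices -> group mean matrices, strengths, hubs and
#' proportional loss -> expression normalization, mirroring, matching and
#' aggregation -> permutation statistics and corrections. Any stage error
#' aborts naming the stage (and subject where applicable). Results and full
#' provenance (config, seeds) are written under `cfg$out_dir`; rerunning the
#' same config reproduces the outputs byte-identically.
#'
#' @param cfg a [pipeline_config()].
#' @return the results bundle (list of class `pipeline_results`), invisibly
#'   written to `out_dir/results.json` and TSV tables.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- "validate"
  fail <- function(e, subject = NULL) {
    stop_hv("pipeline stage '%s'%s failed: %s", stage,
            if (is.null(subject)) "" else paste0(" (", subject, ")"),
            conditionMessage(e))
  }
  subjects_path <- file.path(cfg$input_dir, "subjects.tsv")
  if (!file.exists(subjects_path)) stop_hv("pipeline stage 'validate' failed: missing subjects table %s", subjects_path)
  subjects <- read_tsv(subjects_path)
  paths <- .cfg_paths(cfg, subjects$subject_id)
  for (p in c(paths$mask, paste0(paths$parc, ".nii.gz"), paths$samples,
              paths$probes, paths$bold, paths$motion)) {
    if (!file.exists(p)) stop_hv("pipeline stage 'validate' failed: missing input %s", p)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  parc0 <- read_parcellation(paths$parc, mask_path = paths$mask)

  stage <- "qc"
  qc <- list(); keep <- logical(nrow(subjects))
  series_raw <- list(); coverage <- list()
  for (i in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[i]
    res <- tryCatch({
      nii <- read_nifti(paths$bold[i])
      check_affines(nii$affine, parc0$grid$affine)
      mot <- read_motion(paths$motion[i], repetition_time = nii$tr)
      fd <- framewise_displacement(mot)
      fd_dec <- exclude_by_fd(fd, limit = cfg$fd_limit)
      ts <- extract_timeseries(nii$data, parc0, n_discard = cfg$n_discard)
      db <- delta_bold_check(ts, fd[-seq_len(cfg$n_discard)],
                             fd_threshold = cfg$scrub_threshold,
                             n_perm = cfg$qc_n_perm, level = cfg$level,
                             filter_name = cfg$filter_name,
                             seed = derive_seed(cfg$seed, "qc", id))
      # voxel covered iff it varies over the scan
      v <- apply(array(nii$data, dim = dim(nii$data)), 1:3, stats::var)
      list(fd = fd_dec, db = db, ts = ts, cov = v > 0)
    }, error = function(e) fail(e, id))
    keep[i] <- !res$fd$excluded && !res$db$excluded
    qc[[id]] <- list(max_fd = res$fd$max_fd, fd_excluded = res$fd$excluded,
                     delta_bold_p = res$db$p_value,
                     delta_bold_stat = res$db$statistic,
                     delta_bold_excluded = res$db$excluded,
                     retained = keep[i])
    series_raw[[id]] <- res$ts
    coverage[[id]] <- res$cov
  }
  subjects <- subjects[keep, , drop = FALSE]
  if (!nrow(subjects)) stop_hv("pipeline stage 'qc' failed: all subjects excluded")

  stage <- "parcellate"
  parc <- tryCatch(apply_coverage_exclusion(parc0, coverage[subjects$subject_id],
                                            min_fraction = cfg$min_coverage),
                   error = fail)

  stage <- "connect"
  mats <- lapply(subjects$subject_id, function(id) {
    tryCatch({
      old <- series_raw[[id]]
      keep_reg <- which(parc$old_to_new > 0)
      x <- unclass(old)[, match(keep_reg, attr(old, "region_ids")), drop = FALSE]
      ts <- region_ts(x, attr(old, "repetition_time"),
                      region_ids = parc$region_ids,
                      n_discarded = attr(old, "n_discarded"))
      build_association_matrix(ts, level = cfg$level, filter_name = cfg$filter_name)
    }, error = function(e) fail(e, id))
  })
  names(mats) <- subjects$subject_id

  stage <- "group_matrices"
  groups <- unique(subjects$group)
  if (!"control" %in% groups) stop_hv("pipeline stage 'group_matrices' failed: no control subjects")
  gmat <- lapply(groups, function(g) group_mean_matrix(mats[subjects$group == g]))
  names(gmat) <- groups
  strengths <- lapply(gmat, connection_strength)
  hubs <- define_hubs(strengths$control, k = cfg$hub_k)
  loss <- lapply(setdiff(groups, "control"), function(g) {
    proportional_loss(strengths$control, strengths[[g]], disease_group = g)
  })
  names(loss) <- setdiff(groups, "control")

  stage <- "expression"
  expr <- tryCatch({
    samples <- read_tsv(paths$samples)
    probes <- read_tsv(paths$probes)
    probes$qc_pass <- as.logical(probes$qc_pass)
    norm <- normalize_within_donor(samples, probes)
    sym <- if (nrow(probes) >= 100L) {
      tryCatch(interhemispheric_symmetry_test(norm, probes,
                                              seed = derive_seed(cfg$seed, "sym")),
               error = function(e) conditionMessage(e))
    } else sprintf("skipped: %d probes < 100", nrow(probes))
    mir <- mirror_samples(norm)
    rmap <- match_regions(parc, mir)
    per_gene <- lapply(cfg$genes, function(g) aggregate_expression(rmap, mir, probes, g))
    names(per_gene) <- cfg$genes
    list(symmetry = sym, region_map = rmap, per_gene = per_gene,
         probes = probes)
  }, error = fail)

  stage <- "stats"
  res_stats <- tryCatch({
    expr_strength <- lapply(cfg$genes, function(g) {
      v <- expr$per_gene[[g]]$value
      ok <- is.finite(v)
      pt <- pearson_permutation(v[ok], strengths$control[ok],
                                n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, "expr_strength", g))
      list(gene = g, r = pt$statistic, p = pt$p_value, n = sum(ok))
    })
    names(expr_strength) <- cfg$genes
    probe_strength <- list()
    for (g in cfg$genes) {
      pp <- attr(expr$per_gene[[g]], "per_probe")
      for (pr in colnames(pp)) {
        ok <- is.finite(pp[, pr])
        pt <- pearson_permutation(pp[ok, pr], strengths$control[ok],
                                  n_perm = cfg$n_perm,
                                  seed = derive_seed(cfg$seed, "probe_strength", pr))
        probe_strength[[pr]] <- list(gene = g, probe = pr,
                                     r = pt$statistic, p = pt$p_value)
      }
    }
    p_raw <- vapply(expr_strength, function(x) x$p, numeric(1))
    p_corr <- stats::setNames(bonferroni(p_raw, m = length(cfg$genes)),
                              names(p_raw))
    expr_loss <- list()
    for (g in names(loss)) {
      for (gene in cfg$genes) {
        v <- expr$per_gene[[gene]]$value
        li <- loss[[g]]$loss
        ridx <- setdiff(seq_along(strengths$control), loss[[g]]$excluded_regions)
        ok <- is.finite(v[ridx])
        pt <- pearson_permutation(v[ridx][ok], li[ok], n_perm = cfg$n_perm,
                                  seed = derive_seed(cfg$seed, "expr_loss", g, gene))
        expr_loss[[paste(g, gene, sep = "_")]] <-
          list(group = g, gene = gene, r = pt$statistic, p = pt$p_value)
      }
    }
    strength_loss <- lapply(names(loss), function(g) {
      ridx <- setdiff(seq_along(strengths$control), loss[[g]]$excluded_regions)
      pt <- pearson_permutation(strengths$control[ridx], loss[[g]]$loss,
                                n_perm = cfg$n_perm,
                                seed = derive_seed(cfg$seed, "strength_loss", g))
      list(group = g, r = pt$statistic, p = pt$p_value)
    })
    names(strength_loss) <- names(loss)
    hubstr <- vapply(subjects$subject_id, function(id) mean_hub_strength(mats[[id]], hubs),
                     numeric(1))
    flu <- fluency_covariance(hubstr, subjects$fluency, subjects$group,
                              n_perm = cfg$n_perm,
                              seed = derive_seed(cfg$seed, "fluency"))
    list(expression_strength = expr_strength,
         probe_strength = probe_strength,
         expression_strength_p_corrected = as.list(p_corr),
         correction = list(method = cfg$correction, m = length(cfg$genes)),
         expression_loss = expr_loss,
         strength_loss = strength_loss,
         fluency = list(main = flu$main, interaction = flu$interaction,
                        per_group = flu$per_group, slope = flu$slope),
         hub_strength_by_subject = stats::setNames(as.list(hubstr), subjects$subject_id))
  }, error = fail)

  stage <- "report"
  bundle <- structure(list(
    qc = qc,
    n_regions_retained = parc$K,
    excluded_region_ids = parc$excluded_ids,
    hubs = list(ids = hubs$hub_ids, threshold = hubs$threshold, k = hubs$k),
    strengths = strengths,
    proportional_loss = lapply(loss, function(l) {
      list(loss = as.list(l$loss), excluded_regions = l$excluded_regions)
    }),
    symmetry = if (is.character(expr$symmetry)) expr$symmetry else {
      lapply(expr$symmetry, function(s) list(mean_z = s$observed_mean_z,
                                             p = s$p_value,
                                             n_pairs = length(s$per_pair_z)))
    },
    stats = res_stats,
    provenance = list(config = unclass(cfg), seed = cfg$seed,
                      package_version = as.character(utils::packageVersion("hubvuln")))
  ), class = "pipeline_results")

  jsonlite::write_json(bundle, file.path(cfg$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE, pretty = TRUE)
  for (g in cfg$genes) {
    write_tsv(expr$per_gene[[g]], file.path(cfg$out_dir, paste0("expression_", g, ".tsv")))
  }
  st_tab <- data.frame(region_id = seq_along(strengths$control),
                       hub = seq_along(strengths$control) %in% hubs$hub_ids)
  for (g in groups) st_tab[[paste0("strength_", g)]] <- strengths[[g]]
  write_tsv(st_tab, file.path(cfg$out_dir, "strength.tsv"))
  invisible(bundle)
}

#' Human-readable summary of a results bundle
#'
#' @param results a `pipeline_results` bundle from [run_pipeline()].
#' @param file optional path to also write the report text to.
#' @return character vector of report lines, invisibly.
#' @export
report <- function(results, file = NULL) {
  lines <- c("== hub vulnerability analysis report ==", "")
  lines <- c(lines, sprintf("Regions retained: %d (%d excluded by coverage)",
                            results$n_regions_retained,
                            length(results$excluded_region_ids)))
  nh <- length(results$hubs$ids)
  lines <- c(lines, if (nh) {
    sprintf("Hubs (strength > mean + %.1f sd = %.3f): %s", results$hubs$k,
            results$hubs$threshold, paste(results$hubs$ids, collapse = ", "))
  } else "WARNING: empty hub set")
  excl <- names(Filter(function(q) !isTRUE(q$retained), results$qc))
  lines <- c(lines, sprintf("Subjects excluded by QC: %s",
                            if (length(excl)) paste(excl, collapse = ", ") else "none"))
  lines <- c(lines, "", sprintf("Expression ~ control strength (%s correction, m = %d):",
                                results$stats$correction$method, results$stats$correction$m))
  for (g in names(results$stats$expression_strength)) {
    es <- results$stats$expression_strength[[g]]
    lines <- c(lines, sprintf("  %s [combined over QC-passing probes]: r = %.3f, p = %.4g, corrected p = %.4g",
                              g, es$r, es$p,
                              results$stats$expression_strength_p_corrected[[g]]))
    for (nm in names(results$stats$probe_strength)) {
      ps <- results$stats$probe_strength[[nm]]
      if (ps$gene == g) {
        lines <- c(lines, sprintf("    probe %s: r = %.3f, p = %.4g",
                                  ps$probe, ps$r, ps$p))
      }
    }
  }
  lines <- c(lines, "", "Control strength ~ proportional loss:")
  for (g in names(results$stats$strength_loss)) {
    sl <- results$stats$strength_loss[[g]]
    lines <- c(lines, sprintf("  %s: r = %.3f, p = %.4g", g, sl$r, sl$p))
  }
  lines <- c(lines, "", "Expression ~ proportional loss:")
  for (nm in names(results$stats$expression_loss)) {
    el <- results$stats$expression_loss[[nm]]
    lines <- c(lines, sprintf("  %s / %s: r = %.3f, p = %.4g",
                              el$group, el$gene, el$r, el$p))
  }
  fl <- results$stats$fluency
  lines <- c(lines, "", sprintf("Fluency ~ group + hub strength: F = %.2f (df %d), p = %.4g; interaction F = %.2f, p = %.4g",
                                fl$main$F, fl$main$df, fl$main$p,
                                fl$interaction$F, fl$interaction$p))
  pg <- fl$per_group
  for (i in seq_len(nrow(pg))) {
    lines <- c(lines, sprintf("  post hoc %s: r = %.3f, p = %.4g",
                              pg$group[i], pg$r[i], pg$p_value[i]))
  }
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}
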