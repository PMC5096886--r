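# Shared fixtures (built once per run) and independent oracles.

.fx_cache <- new.env(parent = emptyenv())
fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

tiny_grid <- function() fx("tiny_grid", function() make_mask(c(14, 14, 10), "two_lobes"))
tiny_parc <- function() fx("tiny_parc", function() tessellate(tiny_grid(), 40, seed = 42))
tiny_scen <- function() fx("tiny_scen", function() {
  scenario(n_regions = 40, n_subjects_per_group = 5, n_timepoints = 150)
})
tiny_gt <- function() fx("tiny_gt", function() ground_truth(tiny_parc(), tiny_scen(), seed = 7))

# independent brute-force nearest-centroid oracle (per-voxel loop, mm space)
oracle_nearest <- function(vox, cent, voxel_size) {
  t(apply(vox, 1, function(v) {
    d2 <- colSums((t(cent) - v)^2 * voxel_size^2)
    mn <- min(d2)
    c(label = which.min(d2), n_tied = sum(d2 == mn), best = mn)
  }))
}

# independent BH oracle via the step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- prev
  }
  adj
}

oracle_bonferroni <- function(p, m) vapply(p, function(x) min(1, x * m), numeric(1))

# hand-built sample/probe tables for expression tests
toy_probes <- function() data.frame(
  probe_id = c("MAPT_probe_1", "MAPT_probe_2", "MAPT_probe_3", "MAPT_probe_4",
               "SNCA_probe_1", "SNCA_probe_2"),
  gene = c(rep("MAPT", 4), rep("SNCA", 2)),
  qc_pass = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)

# stated worlds for the acceptance criteria
accept_world <- function() fx("accept_world", function() {
  parc <- tessellate(make_mask(c(16, 16, 12), "two_lobes"), 60, seed = 601)
  scen <- scenario(n_regions = 60, n_subjects_per_group = 10, n_timepoints = 256)
  list(parc = parc, scen = scen, gt = ground_truth(parc, scen, seed = 602))
})
accept_world_big <- function() fx("accept_world_big", function() {
  parc <- tessellate(make_mask(c(20, 20, 16), "two_lobes"), 100, seed = 611)
  scen <- scenario(n_regions = 100, n_subjects_per_group = 20, n_timepoints = 512)
  list(parc = parc, scen = scen, gt = ground_truth(parc, scen, seed = 612))
})
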