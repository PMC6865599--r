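#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper: [generate_cohort()] + [write_cohort()].
#'
#' @param spec a `leida_synth_spec`
#' @param out_dir output directory
#' @return manifest path, invisibly
#' @export
simulate_cohort <- function(spec, out_dir) {
  write_cohort(generate_cohort(spec), out_dir)
}

#' Run the full LEiDA pipeline from a manifest
#'
#' Stages, in order: read scans, band-pass filter, Hilbert phases and
#' per-frame leading eigenvectors (pooled with provenance), independent
#' k-means partitions over `k_min..k_max`, per-scan state metrics at
#' `selected_k`, and permutation-based group comparisons with per-partition
#' Bonferroni correction. Result tables and a provenance record (effective
#' configuration and seeds) are written to `output_dir`.
#'
#' @param manifest_path cohort manifest CSV
#' @param output_dir directory for result files (created)
#' @param band_low_hz,band_high_hz,filter_order band-pass settings
#' @param k_min,k_max partition sweep range
#' @param selected_k partition examined in depth (switching cells, metrics
#'   tables)
#' @param n_replicates k-means restarts per k
#' @param n_perm permutations per test
#' @param alpha nominal significance level before correction
#' @param seed master seed (fans out to clustering and permutation sub-seeds)
#' @param distance k-means distance ("cosine" or "euclidean")
#' @param conditional_on_switch,include_truncated metric options
#' @return list with `sample`, `models`, `metrics`, `comparisons`, invisibly
#' @export
run_pipeline <- function(manifest_path, output_dir,
                         band_low_hz = 0.02, band_high_hz = 0.1,
                         filter_order = 2, k_min = 2L, k_max = 20L,
                         selected_k = 10L, n_replicates = 20L,
                         n_perm = 10000L, alpha = 0.05, seed = 1L,
                         distance = "cosine",
                         conditional_on_switch = TRUE,
                         include_truncated = TRUE) {
  stopifnot(2L <= k_min, k_min <= selected_k, selected_k <= k_max)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  message("reading cohort: ", manifest_path)
  scans <- read_cohort(manifest_path)
  message("  ", length(scans), " scans")
  filtered <- lapply(scans, bandpass_filter, low_hz = band_low_hz,
                     high_hz = band_high_hz, order = filter_order)
  sample <- pool_eigenvectors(filtered)
  message("pooled ", nrow(sample$matrix), " leading eigenvectors (",
          sum(vapply(scans, function(s) nrow(s$data), numeric(1))),
          " frames)")
  data.table::fwrite(sample$qc, file.path(output_dir, "eigen_qc.csv"))
  seeds <- derive_seeds(seed, 2L)
  models <- sweep_k(sample, k_min = k_min, k_max = k_max, seed = seeds[1L],
                    n_replicates = n_replicates, distance = distance)
  message("clustered k = ", k_min, "..", k_max)
  for (m in models) {
    cen <- data.table::as.data.table(m$centroids)
    data.table::setnames(cen, sample$area_labels)
    cen <- cbind(data.table::data.table(state = seq_len(m$k)), cen)
    data.table::fwrite(cen, file.path(output_dir,
                                      sprintf("centroids_k%02d.csv", m$k)))
  }
  tcs <- extract_timecourses(models[[paste0("k", selected_k)]], sample$index)
  metrics <- cohort_metrics(tcs, selected_k,
                            include_truncated = include_truncated,
                            conditional_on_switch = conditional_on_switch)
  data.table::fwrite(metrics$by_state,
                     file.path(output_dir, "metrics_by_state.csv"))
  data.table::fwrite(metrics$by_scan,
                     file.path(output_dir, "metrics_by_scan.csv"))
  data.table::fwrite(metrics$switching,
                     file.path(output_dir, "switching_profiles.csv"))
  cmp <- compare_all(sample, models, selected_k = selected_k, n_perm = n_perm,
                     alpha = alpha, seed = seeds[2L],
                     include_truncated = include_truncated,
                     conditional_on_switch = conditional_on_switch)
  data.table::fwrite(cmp$results, file.path(output_dir, "comparisons.csv"))
  data.table::fwrite(cmp$consistency,
                     file.path(output_dir, "consistency.csv"))
  cfg <- list(manifest_path = manifest_path, band_low_hz = band_low_hz,
              band_high_hz = band_high_hz, filter_order = filter_order,
              k_min = k_min, k_max = k_max, selected_k = selected_k,
              n_replicates = n_replicates, n_perm = n_perm, alpha = alpha,
              seed = seed, distance = distance,
              conditional_on_switch = conditional_on_switch,
              include_truncated = include_truncated,
              n_scans = length(scans), n_eigenvectors = nrow(sample$matrix))
  jsonlite::write_json(cfg, file.path(output_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  message("results written to ", output_dir)
  invisible(list(sample = sample, models = models, metrics = metrics,
                 comparisons = cmp))
}
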