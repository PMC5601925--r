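# End-to-end driver: simulate -> normalize -> randomize zeros -> debarcode
# -> gate -> decode -> hit calling (-> profile), with a JSON run manifest
# sufficient to re-run every stage bit-identically.

#' Build a run configuration
#'
#' @param outdir output directory for stage CSVs and the manifest.
#' @param seed base seed; every stage derives its stream from it.
#' @param n_cells named per-tissue event counts (or scalar). The default
#'   samples low-frequency tissues more deeply (sampling depth scales
#'   inversely with the expected antigen frequency near the 0.15% cutoff).
#' @param arm treatment arm.
#' @param replicates independent simulated experiments.
#' @param dual_config simulate and decode both staining configurations.
#' @param drift injected acquisition drift coefficient (0 = none).
#' @param decode a [decode_params()] list.
#' @param profile a [profile_params()] list; set `run_embedding = FALSE` to
#'   skip t-SNE/k-means (rule labels are always computed).
#' @param run_embedding run t-SNE + k-means on tumour CD8 cells.
#' @param panel_file candidate CSV (default: shipped fixture).
#' @return a `run_config` list.
#' @export
run_config <- function(outdir = tempfile("combitet_run_"), seed = 1L,
                       n_cells = c(tumour = 4000, spleen = 6000,
                                   dLN = 10000, ndLN = 20000),
                       arm = "isotype", replicates = 5L,
                       dual_config = TRUE, drift = 0,
                       decode = decode_params(),
                       profile = profile_params(),
                       run_embedding = FALSE,
                       panel_file = NULL) {
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_cells = n_cells, arm = arm,
                 replicates = as.integer(replicates),
                 dual_config = isTRUE(dual_config), drift = drift,
                 decode = decode, profile = profile,
                 run_embedding = isTRUE(run_embedding),
                 panel_file = panel_file),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with any subset of the [run_config()] fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ct_config_error("config file not found: %s", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  for (nm in names(raw)) {
    if (!nm %in% names(cfg))
      ct_config_error("unknown config field: %s", nm)
    if (nm %in% c("decode", "profile")) {
      cfg[[nm]] <- do.call(if (nm == "decode") decode_params
                           else profile_params, as.list(raw[[nm]]))
    } else cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(cfg$n_cells) && length(cfg$n_cells) > 1 &&
      is.null(names(cfg$n_cells)))
    ct_config_error("n_cells must be named by tissue")
  cfg
}

#' Run the full screen pipeline
#'
#' Stage order mirrors the standard CyTOF workflow: per replicate, the four
#' tissues are simulated, pooled, bead-normalized, zero-randomized and
#' debarcoded; each recovered sample is gated to live CD8+ T cells and
#' decoded against the active coding scheme(s). Frequencies are averaged
#' over replicates, hits called at the strict >0.15% cutoff, and (with
#' dual configurations) concordance computed. Fully deterministic under
#' the config seed.
#'
#' @param config a [run_config()] (or path to a JSON config).
#' @return a `run_manifest` list (also written to
#'   `outdir/manifest.json`); `$results` holds hit tables, frequencies,
#'   decoy rates and the cluster profile in memory.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  t_start <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  panel <- if (is.null(config$panel_file)) build_default_panel()
           else build_default_panel(config$panel_file)
  channels <- default_channels()
  scheme_a <- assign_codes(panel, channels, "A",
                           seed = derive_seed(config$seed, "codeA"))
  schemes <- list(A = scheme_a)
  if (config$dual_config)
    schemes$B <- assign_codes(panel, channels, "B",
                              seed = derive_seed(config$seed, "codeB"),
                              avoid = scheme_a)

  n_cells <- config$n_cells
  tissues <- c("tumour", "spleen", "dLN", "ndLN")
  if (length(n_cells) == 1L)
    n_cells <- stats::setNames(rep(n_cells, 4), tissues)
  spec <- default_experiment(n_cells = n_cells,
                             replicates = config$replicates,
                             seed = config$seed)
  if (is.null(spec$barcodes)) ct_config_error("missing barcode scheme")
  spec <- apply_treatment_effect(spec, config$arm)
  noise <- noise_model(drift = config$drift)
  antigens <- screened_antigens(panel)

  freq_rows <- list()
  decoy_rows <- list()
  gate_reports <- list()
  tumour_cd8 <- list()
  for (rep_i in seq_len(config$replicates)) {
    sim <- simulate_experiment(spec, schemes, noise,
                               seed = derive_seed(config$seed, "sim", rep_i))
    for (cfg in names(schemes)) {
      pooled <- bind_events(lapply(tissues, function(t) sim[[t]][[cfg]]))
      norm <- normalize_beads(pooled)
      ev <- randomize_zeros(norm$events,
                            seed = derive_seed(config$seed, "zeros", rep_i,
                                               cfg))
      bc <- debarcode(ev, spec$barcodes)
      # gate thresholds are fitted once on the pooled acquisition (all
      # populations present, so every gating channel is bimodal) and then
      # applied as fixed gates per recovered sample
      tree <- default_gate_tree(channels)
      thr <- apply_gate_tree(ev, tree)$thresholds
      for (t in tissues) {
        sub <- subset_events(ev, which(!is.na(bc$sample_id) &
                                         bc$sample_id == t))
        gat <- apply_gate_tree(sub, tree, overrides = thr)
        cd8 <- subset_events(sub, gat$mask)
        dec <- decode_cells(cd8, schemes[[cfg]], config$decode)
        fr <- compute_frequencies(dec, antigens = antigens)
        fr$tissue <- t; fr$config <- cfg; fr$replicate <- rep_i
        fr$arm <- config$arm
        freq_rows[[length(freq_rows) + 1L]] <- fr
        decoy_rows[[length(decoy_rows) + 1L]] <-
          data.frame(tissue = t, config = cfg, replicate = rep_i,
                     decoy_rate = mean(dec$decoy), n_cd8 = n_events(cd8))
        gate_reports[[length(gate_reports) + 1L]] <-
          cbind(gat$counts, tissue = t, config = cfg, replicate = rep_i)
        if (t == "tumour" && cfg == "A")
          tumour_cd8[[rep_i]] <- cd8
      }
    }
  }
  freqs <- do.call(rbind, freq_rows)
  decoys <- do.call(rbind, decoy_rows)

  mean_freq <- function(cfg) {
    f <- freqs[freqs$config == cfg & freqs$antigen != "unassigned", ]
    agg <- stats::aggregate(frequency ~ antigen + tissue, data = f,
                            FUN = mean)
    agg$arm <- config$arm
    agg
  }
  hits_a <- call_hits(mean_freq("A"), config$decode)
  results <- list(frequencies = freqs, hits = hits_a, decoys = decoys)
  if (config$dual_config) {
    hits_b <- call_hits(mean_freq("B"), config$decode)
    results$hits <- hit_concordance(hits_a, hits_b)
  }

  # phenotype profile of pooled tumour CD8+ T cells (configuration A)
  pool <- bind_events(tumour_cd8)
  pool <- downsample_events(pool, config$profile$downsample_cap,
                            seed = derive_seed(config$seed, "downsample"))
  labels <- assign_rule_clusters(pool)
  results$rule_labels <- labels
  results$profile <- cluster_profile(pool, labels,
                                     markers = config$profile$markers)
  if (config$run_embedding) {
    tx <- transform_channels(pool, config$profile$markers)
    emb <- run_tsne(tx, config$profile)
    km <- cluster_embedding(emb$Y, k = config$profile$k,
                            restarts = config$profile$restarts,
                            seed = derive_seed(config$seed, "kmeans"))
    results$embedding <- emb$Y
    results$kmeans <- km
    results$concordance <- compare_clusterings(km$labels, labels)
  }

  paths <- c(frequencies = "frequencies.csv", hits = "hits.csv",
             decoys = "decoy_rates.csv", gating = "gating_report.csv",
             profile = "cluster_profile.csv")
  utils::write.csv(freqs, file.path(config$outdir, paths["frequencies"]),
                   row.names = FALSE)
  utils::write.csv(results$hits, file.path(config$outdir, paths["hits"]),
                   row.names = FALSE)
  utils::write.csv(decoys, file.path(config$outdir, paths["decoys"]),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, gate_reports),
                   file.path(config$outdir, paths["gating"]),
                   row.names = FALSE)
  utils::write.csv(results$profile,
                   file.path(config$outdir, paths["profile"]),
                   row.names = FALSE)

  files <- file.path(config$outdir, paths)
  manifest <- list(
    package_version = as.character(utils::packageVersion("combitet")),
    r_version = R.version.string,
    created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    wall_clock_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    seed = config$seed,
    parameters = config[c("n_cells", "arm", "replicates", "dual_config",
                          "drift")],
    decode = unclass(config$decode),
    profile = unclass(config$profile)[c("downsample_cap", "markers",
                                        "perplexity", "iterations", "theta",
                                        "k", "restarts")],
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files))
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(c(manifest, list(results = results, outdir = config$outdir)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("combitet run (%s): seed %d, %d files in %s\n",
              x$created, x$seed, length(x$files), x$outdir))
  hits <- x$results$hits
  ch <- unique(hits$antigen[hits$consistent_hit])
  cat("consistent hits:", if (length(ch)) paste(ch, collapse = ", ")
      else "none", "\n")
  invisible(x)
}
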