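#' Default end-to-end pipeline configuration
#'
#' A flat list of every tunable the pipeline uses, suitable for editing or
#' serializing to YAML. All defaults are recorded in the run manifest so
#' each under-specified analysis choice (percentile rule, detection
#' threshold, inclusive cutoffs) is documented per run.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @return Named list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phases = c("simulate", "diffexp", "onoff", "concord", "plasma"),
    # class counts are named lists (not atomic vectors) so YAML
    # serialization round-trips the names
    simulation = list(n_probesets = 2000,
                      samples_per_class = list(normal = 20, IBD = 10,
                                               adenoma = 10, cancer = 20),
                      n_de_up = 50, n_de_down = 50, de_effect = 1,
                      n_onoff_on = 10, n_onoff_off = 10,
                      within_class_sd = 0.5),
    validation_fraction_concordant = 0.8,
    contrast = list(name = "neoplasia", class_a = c("normal", "IBD"),
                    class_b = c("adenoma", "cancer")),
    alpha = 0.05,
    discovery_method = "bonferroni",
    validation_method = "bh",
    onoff = list(percentile = 0.30, class_call_quantile = 0.5, margin = 0),
    plasma = list(n_per_group = list(normal = 20, adenoma = 20, cancer = 20),
                  min_detected_replicates = 2)
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the discovery/validation/plasma pipeline end to end
#'
#' Orchestrates: cohort simulation (paired discovery + validation),
#' discovery differential expression, switched-on/off calling, candidate
#' validation concordance, and plasma panel analysis. Every output is a
#' plain-text table under `out_dir`, listed in `manifest.tsv` with its md5
#' checksum; rerunning with the same config reproduces identical files.
#'
#' @param config A config list from [default_run_config()], a partial list
#'   merged over the defaults, or a path to a YAML file holding one.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory phase results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  base <- default_run_config(seed = config$seed %||% 1L)
  cfg <- utils::modifyList(base, config)
  phases <- cfg$phases
  known <- c("simulate", "diffexp", "onoff", "concord", "plasma")
  if (length(setdiff(phases, known))) {
    stop("unknown phase(s): ", paste(setdiff(phases, known), collapse = ", "))
  }
  needs <- list(diffexp = "simulate", onoff = c("simulate", "diffexp"),
                concord = c("simulate", "diffexp"), plasma = character(0))
  for (ph in phases) {
    miss <- setdiff(needs[[ph]] %||% character(0), phases)
    if (length(miss)) {
      stop("phase '", ph, "' requires phase(s): ",
           paste(miss, collapse = ", "))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ctr <- define_contrast(cfg$contrast$name, cfg$contrast$class_a,
                         cfg$contrast$class_b)
  files <- character(0)
  results <- list(config = cfg)

  if ("simulate" %in% phases) {
    sim_args <- cfg$simulation
    sim_args$contrast <- ctr
    sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    paired <- simulate_paired_cohorts(scfg,
                                      cfg$validation_fraction_concordant)
    results$cohorts <- paired
    files <- c(files,
      write_expression(paired$discovery$matrix,
                       file.path(out_dir, "discovery.gct"), "gct"),
      write_expression(paired$validation$matrix,
                       file.path(out_dir, "validation.gct"), "gct"),
      write_tsv(paired$discovery$phenotypes,
                file.path(out_dir, "discovery_phenotypes.tsv")),
      write_tsv(paired$validation$phenotypes,
                file.path(out_dir, "validation_phenotypes.tsv")),
      write_tsv(paired$truth, file.path(out_dir, "ground_truth.tsv")))
  }

  if ("diffexp" %in% phases) {
    de <- run_contrast(results$cohorts$discovery$matrix,
                       results$cohorts$discovery$phenotypes, ctr,
                       method = cfg$discovery_method, alpha = cfg$alpha)
    results$discovery_de <- de
    results$discovery_summary <- summarize_contrasts(de, alpha = cfg$alpha)
    pca <- pc_scores(results$cohorts$discovery$matrix, k = 2)
    files <- c(files,
      write_tsv(de, file.path(out_dir, "discovery_de.tsv")),
      write_tsv(results$discovery_summary,
                file.path(out_dir, "discovery_summary.tsv")),
      write_tsv(data.frame(sample_id = rownames(pca$scores), pca$scores),
                file.path(out_dir, "discovery_pc_scores.tsv")))
  }

  if ("onoff" %in% phases) {
    thr <- silence_threshold(results$cohorts$discovery$matrix,
                             cfg$onoff$percentile)
    calls <- classify_onoff(results$cohorts$discovery$matrix,
                            results$cohorts$discovery$phenotypes, ctr, thr,
                            de_results = results$discovery_de,
                            class_call_quantile = cfg$onoff$class_call_quantile,
                            margin = cfg$onoff$margin)
    cand <- phenotype_specific_candidates(calls)
    results$silence_threshold <- thr
    results$onoff_calls <- calls
    results$onoff_candidates <- cand
    files <- c(files,
      write_tsv(calls, file.path(out_dir, "onoff_calls.tsv")),
      write_tsv(cand$switched_on, file.path(out_dir, "switched_on.tsv")),
      write_tsv(cand$switched_off, file.path(out_dir, "switched_off.tsv")))
  }

  if ("concord" %in% phases) {
    cand <- candidate_list(results$discovery_de, require_fc2 = TRUE)
    report <- validate_candidates(cand, results$cohorts$validation$matrix,
                                  results$cohorts$validation$phenotypes,
                                  ctr, alpha = cfg$alpha,
                                  method = cfg$validation_method)
    results$candidates <- cand
    results$concordance <- report
    files <- c(files,
      write_tsv(cand, file.path(out_dir, "candidates.tsv")),
      write_tsv(concordance_summary(report),
                file.path(out_dir, "concordance_summary.tsv")))
  }

  if ("plasma" %in% phases) {
    plasma_args <- cfg$plasma
    plasma_args$min_detected_replicates <- NULL
    plasma_args$seed <- cfg$seed
    panel <- do.call(simulate_plasma_panel, plasma_args)
    plasma <- analyze_plasma(
      panel, min_detected_replicates = cfg$plasma$min_detected_replicates)
    det <- plasma$detected
    mw <- if (any(det & plasma$group != "normal") && any(det & plasma$group == "normal")) {
      mann_whitney_exact(
        plasma$normalized_ct[det & plasma$group != "normal"],
        plasma$normalized_ct[det & plasma$group == "normal"])
    } else NULL
    results$plasma_panel <- panel
    results$plasma <- plasma
    results$plasma_test <- mw
    files <- c(files,
      write_ct_table(panel, file.path(out_dir, "plasma_ct.csv")),
      write_tsv(plasma, file.path(out_dir, "plasma_results.tsv")))
  }

  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files),
    seed = cfg$seed,
    version = as.character(utils::packageVersion("neomarker")),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  results$manifest <- manifest
  invisible(results)
}
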