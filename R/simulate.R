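#' Simulation configuration for synthetic expression cohorts
#'
#' Describes a cohort of log2 expression profiles over the four colorectal
#' phenotypes with planted structure: a log-normal background floor for
#' unexpressed probesets, a constitutively expressed fraction shifted above
#' it, planted differential effects of a chosen log2 magnitude on one
#' contrast, and planted phenotype-specific ("switched-on"/"switched-off")
#' probesets that sit at background level in one class and at expressed level
#' in the other. Planted levels are deterministic given the config, so
#' zero-noise cohorts recover the planted effects exactly.
#'
#' @param n_probesets Number of probesets.
#' @param samples_per_class Named integer vector, samples per phenotype class.
#' @param background_mean,background_sd Mean and spread (log2 units) of the
#'   unexpressed background floor across probesets.
#' @param expressed_fraction Fraction of unplanted probesets constitutively
#'   expressed, in \[0, 1\].
#' @param expressed_mean_shift Log2 units separating expressed baselines from
#'   the background mean.
#' @param n_de_up,n_de_down Planted differentially expressed probesets
#'   (up/down in class B of `contrast`).
#' @param de_effect Planted log2 effect size (1 = two-fold).
#' @param n_onoff_on,n_onoff_off Planted switched-on / switched-off probesets.
#'   Their silent class sits at `background_mean - background_sd`, a typical
#'   low-background intensity safely below the silence threshold.
#' @param within_class_sd Within-class log2 noise SD (0 = noise-free cohort).
#' @param contrast The contrast carrying the planted effects.
#' @param seed Integer seed; identical configs reproduce identical cohorts.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_probesets = 2000,
                       samples_per_class = c(normal = 20, IBD = 10,
                                             adenoma = 10, cancer = 20),
                       background_mean = 5, background_sd = 0.5,
                       expressed_fraction = 0.4, expressed_mean_shift = 3,
                       n_de_up = 50, n_de_down = 50, de_effect = 1,
                       n_onoff_on = 10, n_onoff_off = 10,
                       within_class_sd = 0.5,
                       contrast = define_contrast("neoplasia",
                                                  c("normal", "IBD"),
                                                  c("adenoma", "cancer")),
                       seed = 1L) {
  samples_per_class <- unlist(samples_per_class)  # tolerate YAML lists
  cfg <- list(n_probesets = n_probesets, samples_per_class = samples_per_class,
              background_mean = background_mean, background_sd = background_sd,
              expressed_fraction = expressed_fraction,
              expressed_mean_shift = expressed_mean_shift,
              n_de_up = n_de_up, n_de_down = n_de_down, de_effect = de_effect,
              n_onoff_on = n_onoff_on, n_onoff_off = n_onoff_off,
              within_class_sd = within_class_sd, contrast = contrast,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(n_probesets = cfg$n_probesets, n_de_up = cfg$n_de_up,
              n_de_down = cfg$n_de_down, n_onoff_on = cfg$n_onoff_on,
              n_onoff_off = cfg$n_onoff_off)
  for (nm in names(counts)) {
    if (length(counts[[nm]]) != 1 || is.na(counts[[nm]]) || counts[[nm]] < 0) {
      stop("invalid configuration: '", nm, "' must be a nonnegative count")
    }
  }
  if (cfg$n_probesets < 1) {
    stop("invalid configuration: 'n_probesets' must be positive")
  }
  if (cfg$expressed_fraction < 0 || cfg$expressed_fraction > 1) {
    stop("invalid configuration: 'expressed_fraction' must lie in [0, 1]")
  }
  planted <- cfg$n_de_up + cfg$n_de_down + cfg$n_onoff_on + cfg$n_onoff_off
  if (planted > cfg$n_probesets) {
    stop("invalid configuration: planted probesets (", planted,
         ") exceed 'n_probesets' (", cfg$n_probesets, ")")
  }
  if (is.null(names(cfg$samples_per_class)) ||
      any(!nzchar(names(cfg$samples_per_class)))) {
    stop("invalid configuration: 'samples_per_class' must be a named vector")
  }
  if (any(cfg$samples_per_class < 0)) {
    stop("invalid configuration: 'samples_per_class' has negative counts")
  }
  for (nm in c("background_sd", "within_class_sd")) {
    if (cfg[[nm]] < 0) {
      stop("invalid configuration: '", nm, "' must be nonnegative")
    }
  }
  invisible(cfg)
}

# Draw the per-probeset, per-class mean plan and the ground-truth table.
# Separated from noise sampling so paired cohorts can share one plan.
sim_plan <- function(cfg) {
  classes <- names(cfg$samples_per_class)
  n <- cfg$n_probesets
  ids <- sprintf("ps%05d", seq_len(n))
  status <- rep("null", n)
  k <- 0L
  take <- function(m) {
    idx <- k + seq_len(m); k <<- k + m; idx
  }
  i_up <- take(cfg$n_de_up)
  i_down <- take(cfg$n_de_down)
  i_on <- take(cfg$n_onoff_on)
  i_off <- take(cfg$n_onoff_off)
  status[i_up] <- "de_up"; status[i_down] <- "de_down"
  status[i_on] <- "onoff_on"; status[i_off] <- "onoff_off"

  bg <- cfg$background_mean
  expr_level <- bg + cfg$expressed_mean_shift
  low <- bg - cfg$background_sd  # planted silent-class level

  i_null <- which(status == "null")
  n_expr <- round(cfg$expressed_fraction * length(i_null))
  expressed_null <- if (length(i_null)) {
    i_null[sample.int(length(i_null), n_expr)]
  } else integer(0)

  baseline <- numeric(n)
  baseline[i_null] <- stats::rnorm(length(i_null), bg, cfg$background_sd)
  baseline[expressed_null] <- baseline[expressed_null] + cfg$expressed_mean_shift
  baseline[c(i_up, i_down, i_on, i_off)] <- expr_level  # deterministic

  means <- matrix(rep(baseline, length(classes)), nrow = n,
                  dimnames = list(ids, classes))
  in_b <- classes %in% cfg$contrast$class_b
  in_a <- classes %in% cfg$contrast$class_a
  means[i_up, in_b] <- expr_level + cfg$de_effect
  means[i_down, in_b] <- expr_level - cfg$de_effect
  # switched-on: silent in class A, expressed in class B (mirror for off);
  # classes outside the contrast follow the silent level
  means[i_on, !in_b] <- low
  means[i_on, in_b] <- expr_level
  means[i_off, !in_a] <- low
  means[i_off, in_a] <- expr_level

  effect <- numeric(n)
  effect[i_up] <- cfg$de_effect
  effect[i_down] <- -cfg$de_effect
  effect[i_on] <- expr_level - low
  effect[i_off] <- -(expr_level - low)

  truth <- data.frame(
    probeset_id = ids, status = status, effect = effect,
    contrast = ifelse(status == "null", NA_character_, cfg$contrast$name),
    stringsAsFactors = FALSE
  )
  list(means = means, truth = truth)
}

sim_samples <- function(cfg, plan, tag = NULL) {
  classes <- names(cfg$samples_per_class)
  lab <- rep(classes, times = cfg$samples_per_class)
  sid <- unlist(lapply(classes, function(cl) {
    m <- cfg$samples_per_class[[cl]]
    if (m) sprintf("%s%s_%02d", cl, if (is.null(tag)) "" else paste0(".", tag),
                   seq_len(m)) else character(0)
  }), use.names = FALSE)
  mat <- plan$means[, lab, drop = FALSE]
  if (cfg$within_class_sd > 0) {
    mat <- mat + matrix(stats::rnorm(length(mat), 0, cfg$within_class_sd),
                        nrow = nrow(mat))
  }
  dimnames(mat) <- list(rownames(plan$means), sid)
  pheno <- data.frame(sample_id = sid, phenotype = lab,
                      stringsAsFactors = FALSE)
  list(matrix = mat, phenotypes = pheno)
}

#' Simulate an expression cohort with planted ground truth
#'
#' @param config A [sim_config()] object.
#' @return List with `matrix` (log2 intensities, probesets x samples),
#'   `phenotypes` (sample_id, phenotype) and `truth` (per-probeset status in
#'   \{null, de_up, de_down, onoff_on, onoff_off\}, true log2 effect,
#'   affected contrast). Deterministic given `config$seed`.
#' @examples
#' cohort <- simulate_expression_cohort(sim_config(n_probesets = 200, seed = 1))
#' table(cohort$truth$status)
#' @export
simulate_expression_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    plan <- sim_plan(config)
    cohort <- sim_samples(config, plan)
    list(matrix = cohort$matrix, phenotypes = cohort$phenotypes,
         truth = plan$truth, seed = config$seed)
  })
}

#' Simulate paired discovery and validation cohorts
#'
#' Both cohorts share one planted truth except for a randomly chosen
#' `1 - validation_fraction_concordant` subset of planted probesets whose
#' effect is removed in the validation cohort (they revert to a flat
#' expressed baseline for differential effects, or to the silent level for
#' on/off effects). Noise draws are independent between cohorts.
#'
#' @param config A [sim_config()] object.
#' @param validation_fraction_concordant Fraction in \[0, 1\] of planted
#'   effects retained in the validation cohort; the concordant subset has
#'   exactly `round(fraction * n_planted)` members.
#' @return List with `discovery` and `validation` cohorts (each as in
#'   [simulate_expression_cohort()]) and `truth`: the discovery truth plus a
#'   logical `concordant` column.
#' @export
simulate_paired_cohorts <- function(config, validation_fraction_concordant = 0.8) {
  stopifnot(inherits(config, "sim_config"))
  f <- validation_fraction_concordant
  if (length(f) != 1 || is.na(f) || f < 0 || f > 1) {
    stop("validation_fraction_concordant must lie in [0, 1]")
  }
  with_local_seed(config$seed, {
    plan <- sim_plan(config)
    discovery <- sim_samples(config, plan, tag = "d")

    planted <- which(plan$truth$status != "null")
    n_keep <- round(f * length(planted))
    keep <- if (length(planted)) {
      sort(planted[sample.int(length(planted), n_keep)])
    } else integer(0)
    drop <- setdiff(planted, keep)

    vplan <- plan
    if (length(drop)) {
      flat_level <- ifelse(grepl("^de_", plan$truth$status[drop]),
                           config$background_mean + config$expressed_mean_shift,
                           config$background_mean - config$background_sd)
      vplan$means[drop, ] <- flat_level
      vplan$truth$status[drop] <- "null"
      vplan$truth$effect[drop] <- 0
      vplan$truth$contrast[drop] <- NA_character_
    }
    validation <- sim_samples(config, vplan, tag = "v")

    truth <- plan$truth
    truth$concordant <- seq_len(nrow(truth)) %in% keep
    truth$concordant[truth$status == "null"] <- NA

    list(
      discovery = list(matrix = discovery$matrix,
                       phenotypes = discovery$phenotypes, truth = plan$truth),
      validation = list(matrix = validation$matrix,
                        phenotypes = validation$phenotypes,
                        truth = vplan$truth),
      truth = truth
    )
  })
}

#' Simulate a tissue qPCR experiment (target + endogenous reference)
#'
#' Generates replicate cycle-threshold values for a target gene and an
#' endogenous reference so that comparative-threshold analysis recovers the
#' supplied relative quantities: the target's true Ct is
#' `reference_ct + calibrator_delta_ct - log2(true_rq)`, i.e. each doubling of
#' relative quantity lowers the target Ct by one cycle.
#'
#' @param true_rq Numeric vector (> 0) of per-sample relative quantities; the
#'   calibrator sample should have `true_rq = 1`.
#' @param replicate_sd Replicate-level Ct noise SD (0 = exact).
#' @param n_replicates Replicates per (sample, target); assays are typically
#'   run in duplicate.
#' @param target,reference Assay names.
#' @param reference_ct True reference-gene Ct, identical across samples.
#' @param calibrator_delta_ct True delta-Ct (target - reference) of the
#'   calibrator sample.
#' @param seed Integer seed.
#' @return Long-format data frame (`sample_id`, `target`, `replicate`, `ct`)
#'   with attribute `"calibrator"` naming the first sample.
#' @export
simulate_tissue_qpcr <- function(true_rq, replicate_sd = 0.1,
                                 n_replicates = 2, target = "KIAA1199",
                                 reference = "HPRT1", reference_ct = 20,
                                 calibrator_delta_ct = 7, seed = 1L) {
  true_rq <- as.numeric(true_rq)
  if (any(!is.finite(true_rq)) || any(true_rq <= 0)) {
    stop("true_rq must be positive and finite")
  }
  n <- length(true_rq)
  sid <- sprintf("tissue_%02d", seq_len(n))
  with_local_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      ct_ref <- reference_ct +
        stats::rnorm(n_replicates, 0, replicate_sd)
      ct_tgt <- reference_ct + calibrator_delta_ct - log2(true_rq[i]) +
        stats::rnorm(n_replicates, 0, replicate_sd)
      data.frame(
        sample_id = sid[i],
        target = rep(c(target, reference), each = n_replicates),
        replicate = rep(seq_len(n_replicates), 2L),
        ct = c(ct_tgt, ct_ref),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    attr(out, "calibrator") <- sid[1]
    out
  })
}

#' Simulate a plasma qPCR panel with spike-in and dropout
#'
#' Emulates a circulating-RNA panel: triplicate Ct values for a low-abundance
#' target (KIAA1199), an abundant control (GAPDH) and an armored-RNA spike
#' added before extraction. A per-sample extraction-yield offset (SD
#' `yield_sd`) shifts all three targets of a sample identically — exactly the
#' error mode the spike-in normalization removes. Replicate dropout
#' (UNDETERMINED, stored as `NA`) is logistic in the replicate's underlying
#' Ct: detection probability `plogis((dropout_midpoint - ct) / dropout_slope)`,
#' so scarcer template (higher Ct) drops out more often.
#'
#' @param n_per_group Named counts for the `normal`, `adenoma`, `cancer`
#'   groups.
#' @param target_ct_mean,target_ct_sd Named per-group mean/SD of the true
#'   yield-free KIAA1199 Ct.
#' @param gapdh_ct_mean,gapdh_ct_sd Mean/SD of the true GAPDH Ct (all groups).
#' @param arm_ct True armored-RNA Ct, constant across samples by design.
#' @param yield_sd SD of the per-sample extraction-yield Ct offset.
#' @param replicate_sd Replicate-level Ct noise SD.
#' @param dropout_midpoint Ct at which detection probability is 50%; `Inf`
#'   disables dropout.
#' @param dropout_slope Logistic slope (cycles per logit).
#' @param dropout_targets Targets subject to dropout (default the
#'   low-abundance target only; the spike and GAPDH amplify reliably).
#' @param max_cycles Plasma assays run 60 cycles; Ct values are capped there
#'   (replicates beyond are undetermined).
#' @param seed Integer seed.
#' @return Long-format data frame (`sample_id`, `group`, `target`,
#'   `replicate`, `ct`; `NA` = UNDETERMINED) with attribute `"truth"` holding
#'   per-sample true yield-free Ct values and yield offsets.
#' @export
simulate_plasma_panel <- function(n_per_group = c(normal = 20, adenoma = 20,
                                                  cancer = 20),
                                  target_ct_mean = c(normal = 41,
                                                     adenoma = 38.5,
                                                     cancer = 36.5),
                                  target_ct_sd = c(normal = 1.5,
                                                   adenoma = 1.5,
                                                   cancer = 1.5),
                                  gapdh_ct_mean = 31, gapdh_ct_sd = 1,
                                  arm_ct = 28, yield_sd = 1,
                                  replicate_sd = 0.25,
                                  dropout_midpoint = 40, dropout_slope = 1.5,
                                  dropout_targets = "KIAA1199",
                                  max_cycles = 60, seed = 1L) {
  n_per_group <- unlist(n_per_group)  # tolerate YAML lists
  target_ct_mean <- unlist(target_ct_mean)
  target_ct_sd <- unlist(target_ct_sd)
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups))) {
    stop("n_per_group must be a named vector of group counts")
  }
  unknown <- setdiff(groups, c("normal", "adenoma", "cancer"))
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  }
  if (any(n_per_group <= 0)) stop("group counts must be positive")
  if (any(!groups %in% names(target_ct_mean))) {
    stop("target_ct_mean must name every group")
  }

  with_local_seed(seed, {
    grp <- rep(groups, times = n_per_group)
    n <- length(grp)
    sid <- sprintf("plasma_%s_%02d", grp,
                   unlist(lapply(n_per_group, seq_len), use.names = FALSE))
    sdv <- target_ct_sd[grp]
    true_target <- stats::rnorm(n, target_ct_mean[grp], sdv)
    true_gapdh <- stats::rnorm(n, gapdh_ct_mean, gapdh_ct_sd)
    yield <- stats::rnorm(n, 0, yield_sd)

    targets <- c("KIAA1199", "GAPDH", "armRNA")
    true_ct <- cbind(KIAA1199 = true_target, GAPDH = true_gapdh,
                     armRNA = rep(arm_ct, n))
    rows <- vector("list", n * length(targets))
    k <- 0L
    for (i in seq_len(n)) {
      for (tg in targets) {
        ct <- true_ct[i, tg] + yield[i] +
          stats::rnorm(3L, 0, replicate_sd)
        if (tg %in% dropout_targets && is.finite(dropout_midpoint)) {
          p_det <- stats::plogis((dropout_midpoint - ct) / dropout_slope)
          ct[stats::runif(3L) > p_det] <- NA_real_
        }
        ct[!is.na(ct) & ct > max_cycles] <- NA_real_
        k <- k + 1L
        rows[[k]] <- data.frame(sample_id = sid[i], group = grp[i],
                                target = tg, replicate = 1:3, ct = ct,
                                stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- data.frame(
      sample_id = sid, group = grp,
      true_ct_KIAA1199 = true_target, true_ct_GAPDH = true_gapdh,
      true_ct_armRNA = rep(arm_ct, n), yield_offset = yield,
      stringsAsFactors = FALSE
    )
    attr(out, "max_cycles") <- max_cycles
    out
  })
}
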