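# Convention used throughout: lower Ct = more abundant template, one cycle
# = one factor of two. Undetermined replicates are stored as NA and are
# never imputed at max_cycles; they are excluded from means and handled by
# the separate detection call.

#' Read / write a cycle-threshold table
#'
#' CSV with columns `sample_id`, (optional `group`,) `target`, `replicate`,
#' `ct`; the literal `UNDETERMINED` marks replicates with no amplification
#' and is stored as `NA`.
#'
#' @param path CSV file.
#' @return Data frame with numeric `ct` (`NA` = undetermined).
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "target", "replicate", "ct")
  if (!all(need %in% names(tab))) {
    stop("ct table needs columns: ", paste(need, collapse = ", "))
  }
  ct <- suppressWarnings(as.numeric(tab$ct))
  undet <- toupper(trimws(tab$ct)) %in% c("UNDETERMINED", "NA", "")
  if (any(is.na(ct) & !undet)) {
    stop("non-numeric ct value(s) that are not UNDETERMINED: ",
         paste(unique(tab$ct[is.na(ct) & !undet]), collapse = ", "))
  }
  tab$ct <- ct
  tab$replicate <- as.integer(tab$replicate)
  tab
}

#' @rdname read_ct_table
#' @param ct_table Data frame as returned by [read_ct_table()] or the
#'   simulators.
#' @return `write_ct_table`: `path`, invisibly.
#' @export
write_ct_table <- function(ct_table, path) {
  out <- ct_table
  out$ct <- ifelse(is.na(out$ct), "UNDETERMINED", sprintf("%.17g", out$ct))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse replicate Ct values to per-(sample, target) means
#'
#' The mean is taken over determined replicates only; a group with no
#' determined replicate gets `NA` and detected count 0.
#'
#' @param ct_table Long-format Ct table (`sample_id`, `target`, `ct`,
#'   optional `group`).
#' @return Data frame: `sample_id`, (`group`,) `target`, `mean_ct`,
#'   `n_replicates`, `n_detected`.
#' @export
collapse_replicates <- function(ct_table) {
  key <- interaction(ct_table$sample_id, ct_table$target, drop = TRUE,
                     lex.order = TRUE)
  pieces <- split(ct_table, key)
  out <- do.call(rbind, lapply(pieces, function(d) {
    det <- d$ct[!is.na(d$ct)]
    row <- data.frame(
      sample_id = d$sample_id[1], target = d$target[1],
      mean_ct = if (length(det)) mean(det) else NA_real_,
      n_replicates = nrow(d), n_detected = length(det),
      stringsAsFactors = FALSE
    )
    if ("group" %in% names(d)) row <- cbind(row[1], group = d$group[1],
                                            row[-1])
    row
  }))
  rownames(out) <- NULL
  out
}

#' Comparative-threshold (2^-ddCt) relative quantification
#'
#' Livak's method: `dCt = Ct_target - Ct_reference` per sample,
#' `ddCt = dCt - dCt_calibrator`, relative quantity `rq = 2^-ddCt`. The
#' calibrator sample has `ddCt = 0` and `rq = 1` by construction.
#'
#' @param ct_target,ct_reference Numeric vectors of mean Ct values, aligned
#'   by sample.
#' @param calibrator_delta_ct The calibrator sample's `dCt` (scalar).
#' @param sample_id Optional sample ids for the output.
#' @return Data frame: `sample_id`, `delta_ct`, `delta_delta_ct`, `rq`.
#' @examples
#' delta_delta_ct(25.1, 20.1, calibrator_delta_ct = 7)  # rq = 4
#' @export
delta_delta_ct <- function(ct_target, ct_reference, calibrator_delta_ct,
                           sample_id = NULL) {
  if (length(ct_target) != length(ct_reference)) {
    stop("ct_target and ct_reference differ in length")
  }
  if (anyNA(ct_target) || anyNA(ct_reference)) {
    stop("undetermined mean Ct; collapse replicates and check detection first")
  }
  if (length(calibrator_delta_ct) != 1 || is.na(calibrator_delta_ct)) {
    stop("calibrator_delta_ct must be a single determined value")
  }
  dct <- ct_target - ct_reference
  ddct <- dct - calibrator_delta_ct
  data.frame(
    sample_id = sample_id %||% as.character(seq_along(dct)),
    delta_ct = dct, delta_delta_ct = ddct, rq = 2^(-ddct),
    stringsAsFactors = FALSE
  )
}

#' Tissue qPCR relative quantification from a replicate table
#'
#' Collapses replicates, flags discordant duplicates (spread above
#' `discordance_limit` cycles, warning only), and applies [delta_delta_ct()]
#' with the named endogenous reference and calibrator sample.
#'
#' @param ct_table Long-format Ct table.
#' @param target,reference Assay names (e.g. `"KIAA1199"`, `"HPRT1"`).
#' @param calibrator Sample id whose relative quantity defines 1.
#' @param discordance_limit Max within-duplicate Ct spread before a QC
#'   warning (default 1.5 cycles).
#' @return Data frame as from [delta_delta_ct()], one row per sample.
#' @export
tissue_relative_quantity <- function(ct_table, target = "KIAA1199",
                                     reference = "HPRT1", calibrator,
                                     discordance_limit = 1.5) {
  spread <- tapply(ct_table$ct,
                   interaction(ct_table$sample_id, ct_table$target,
                               drop = TRUE),
                   function(v) diff(range(v[!is.na(v)])))
  bad <- names(spread)[!is.na(spread) & spread > discordance_limit]
  if (length(bad)) {
    warning("discordant replicates (spread > ", discordance_limit,
            " cycles): ", paste(bad, collapse = ", "))
  }
  coll <- collapse_replicates(ct_table)
  tgt <- coll[coll$target == target, ]
  ref <- coll[coll$target == reference, ]
  if (!nrow(ref)) stop("reference assay '", reference, "' missing")
  ids <- tgt$sample_id
  ref_ct <- ref$mean_ct[match(ids, ref$sample_id)]
  if (!calibrator %in% ids) stop("calibrator sample '", calibrator,
                                 "' not found")
  cal_dct <- tgt$mean_ct[ids == calibrator] - ref_ct[ids == calibrator]
  delta_delta_ct(tgt$mean_ct, ref_ct, cal_dct, sample_id = ids)
}

#' Spike-in (armored RNA) normalization of plasma Ct values
#'
#' Corrects per-sample extraction-yield differences using the armored-RNA
#' spike added to every plasma sample before extraction: the sample's Ct is
#' shifted by the amount its spike Ct deviates from the panel-wide mean
#' spike Ct, `ct - (ct_arm_sample - mean(ct_arm_panel))`. Any Ct offset
#' applied identically to all targets of a sample cancels exactly.
#'
#' @param ct Numeric vector of mean Ct values to normalize.
#' @param arm_ct_sample Matching vector of the same samples' spike Ct.
#' @param arm_ct_panel_mean Mean spike Ct over the complete panel (scalar).
#' @return Normalized Ct values; `NA` where the spike was undetected (such
#'   samples are extraction failures and should be excluded).
#' @export
normalize_plasma_ct <- function(ct, arm_ct_sample, arm_ct_panel_mean) {
  if (length(ct) != length(arm_ct_sample)) {
    stop("ct and arm_ct_sample differ in length")
  }
  if (anyNA(arm_ct_sample)) {
    warning(sum(is.na(arm_ct_sample)), " sample(s) with undetected spike-in ",
            "flagged as extraction failures (normalized Ct set to NA)")
  }
  ct - (arm_ct_sample - arm_ct_panel_mean)
}

#' Fold change relative to a reference group's median
#'
#' `FC = 2^(median_ref - ct)`: a sample two cycles below the reference
#' median has four-fold the reference abundance. The reference group's
#' median fold change is exactly 1.
#'
#' @param normalized_ct Numeric vector of (spike-normalized) Ct values; `NA`
#'   for undetected samples propagates.
#' @param group Group labels aligned with `normalized_ct`.
#' @param reference_group Label of the control group (default `"normal"`).
#' @return Numeric vector of fold changes.
#' @export
fold_change_vs_reference_group <- function(normalized_ct, group,
                                           reference_group = "normal") {
  ref <- normalized_ct[group == reference_group & !is.na(normalized_ct)]
  if (!length(ref)) {
    stop("reference group '", reference_group,
         "' has no detected samples")
  }
  2^(stats::median(ref) - normalized_ct)
}

#' Replicate-level detection call
#'
#' @param n_detected Number of determined replicates (vectorized), or a Ct
#'   table row subset's `ct` values via [collapse_replicates()].
#' @param min_detected_replicates Detection threshold (default 2, a majority
#'   of a triplicate).
#' @return Logical vector.
#' @export
detection_call <- function(n_detected, min_detected_replicates = 2) {
  n_detected >= min_detected_replicates
}

#' Plasma panel analysis
#'
#' Full plasma workflow for one target: collapse replicates, make detection
#' calls, spike-normalize with the armored-RNA panel mean, and express
#' detected samples as fold change versus the control-group median.
#'
#' @param ct_table Long-format plasma Ct table with a `group` column and
#'   targets including `target` and `"armRNA"`.
#' @param target Target assay (default `"KIAA1199"`).
#' @param reference_group Control group (default `"normal"`).
#' @param min_detected_replicates Detection rule threshold.
#' @return Data frame per sample: `sample_id`, `group`, `mean_ct`,
#'   `n_detected`, `detected`, `normalized_ct`, `fold_change` (NA when not
#'   detected).
#' @export
analyze_plasma <- function(ct_table, target = "KIAA1199",
                           reference_group = "normal",
                           min_detected_replicates = 2) {
  coll <- collapse_replicates(ct_table)
  tgt <- coll[coll$target == target, ]
  arm <- coll[coll$target == "armRNA", ]
  if (!nrow(arm)) stop("armRNA spike-in measurements missing")
  arm_ct <- arm$mean_ct[match(tgt$sample_id, arm$sample_id)]
  panel_mean <- mean(arm$mean_ct, na.rm = TRUE)

  detected <- detection_call(tgt$n_detected, min_detected_replicates)
  norm_ct <- normalize_plasma_ct(tgt$mean_ct, arm_ct, panel_mean)
  norm_ct[!detected] <- NA_real_

  grp <- if ("group" %in% names(tgt)) tgt$group else
    ct_table$group[match(tgt$sample_id, ct_table$sample_id)]
  fc <- rep(NA_real_, nrow(tgt))
  ok <- !is.na(norm_ct)
  if (any(ok & grp == reference_group)) {
    fc[ok] <- fold_change_vs_reference_group(norm_ct[ok], grp[ok],
                                             reference_group)
  } else {
    warning("no detected '", reference_group, "' samples; fold changes ",
            "not computed")
  }
  data.frame(sample_id = tgt$sample_id, group = grp,
             mean_ct = tgt$mean_ct, n_detected = tgt$n_detected,
             detected = detected, normalized_ct = norm_ct,
             fold_change = fc, stringsAsFactors = FALSE)
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two groups. For combined
#' sizes up to `exact_limit` with no ties the p-value is computed by full
#' enumeration of all group labelings; otherwise the normal approximation
#' with tie correction is used (no continuity correction, so identical
#' groups give p = 1). U is reported for `x` (number of (x, y) pairs with
#' x > y, plus half-ties).
#'
#' @param x,y Numeric vectors, both nonempty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_limit Max `length(x) + length(y)` for the exact path
#'   (default 12).
#' @return List with `U`, `p`, and `method` (`"exact"` or `"approximate"`).
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_exact <- function(x, y,
                               alternative = c("two.sided", "less",
                                               "greater"),
                               exact_limit = 12) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))

  if (n <= exact_limit && !ties) {
    ranks <- seq_len(n)
    combos <- utils::combn(n, nx)
    stats_all <- colSums(matrix(ranks[combos], nrow = nx)) -
      nx * (nx + 1) / 2
    p <- switch(alternative,
      two.sided = min(1, 2 * min(mean(stats_all <= U),
                                 mean(stats_all >= U))),
      less = mean(stats_all <= U),
      greater = mean(stats_all >= U))
    return(list(U = U, p = p, method = "exact"))
  }

  mu <- nx * ny / 2
  tie_tab <- table(pooled)
  sigma2 <- nx * ny / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(U = U, p = 1, method = "approximate"))
  }
  z <- (U - mu) / sqrt(sigma2)
  p <- switch(alternative,
    two.sided = min(1, 2 * stats::pnorm(-abs(z))),
    less = stats::pnorm(z),
    greater = stats::pnorm(z, lower.tail = FALSE))
  list(U = U, p = p, method = "approximate")
}

#' Penalized logistic classifier on cycle-threshold features
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares with a small ridge penalty on the slope coefficients
#' (intercept unpenalized). The penalty keeps the fit finite on perfectly
#' separated Ct data, which is plausible at these sample sizes.
#'
#' @param x Numeric vector or matrix of features (e.g. normalized Ct),
#'   samples in rows.
#' @param y Binary labels: logical, 0/1, or a factor whose second level is
#'   the positive (neoplasia) class.
#' @param lambda Ridge penalty on slopes (default 1e-4).
#' @param max_iter IRLS iteration cap (default 100); non-convergence is an
#'   error reporting the iteration count.
#' @param tol Convergence tolerance on the max coefficient change.
#' @return Object of class `"ct_logit"` with `coefficients`, `iterations`,
#'   `converged`, `lambda`.
#' @export
fit_logistic_classifier <- function(x, y, lambda = 1e-4, max_iter = 100,
                                    tol = 1e-10) {
  X <- cbind(`(Intercept)` = 1, as.matrix(x))
  if (is.null(colnames(X)) || any(!nzchar(colnames(X)[-1]))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  }
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1, logical or factor)")
  if (sum(y == 0) < 2 || sum(y == 1) < 2) {
    stop("need at least 2 samples per class to fit")
  }
  if (nrow(X) != length(y)) stop("x and y differ in length")

  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)), ncol(X))
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - p) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("IRLS did not converge within ", max_iter, " iterations")
  }
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, iterations = it, converged = converged,
                 lambda = lambda),
            class = "ct_logit")
}

#' @export
print.ct_logit <- function(x, ...) {
  cat("Penalized logistic Ct classifier (lambda =", x$lambda, ",",
      x$iterations, "IRLS iterations)\n")
  print(x$coefficients)
  invisible(x)
}

#' Predicted neoplasia probability
#'
#' @param object A fitted [fit_logistic_classifier()] model.
#' @param x Feature vector/matrix as used at fit time.
#' @param ... Unused.
#' @return Numeric vector of predicted probabilities.
#' @export
predict.ct_logit <- function(object, x, ...) {
  X <- cbind(1, as.matrix(x))
  stats::plogis(drop(X %*% object$coefficients))
}

#' Classify samples as neoplasia from cycle-threshold features
#'
#' Applies the inclusive 50% rule: a sample is classified as neoplasia
#' (adenoma or cancer) when the model's predicted probability is greater
#' than or equal to 0.5.
#'
#' @param model A fitted [fit_logistic_classifier()] model.
#' @param x Feature vector/matrix.
#' @return Logical vector, `TRUE` = neoplasia.
#' @export
classify_neoplasia <- function(model, x) {
  predict.ct_logit(model, x) >= 0.5
}
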