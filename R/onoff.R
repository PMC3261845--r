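#' Estimate the transcriptional silence threshold
#'
#' Most transcripts in a given tissue are not constitutively expressed above
#' the background floor, so a low quantile of the per-probeset mean intensity
#' distribution is a conservative upper bound on non-specific hybridization
#' signal. The per-probeset means (across all samples) are ranked and the
#' nearest-rank percentile — the observed value at index `ceiling(q * n)` of
#' the ascending means — is returned as the threshold, default the 30th
#' percentile.
#'
#' @param mat Expression matrix (log2), probesets x samples.
#' @param percentile Quantile in (0, 1); default 0.30.
#' @return Object of class `"silence_threshold"`: list with `tau` (log2
#'   intensity), `percentile`, and `n_probesets_used`.
#' @export
silence_threshold <- function(mat, percentile = 0.30) {
  check_expression_matrix(mat)
  if (length(percentile) != 1 || is.na(percentile) ||
      percentile <= 0 || percentile >= 1) {
    stop("percentile must lie strictly within (0, 1)")
  }
  means <- sort(rowMeans(mat))
  tau <- means[ceiling(percentile * length(means))]
  structure(list(tau = unname(tau), percentile = percentile,
                 n_probesets_used = length(means)),
            class = "silence_threshold")
}

#' @export
print.silence_threshold <- function(x, ...) {
  cat(sprintf("Silence threshold: tau = %.4f log2 units (nearest-rank %g%%
of %d per-probeset means)\n", x$tau, 100 * x$percentile,
              x$n_probesets_used))
  invisible(x)
}

#' Classify probesets as switched-on/off between phenotype classes
#'
#' Filters differentially expressed probesets for transcripts qualitatively
#' expressed in one phenotype class and silent in the comparator. A class is
#' called "off" when its sample quantile (default the median) falls below
#' `tau - margin` and "on" when it is at least `tau + margin` (ties at the
#' threshold count as on). A probeset is `on_in_b` when class A is off and
#' class B on — provided it passed the contrast's differential expression
#' filter — and `off_in_b` in the mirror case; probesets on (off) in both
#' classes are `expressed_both` (`silent_both`), and everything else,
#' including on/off patterns lacking DE support or medians inside the margin
#' band, is `indeterminate`.
#'
#' @param mat Expression matrix used for the contrast.
#' @param phenotypes Phenotype table.
#' @param contrast The contrast defining class A and class B.
#' @param threshold A [silence_threshold()] object (or a bare tau value).
#' @param de_results [run_contrast()] output for the same matrix/contrast;
#'   its `significant` column gates eligibility. Pass `NULL` to drop the DE
#'   requirement.
#' @param class_call_quantile Sample quantile summarizing each class
#'   (default 0.5, the class median).
#' @param margin Symmetric dead band (log2 units) around tau within which a
#'   class call is indeterminate; default 0.
#' @return Data frame: `probeset_id`, `status`, `class_a_summary`,
#'   `class_b_summary`, `tau`, `de_significant`.
#' @export
classify_onoff <- function(mat, phenotypes, contrast, threshold,
                           de_results = NULL, class_call_quantile = 0.5,
                           margin = 0) {
  check_expression_matrix(mat)
  tau <- if (inherits(threshold, "silence_threshold")) threshold$tau
         else as.numeric(threshold)
  if (inherits(threshold, "silence_threshold") &&
      threshold$n_probesets_used != nrow(mat)) {
    stop("threshold was estimated on ", threshold$n_probesets_used,
         " probesets but the matrix has ", nrow(mat))
  }
  idx <- resolve_contrast(mat, phenotypes, contrast)
  qa <- apply(mat[, idx$idx_a, drop = FALSE], 1, stats::quantile,
              probs = class_call_quantile, names = FALSE)
  qb <- apply(mat[, idx$idx_b, drop = FALSE], 1, stats::quantile,
              probs = class_call_quantile, names = FALSE)

  if (!is.null(de_results)) {
    if (!all(rownames(mat) %in% de_results$probeset_id)) {
      stop("de_results do not cover every probeset in the matrix")
    }
    sig <- de_results$significant[match(rownames(mat),
                                        de_results$probeset_id)]
  } else {
    sig <- rep(TRUE, nrow(mat))
  }

  call_class <- function(q) {
    ifelse(q >= tau + margin, "on", ifelse(q < tau - margin, "off", "mid"))
  }
  ca <- call_class(qa)
  cb <- call_class(qb)
  status <- rep("indeterminate", nrow(mat))
  status[ca == "on" & cb == "on"] <- "expressed_both"
  status[ca == "off" & cb == "off"] <- "silent_both"
  status[ca == "off" & cb == "on" & sig] <- "on_in_b"
  status[ca == "on" & cb == "off" & sig] <- "off_in_b"

  data.frame(probeset_id = rownames(mat), status = status,
             class_a_summary = unname(qa), class_b_summary = unname(qb),
             tau = tau, de_significant = sig,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract phenotype-specific candidate lists from on/off calls
#'
#' @param calls Output of [classify_onoff()].
#' @return List with data frames `switched_on` (status `on_in_b`) and
#'   `switched_off` (status `off_in_b`).
#' @export
phenotype_specific_candidates <- function(calls) {
  list(switched_on = calls[calls$status == "on_in_b", , drop = FALSE],
       switched_off = calls[calls$status == "off_in_b", , drop = FALSE])
}
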