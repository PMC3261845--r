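#' Build a candidate list from discovery results
#'
#' Selects the discovery probesets carried forward to validation: significant
#' in the discovery contrast, optionally restricted to at least two-fold
#' changers, with their discovery direction and log2 fold change.
#'
#' @param de_results [run_contrast()] output from the discovery cohort.
#' @param require_fc2 Keep only probesets with `|log2fc| >= 1` (default
#'   `TRUE`, the discovery filter used before designing a validation panel).
#' @return Data frame (`probeset_id`, `direction`, `discovery_log2fc`).
#' @export
candidate_list <- function(de_results, require_fc2 = TRUE) {
  keep <- de_results$significant & !is.na(de_results$direction)
  if (require_fc2) keep <- keep & de_results$fc2_flag
  out <- data.frame(probeset_id = de_results$probeset_id[keep],
                    direction = de_results$direction[keep],
                    discovery_log2fc = de_results$log2fc[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Translate candidates to another platform via two mapping tables
#'
#' Discovery probesets are annotated to gene symbols (`forward_map`) and the
#' symbols reverse-mapped to the validation platform's probesets
#' (`reverse_map`); each candidate expands to all composed targets, keeping
#' the discovery probeset as provenance. A validation probeset reached via
#' several symbols or several source candidates is emitted once (first
#' occurrence wins; a conflicting direction triggers a warning).
#'
#' @param candidates Data frame from [candidate_list()] (columns
#'   `probeset_id`, `direction`, optionally `discovery_log2fc`).
#' @param forward_map,reverse_map [read_mapping()]-style data frames
#'   (`source_id`, `target_id`).
#' @return List with `translated` (columns `probeset_id`, `direction`,
#'   `discovery_log2fc`, `source_id`, `symbol`) and `unmapped` (source ids
#'   with no composed target).
#' @export
translate_candidates <- function(candidates, forward_map, reverse_map) {
  rows <- vector("list", nrow(candidates))
  unmapped <- character(0)
  for (i in seq_len(nrow(candidates))) {
    src <- candidates$probeset_id[i]
    syms <- forward_map$target_id[forward_map$source_id == src]
    hits <- reverse_map[reverse_map$source_id %in% syms, , drop = FALSE]
    if (!nrow(hits)) {
      unmapped <- c(unmapped, src)
      next
    }
    hits <- hits[!duplicated(hits$target_id), , drop = FALSE]
    rows[[i]] <- data.frame(
      probeset_id = hits$target_id,
      direction = candidates$direction[i],
      discovery_log2fc = if ("discovery_log2fc" %in% names(candidates))
        candidates$discovery_log2fc[i] else NA_real_,
      source_id = src,
      symbol = hits$source_id,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(probeset_id = character(0), direction = character(0),
                      discovery_log2fc = numeric(0), source_id = character(0),
                      symbol = character(0), stringsAsFactors = FALSE)
  }
  dup <- duplicated(out$probeset_id)
  if (any(dup)) {
    first_dir <- out$direction[match(out$probeset_id, out$probeset_id)]
    if (any(out$direction[dup] != first_dir[dup])) {
      warning("conflicting directions for duplicated validation target(s); ",
              "keeping first occurrence")
    }
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  list(translated = out, unmapped = unique(unmapped))
}

#' Validate candidates on an independent cohort
#'
#' Tests each candidate on the validation cohort and counts directional
#' concordance: a candidate validates iff its adjusted p-value (default
#' Benjamini-Hochberg over the candidate set, the validation panel being a
#' pre-specified hypothesis list) is at most `alpha` and its observed
#' direction matches the discovery direction; the two-fold subcount
#' additionally requires `|log2fc| >= 1`. Candidates absent from the
#' validation matrix are excluded from the denominator and reported.
#'
#' @param candidates Data frame with `probeset_id` and `direction` (from
#'   [candidate_list()] or [translate_candidates()]).
#' @param mat,phenotypes,contrast Validation cohort and contrast.
#' @param alpha Significance level (inclusive, on adjusted p).
#' @param method Correction method (default `"bh"`).
#' @param scope `"candidates"` corrects over the candidate set only;
#'   `"chip"` corrects over the full validation matrix.
#' @return Object of class `"concordance_report"`: list with `by_direction`
#'   (per direction: `n_candidates`, `n_validated`, `n_validated_fc2` and
#'   fractions), `detail` (per-candidate results), `missing` (ids absent
#'   from the validation matrix), and the contrast name.
#' @export
validate_candidates <- function(candidates, mat, phenotypes, contrast,
                                alpha = 0.05, method = "bh",
                                scope = c("candidates", "chip")) {
  scope <- match.arg(scope)
  ids <- unique(candidates$probeset_id)
  present <- ids[ids %in% rownames(mat)]
  missing <- setdiff(ids, present)
  if (length(missing)) {
    message(length(missing), " candidate(s) absent from the validation ",
            "matrix; excluded from the denominator")
  }
  test_mat <- if (scope == "candidates") {
    mat[present, , drop = FALSE]
  } else {
    mat
  }
  res <- run_contrast(test_mat, phenotypes, contrast, method = method,
                      alpha = alpha)
  res <- res[match(present, res$probeset_id), , drop = FALSE]

  cand <- candidates[match(present, candidates$probeset_id), , drop = FALSE]
  validated <- res$significant & !is.na(res$direction) &
    res$direction == cand$direction
  validated_fc2 <- validated & res$fc2_flag

  detail <- data.frame(
    probeset_id = present,
    direction = cand$direction,
    log2fc = res$log2fc, p_adj = res$p_adj,
    validated = validated, validated_fc2 = validated_fc2,
    stringsAsFactors = FALSE
  )
  by_dir <- do.call(rbind, lapply(c("up", "down"), function(d) {
    sel <- cand$direction == d
    n <- sum(sel)
    data.frame(direction = d, n_candidates = n,
               n_validated = sum(validated[sel]),
               n_validated_fc2 = sum(validated_fc2[sel]),
               fraction_validated = if (n) sum(validated[sel]) / n else NA_real_,
               fraction_validated_fc2 = if (n) sum(validated_fc2[sel]) / n
                                        else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(by_direction = by_dir, detail = detail, missing = missing,
                 contrast = contrast$name, alpha = alpha, method = method),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Validation concordance for contrast '", x$contrast, "' (",
      toupper(x$method), ", alpha = ", x$alpha, ")\n", sep = "")
  print(x$by_direction, row.names = FALSE)
  if (length(x$missing)) {
    cat(length(x$missing), "candidate(s) absent from the validation matrix\n")
  }
  invisible(x)
}

#' Tabulate concordance reports across contrasts
#'
#' @param reports A single report or list of [validate_candidates()] reports.
#' @return Data frame, one row per (contrast, direction).
#' @export
concordance_summary <- function(reports) {
  if (inherits(reports, "concordance_report")) reports <- list(reports)
  if (!length(reports)) {
    return(data.frame(contrast = character(0), direction = character(0),
                      n_candidates = integer(0), n_validated = integer(0),
                      n_validated_fc2 = integer(0),
                      fraction_validated = numeric(0),
                      fraction_validated_fc2 = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(reports, function(r) {
    cbind(contrast = r$contrast, r$by_direction, stringsAsFactors = FALSE)
  }))
}
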