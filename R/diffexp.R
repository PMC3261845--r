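#' Define a phenotype contrast
#'
#' A contrast names two disjoint sets of phenotype labels. Differential
#' expression is always reported for class B relative to class A, so "up"
#' means higher expression in class B.
#'
#' @param name Short label for the contrast (used in summaries).
#' @param class_a Character vector of phenotype labels forming class A.
#' @param class_b Character vector of phenotype labels forming class B.
#' @return An object of class `"contrast"`.
#' @examples
#' define_contrast("neoplasia", c("normal", "IBD"), c("adenoma", "cancer"))
#' @export
define_contrast <- function(name, class_a, class_b) {
  class_a <- unique(as.character(class_a))
  class_b <- unique(as.character(class_b))
  if (!length(class_a) || !length(class_b)) {
    stop("both contrast classes must be nonempty")
  }
  if (length(intersect(class_a, class_b))) {
    stop("contrast classes overlap: ",
         paste(intersect(class_a, class_b), collapse = ", "))
  }
  structure(list(name = as.character(name)[1],
                 class_a = class_a, class_b = class_b),
            class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat("Contrast '", x$name, "': {", paste(x$class_a, collapse = ", "),
      "} vs {", paste(x$class_b, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Reverse a contrast (swap class A and class B)
#'
#' @param contrast A [define_contrast()] object.
#' @return The contrast with the two classes exchanged.
#' @export
reverse_contrast <- function(contrast) {
  define_contrast(paste0(contrast$name, "_reversed"),
                  contrast$class_b, contrast$class_a)
}

# Resolve sample indices of a contrast against a matrix + phenotype table.
resolve_contrast <- function(mat, pheno, contrast) {
  pheno <- as_phenotype_table(pheno, sample_ids = colnames(mat))
  lab <- pheno$phenotype[match(colnames(mat), pheno$sample_id)]
  missing_classes <- setdiff(c(contrast$class_a, contrast$class_b), lab)
  idx_a <- which(lab %in% contrast$class_a)
  idx_b <- which(lab %in% contrast$class_b)
  if (length(idx_a) < 2L || length(idx_b) < 2L) {
    stop("contrast '", contrast$name, "' resolves fewer than 2 samples per ",
         "side", if (length(missing_classes))
           paste0("; phenotypes absent from the cohort: ",
                  paste(missing_classes, collapse = ", ")))
  }
  list(idx_a = idx_a, idx_b = idx_b)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Equal-variance two-sided t-test for a difference in means, the per-probeset
#' test used throughout the discovery and validation contrasts. Degenerate
#' inputs are defined rather than errors: two constant, equal groups give
#' t = 0, p = 1; zero pooled variance with unequal means gives p = 0 with
#' `degenerate = TRUE` (this arises only on noise-free synthetic data and must
#' not poison multiple-testing correction with NaN).
#'
#' @param a,b Numeric vectors of log2 intensities, each of length >= 2.
#' @return List with elements `t`, `df`, `p` and logical `degenerate`.
#' @examples
#' student_t_two_sample(c(1, 2, 3), c(3, 4, 5))
#' @export
student_t_two_sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  delta <- mean(b) - mean(a)
  if (sp2 <= 0) {
    if (delta == 0) {
      return(list(t = 0, df = df, p = 1, degenerate = FALSE))
    }
    return(list(t = sign(delta) * Inf, df = df, p = 0, degenerate = TRUE))
  }
  tt <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df), degenerate = FALSE)
}

#' Multiple hypothesis testing correction
#'
#' Bonferroni (used at discovery) or Benjamini-Hochberg step-up (used at
#' validation) adjustment, delegated to [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(tolower(method[1]), c("bonferroni", "bh"))
  p <- as.numeric(p)
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Per-probeset differential expression for one contrast
#'
#' Runs the pooled two-sample t-test on every probeset for the given contrast,
#' adjusts p-values over the probesets tested (no cross-contrast pooling), and
#' annotates direction and the two-fold-change flag (`|log2fc| >= 1`).
#'
#' @param mat Numeric matrix of log2 intensities, probesets x samples.
#' @param phenotypes Phenotype table (`sample_id`, `phenotype`) or labelled
#'   vector.
#' @param contrast A [define_contrast()] object.
#' @param method Correction method passed to [adjust_pvalues()].
#' @param alpha Significance level applied to adjusted p-values (inclusive:
#'   `p_adj <= alpha`).
#' @param strict Logical; if `TRUE` the significance rule is strict
#'   (`p_adj < alpha`).
#' @return Data frame with one row per probeset: `probeset_id`, `mean_a`,
#'   `mean_b`, `log2fc` (mean B minus mean A), `t`, `df`, `p_raw`, `p_adj`,
#'   `direction` (`"up"` = higher in class B), `fc2_flag`, `significant`,
#'   `degenerate`. The contrast, method and alpha are kept as attributes.
#' @export
run_contrast <- function(mat, phenotypes, contrast,
                         method = c("bonferroni", "bh"), alpha = 0.05,
                         strict = FALSE) {
  check_expression_matrix(mat)
  method <- match.arg(tolower(method[1]), c("bonferroni", "bh"))
  idx <- resolve_contrast(mat, phenotypes, contrast)
  A <- mat[, idx$idx_a, drop = FALSE]
  B <- mat[, idx$idx_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  lfc <- mb - ma

  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- lfc / se
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- sp2 <= 0 & lfc != 0
  flat <- sp2 <= 0 & lfc == 0
  tt[degen] <- sign(lfc[degen]) * Inf
  p[degen] <- 0
  tt[flat] <- 0
  p[flat] <- 1

  p_adj <- adjust_pvalues(p, method)
  sig <- if (strict) p_adj < alpha else p_adj <= alpha
  res <- data.frame(
    probeset_id = rownames(mat),
    mean_a = ma, mean_b = mb, log2fc = lfc,
    t = tt, df = df, p_raw = p, p_adj = p_adj,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", NA_character_)),
    fc2_flag = abs(lfc) >= 1,
    significant = sig,
    degenerate = degen,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "contrast") <- contrast
  attr(res, "method") <- method
  attr(res, "alpha") <- alpha
  res
}

#' Summarize differential expression across contrasts
#'
#' Tabulates, per contrast, the number of significant probesets, the subset
#' also changing at least two-fold, and the up/down split of that subset
#' (the layout of a discovery summary table).
#'
#' @param results A single [run_contrast()] result or a list of them.
#' @param alpha Significance level (inclusive) applied to `p_adj`.
#' @return Data frame with columns `contrast`, `n_tested`, `n_sig`,
#'   `n_sig_fc2`, `n_up`, `n_down`; `n_up + n_down == n_sig_fc2`.
#' @export
summarize_contrasts <- function(results, alpha = 0.05) {
  if (is.data.frame(results)) results <- list(results)
  rows <- lapply(results, function(res) {
    ctr <- attr(res, "contrast")
    sig <- res$p_adj <= alpha
    sig_fc2 <- sig & res$fc2_flag
    data.frame(
      contrast = if (!is.null(ctr)) ctr$name else NA_character_,
      n_tested = nrow(res),
      n_sig = sum(sig),
      n_sig_fc2 = sum(sig_fc2),
      n_up = sum(sig_fc2 & res$direction == "up", na.rm = TRUE),
      n_down = sum(sig_fc2 & res$direction == "down", na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Principal component scores of an expression matrix
#'
#' Sample-level PCA scores from the singular value decomposition of the
#' probeset-centered matrix, the genome-wide view used to check that the
#' dominant source of variance tracks neoplastic status.
#'
#' @param mat Numeric matrix, probesets x samples.
#' @param k Number of components (`k <= min(dim(mat))`).
#' @return List with `scores` (samples x k matrix, columns `PC1..PCk`) and
#'   `var_fraction` (fraction of total variance per component, nonincreasing).
#' @export
pc_scores <- function(mat, k = 2) {
  check_expression_matrix(mat)
  if (k < 1 || k > min(dim(mat))) {
    stop("k must be between 1 and min(dim(mat)) = ", min(dim(mat)))
  }
  centred <- mat - rowMeans(mat)
  sv <- svd(centred, nu = 0, nv = k)
  scores <- sv$v * rep(sv$d[seq_len(k)], each = nrow(sv$v))
  dimnames(scores) <- list(colnames(mat), paste0("PC", seq_len(k)))
  list(scores = scores, var_fraction = (sv$d^2 / sum(sv$d^2))[seq_len(k)])
}
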