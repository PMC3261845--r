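# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Coerce the accepted phenotype representations to the canonical two-column
# data.frame (sample_id, phenotype).
as_phenotype_table <- function(phenotypes, sample_ids = NULL) {
  if (is.data.frame(phenotypes)) {
    if (!all(c("sample_id", "phenotype") %in% names(phenotypes))) {
      stop("phenotype table must have columns 'sample_id' and 'phenotype'")
    }
    out <- data.frame(
      sample_id = as.character(phenotypes$sample_id),
      phenotype = as.character(phenotypes$phenotype),
      stringsAsFactors = FALSE
    )
  } else if (is.character(phenotypes) || is.factor(phenotypes)) {
    labs <- as.character(phenotypes)
    ids <- names(phenotypes)
    if (is.null(ids)) ids <- sample_ids
    if (is.null(ids)) {
      stop("positional phenotype labels need sample ids ",
           "(named vector, sample_ids=, or a labelled matrix)")
    }
    if (length(ids) != length(labs)) {
      stop("phenotype labels and sample ids differ in length (",
           length(labs), " vs ", length(ids), ")")
    }
    out <- data.frame(sample_id = as.character(ids), phenotype = labs,
                      stringsAsFactors = FALSE)
  } else {
    stop("unsupported phenotype representation: ", class(phenotypes)[1])
  }
  dup <- out$sample_id[duplicated(out$sample_id)]
  if (length(dup)) {
    stop("duplicate sample ids in phenotype table: ",
         paste(unique(dup), collapse = ", "))
  }
  out
}

check_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs probeset rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate probeset ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids")
  if (any(!is.finite(mat))) stop("expression matrix contains non-finite values")
  invisible(mat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
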