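#' Read an expression matrix (GCT 1.2 or TSV)
#'
#' GCT 1.2 is the two-header-line dense format: `#1.2`, then
#' `<n_rows>\t<n_cols>`, then a table with `Name` and `Description` columns
#' followed by one column per sample. The TSV dialect is the same table
#' without the two header lines or the Description column. Values are log2
#' intensities; parsing is strict — dimension mismatches, duplicate ids and
#' non-numeric cells are errors (with the offending line), never coerced.
#'
#' @param path File to read.
#' @param format `"gct"` or `"tsv"`.
#' @return Numeric matrix, probesets in rows, samples in columns.
#' @export
read_expression <- function(path, format = c("gct", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (format == "gct") {
    if (length(lines) < 3L || !startsWith(lines[1], "#1.2")) {
      stop("not a GCT 1.2 file (line 1 must be '#1.2'): ", path)
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
    if (length(dims) != 2L || anyNA(dims)) {
      stop("GCT line 2 must hold '<rows>\\t<columns>': ", path)
    }
    body <- lines[-(1:2)]
    skip <- 2L
    id_cols <- 2L
  } else {
    body <- lines
    dims <- NULL
    skip <- 0L
    id_cols <- 1L
  }
  body <- body[nzchar(body)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-seq_len(id_cols)]
  n_rows <- length(body) - 1L
  if (!is.null(dims)) {
    if (dims[1] != n_rows) {
      stop("GCT header declares ", dims[1], " rows but body has ", n_rows,
           " (line ", skip + 1L, ")")
    }
    if (dims[2] != length(sample_ids)) {
      stop("GCT header declares ", dims[2], " samples but body has ",
           length(sample_ids), " (line ", skip + 1L, ")")
    }
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (n_rows == 0L) {
    return(matrix(numeric(0), nrow = 0, ncol = length(sample_ids),
                  dimnames = list(character(0), sample_ids)))
  }
  ids <- character(n_rows)
  vals <- matrix(NA_real_, n_rows, length(sample_ids))
  for (i in seq_len(n_rows)) {
    fields <- strsplit(body[i + 1L], "\t", fixed = TRUE)[[1]]
    line_no <- skip + 1L + i
    if (length(fields) != id_cols + length(sample_ids)) {
      stop("line ", line_no, ": expected ", id_cols + length(sample_ids),
           " fields, found ", length(fields))
    }
    ids[i] <- fields[1]
    v <- suppressWarnings(as.numeric(fields[-seq_len(id_cols)]))
    if (anyNA(v)) {
      bad <- fields[-seq_len(id_cols)][is.na(v)][1]
      stop("line ", line_no, ": non-numeric expression value '", bad, "'")
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(ids)) {
    stop("duplicate probeset ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  dimnames(vals) <- list(ids, sample_ids)
  check_expression_matrix(vals)
  vals
}

#' Write an expression matrix (GCT 1.2 or TSV)
#'
#' Values are printed at full double precision (`%.17g`) so that
#' [read_expression()] inverts the write bit-exactly.
#'
#' @param mat Numeric matrix, probesets x samples; non-finite values are
#'   refused.
#' @param path Output file.
#' @param format `"gct"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, format = c("gct", "tsv")) {
  format <- match.arg(format)
  if (nrow(mat) > 0) check_expression_matrix(mat)
  if (any(!is.finite(mat))) stop("refusing to write non-finite values")
  fmt_row <- function(pre, v) paste(c(pre, sprintf("%.17g", v)), collapse = "\t")
  lines <- character(0)
  if (format == "gct") {
    lines <- c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t"),
               paste(c("Name", "Description", colnames(mat)), collapse = "\t"))
    if (nrow(mat)) {
      lines <- c(lines, vapply(seq_len(nrow(mat)), function(i) {
        fmt_row(c(rownames(mat)[i], "na"), mat[i, ])
      }, character(1)))
    }
  } else {
    lines <- paste(c("probeset_id", colnames(mat)), collapse = "\t")
    if (nrow(mat)) {
      lines <- c(lines, vapply(seq_len(nrow(mat)), function(i) {
        fmt_row(rownames(mat)[i], mat[i, ])
      }, character(1)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read phenotype labels (two-column TSV or CLS)
#'
#' The TSV dialect has a header `sample_id\tphenotype`. CLS is the positional
#' categorical format (`<n> <k> 1`, `# label...`, assignment line of indices
#' or label names); it carries no sample ids, so the returned labels are
#' positional — pass `sample_ids` (e.g. `colnames(mat)`) to attach them, or
#' let [align_phenotypes()] do it.
#'
#' @param path File to read.
#' @param format `"tsv"` or `"cls"`.
#' @param sample_ids Optional ids for CLS input, matrix column order.
#' @return Data frame (`sample_id`, `phenotype`), or for CLS without
#'   `sample_ids` a character vector of labels in file order.
#' @export
read_phenotypes <- function(path, format = c("tsv", "cls"),
                            sample_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character")
    if (!all(c("sample_id", "phenotype") %in% names(tab))) {
      stop("phenotype TSV needs header columns 'sample_id' and 'phenotype'")
    }
    return(as_phenotype_table(tab))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("CLS file needs 3 lines: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
  labels <- strsplit(trimws(sub("^#", "", lines[2])), "[ \t]+")[[1]]
  labels <- labels[nzchar(labels)]
  toks <- strsplit(trimws(lines[3]), "[ \t]+")[[1]]
  if (length(toks) != hdr[1]) {
    stop("CLS declares ", hdr[1], " samples but assignment line has ",
         length(toks))
  }
  if (length(labels) != hdr[2]) {
    stop("CLS declares ", hdr[2], " classes but names ", length(labels))
  }
  if (all(grepl("^[0-9]+$", toks))) {
    idx <- as.integer(toks) + 1L  # CLS indices are 0-based
    if (any(idx < 1L | idx > length(labels))) {
      stop("CLS class index out of range")
    }
    lab <- labels[idx]
  } else {
    if (!all(toks %in% labels)) {
      stop("CLS assignment uses unknown label(s): ",
           paste(setdiff(toks, labels), collapse = ", "))
    }
    lab <- toks
  }
  if (is.null(sample_ids)) return(lab)
  as_phenotype_table(lab, sample_ids = sample_ids)
}

#' Write phenotype labels
#'
#' @param phenotypes Phenotype table (`sample_id`, `phenotype`).
#' @param path Output file.
#' @param format `"tsv"` or `"cls"` (CLS drops the sample ids and keeps
#'   order).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path, format = c("tsv", "cls")) {
  format <- match.arg(format)
  pheno <- as_phenotype_table(phenotypes)
  if (format == "tsv") {
    utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    labels <- unique(pheno$phenotype)
    idx <- match(pheno$phenotype, labels) - 1L
    writeLines(c(paste(nrow(pheno), length(labels), 1),
                 paste("#", paste(labels, collapse = " ")),
                 paste(idx, collapse = " ")), path)
  }
  invisible(path)
}

#' Read a two-column id mapping table
#'
#' Many-to-many mappings (e.g. probeset to gene symbol, symbol to exon-level
#' probeset) as headered two-column TSV. Repeated pairs are deduplicated with
#' a warning.
#'
#' @param path File with a header line and two tab-separated columns.
#' @return Data frame with columns `source_id`, `target_id`, unique pairs.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("mapping file needs two columns: ", path)
  out <- data.frame(source_id = tab[[1]], target_id = tab[[2]],
                    stringsAsFactors = FALSE)
  if (any(!nzchar(out$source_id)) || any(!nzchar(out$target_id))) {
    stop("mapping file contains empty ids: ", path)
  }
  dup <- duplicated(out)
  if (any(dup)) {
    warning(sum(dup), " duplicated mapping pair(s) removed from ", path)
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Align an expression matrix with its phenotype table
#'
#' Checks that every matrix sample has exactly one phenotype label, reorders
#' the table to matrix column order, and warns about labelled samples absent
#' from the matrix (they are dropped). Unlabelled matrix samples are an
#' error naming each one. A bare label vector (e.g. from a CLS file) is
#' matched positionally to the matrix columns.
#'
#' @param mat Expression matrix.
#' @param phenotypes Phenotype table or label vector.
#' @return List with `matrix` and the aligned `phenotypes` table.
#' @export
align_phenotypes <- function(mat, phenotypes) {
  check_expression_matrix(mat)
  pheno <- as_phenotype_table(phenotypes, sample_ids = colnames(mat))
  extra <- setdiff(pheno$sample_id, colnames(mat))
  if (length(extra)) {
    warning("ignoring ", length(extra), " labelled sample(s) absent from ",
            "the matrix: ", paste(extra, collapse = ", "))
  }
  missing <- setdiff(colnames(mat), pheno$sample_id)
  if (length(missing)) {
    stop("unlabelled sample(s): ", paste(missing, collapse = ", "))
  }
  pheno <- pheno[match(colnames(mat), pheno$sample_id), , drop = FALSE]
  rownames(pheno) <- NULL
  list(matrix = mat, phenotypes = pheno)
}
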