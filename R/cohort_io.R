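# Tabular formats: FPKM expression, clinical, discrete copy-number calls,
# cell-line panels. All tables are TSV, UTF-8, "." decimal, unquoted; gene
# symbols are case-preserved and matched case-sensitively.

.stop_if_dup <- function(x, what, where) {
  d <- unique(x[duplicated(x)])
  if (length(d))
    stop(where, ": duplicate ", what, ": ", paste(d, collapse = ", "))
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    fill = FALSE)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.gene_table_to_matrix <- function(df, path, integer_calls = FALSE) {
  if (names(df)[1] != "gene")
    stop(path, ": first column must be named 'gene', got '", names(df)[1], "'")
  .stop_if_dup(df$gene, "gene symbol(s)", path)
  .stop_if_dup(names(df)[-1], "sample id(s)", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(path, ": non-numeric values in table")
  rownames(m) <- df$gene
  m
}

#' Read / write an FPKM expression matrix
#'
#' TSV with a leading `gene` column and one column per sample. Values must be
#' non-negative FPKM; violations are reported with their row/column
#' coordinates.
#'
#' @param path File path.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path) {
  m <- .gene_table_to_matrix(.read_tsv(path), path)
  validate_expression(m, where = path)
  m
}

#' @param matrix Genes-by-samples numeric matrix with dimnames.
#' @rdname read_expression
#' @export
write_expression <- function(matrix, path) {
  validate_expression(matrix)
  .write_tsv(data.frame(gene = rownames(matrix), matrix,
                        check.names = FALSE), path)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks: numeric, no missing values, no negative values, unique gene
#' symbols and sample ids.
#'
#' @param matrix Genes-by-samples matrix.
#' @param where Label used in error messages.
#' @return The matrix, invisibly.
#' @export
validate_expression <- function(matrix, where = "expression matrix") {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop(where, ": must be a numeric matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop(where, ": gene and sample names are required")
  .stop_if_dup(rownames(matrix), "gene symbol(s)", where)
  .stop_if_dup(colnames(matrix), "sample id(s)", where)
  if (anyNA(matrix)) stop(where, ": missing values are not allowed")
  neg <- which(matrix < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(where, ": negative FPKM value at gene '",
         rownames(matrix)[neg[1, 1]], "', sample '",
         colnames(matrix)[neg[1, 2]], "'")
  invisible(matrix)
}

.cna_levels <- -2:2

#' Read / write a discrete copy-number call matrix
#'
#' Calls are restricted to the five-level alphabet \{-2, -1, 0, +1, +2\};
#' +2 denotes amplification.
#'
#' @param path File path.
#' @return Integer matrix, genes in rows, samples in columns.
#' @export
read_cna <- function(path) {
  m <- .gene_table_to_matrix(.read_tsv(path), path)
  bad <- which(!(m %in% .cna_levels), arr.ind = FALSE)
  if (length(bad))
    stop(path, ": copy-number calls must be integers in -2..+2")
  storage.mode(m) <- "integer"
  m
}

#' @param matrix Genes-by-samples integer matrix of calls in -2..+2.
#' @rdname read_cna
#' @export
write_cna <- function(matrix, path) {
  if (!all(matrix %in% .cna_levels))
    stop("copy-number calls must be integers in -2..+2")
  .write_tsv(data.frame(gene = rownames(matrix), matrix,
                        check.names = FALSE), path)
  invisible(path)
}

.receptor_levels <- c("positive", "negative", "unknown")
.pam50_levels <- c("LumA", "LumB", "HER2E", "Basal", "Normal-like", "unknown")

#' Read / write a clinical table
#'
#' One row per sample with header `sample, ER, PR, HER2, PAM50, OS_time,
#' OS_event, DMFS_time, DMFS_event`. Receptor status takes values
#' positive/negative/unknown; survival times are positive (months) and event
#' flags are 0/1; both may be NA when unavailable.
#'
#' @param path File path.
#' @return A validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- .read_tsv(path)
  validate_clinical(df, where = path)
}

#' @param clinical Clinical data.frame as described above.
#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  .write_tsv(clinical, path)
  invisible(path)
}

#' Validate a clinical table
#'
#' @param clinical Data.frame to check.
#' @param where Label used in error messages.
#' @return The data.frame (invisibly valid).
#' @export
validate_clinical <- function(clinical, where = "clinical table") {
  need <- c("sample", "ER", "PR", "HER2", "PAM50",
            "OS_time", "OS_event", "DMFS_time", "DMFS_event")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop(where, ": missing column(s): ", paste(miss, collapse = ", "))
  .stop_if_dup(clinical$sample, "sample id(s)", where)
  for (col in c("ER", "PR", "HER2")) {
    if (!all(clinical[[col]] %in% .receptor_levels))
      stop(where, ": ", col, " must be one of ",
           paste(.receptor_levels, collapse = "/"))
  }
  if (!all(clinical$PAM50 %in% .pam50_levels))
    stop(where, ": PAM50 must be one of ",
         paste(.pam50_levels, collapse = "/"))
  for (col in c("OS_time", "DMFS_time")) {
    v <- clinical[[col]]
    if (any(!is.na(v) & v <= 0)) stop(where, ": ", col, " must be positive")
  }
  for (col in c("OS_event", "DMFS_event")) {
    v <- clinical[[col]]
    if (any(!is.na(v) & !(v %in% c(0, 1))))
      stop(where, ": ", col, " must be 0/1")
  }
  clinical
}

#' Read / write a cell-line panel
#'
#' TSV with one row per cell line: `line`, `EC50` (positive, in micromolar),
#' then one column per gene holding log2-scale expression.
#'
#' @param path File path.
#' @return An object of class `cell_line_panel`: a list with `line`, `ec50`
#'   (named numeric), and `expr` (genes x lines matrix, log2 scale).
#' @export
read_panel <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("line", "EC50") %in% names(df)[1:2]))
    stop(path, ": first two columns must be 'line' and 'EC50'")
  .stop_if_dup(df$line, "line id(s)", path)
  if (any(df$EC50 <= 0)) stop(path, ": EC50 values must be positive")
  expr <- t(as.matrix(df[, -(1:2), drop = FALSE]))
  colnames(expr) <- df$line
  cell_line_panel(df$line, stats::setNames(df$EC50, df$line), expr)
}

#' @param panel A `cell_line_panel` object.
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(line = panel$line, EC50 = unname(panel$ec50[panel$line]),
                   t(panel$expr)[panel$line, , drop = FALSE],
                   check.names = FALSE)
  .write_tsv(df, path)
  invisible(path)
}

#' Construct a cell-line panel object
#'
#' @param line Character vector of unique line ids.
#' @param ec50 Positive EC50 per line (micromolar), named by line.
#' @param expr Genes-by-lines matrix of log2 expression.
#' @return An object of class `cell_line_panel`.
#' @export
cell_line_panel <- function(line, ec50, expr) {
  .stop_if_dup(line, "line id(s)", "cell_line_panel")
  if (any(ec50 <= 0)) stop("cell_line_panel: EC50 must be positive")
  if (!all(line %in% colnames(expr)))
    stop("cell_line_panel: expression matrix must cover every line")
  structure(list(line = line, ec50 = ec50[line],
                 expr = expr[, line, drop = FALSE]),
            class = "cell_line_panel")
}

#' Select triple-negative samples from a clinical table
#'
#' Returns exactly the samples with ER, PR and HER2 all `"negative"`;
#' an `"unknown"` status in any receptor excludes the sample.
#'
#' @param clinical Clinical data.frame (see [read_clinical]).
#' @return Character vector of sample ids (possibly empty).
#' @export
select_tnbc <- function(clinical) {
  validate_clinical(clinical)
  keep <- clinical$ER == "negative" & clinical$PR == "negative" &
    clinical$HER2 == "negative"
  clinical$sample[keep]
}

#' Per-gene z-scores of an expression matrix
#'
#' Standardizes each gene over all supplied samples, by default on the
#' log2(FPKM + 1) scale, using the population (divide-by-n) standard
#' deviation. Zero-variance genes map to all-zero rows.
#'
#' @param matrix Genes-by-samples FPKM matrix (or already-transformed values
#'   with `log2p1 = FALSE`).
#' @param log2p1 Apply the log2(x + 1) transform first (default TRUE).
#' @return Matrix of z-scores with the same dimnames.
#' @export
zscore_matrix <- function(matrix, log2p1 = TRUE) {
  if (ncol(matrix) < 2)
    stop("zscore_matrix: at least 2 samples are required")
  x <- if (log2p1) log2(matrix + 1) else matrix
  mu <- rowMeans(x)
  s <- sqrt(pmax(rowMeans(x^2) - mu^2, 0))
  z <- (x - mu) / s
  z[s < 1e-12, ] <- 0
  z
}
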