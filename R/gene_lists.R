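# Named, ordered, unique gene lists with provenance, and the packaged
# published six-list fixture.

#' Construct a gene list
#'
#' A named, ordered collection of unique gene symbols carrying a free-text
#' provenance string describing the criterion that produced it.
#'
#' @param name Non-empty list name (e.g. "GL1").
#' @param symbols Character vector of gene symbols, order-preserving.
#' @param criterion Free-text provenance.
#' @return Object of class `gene_list`.
#' @export
gene_list <- function(name, symbols, criterion = "") {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    stop("gene_list: name must be a non-empty string")
  symbols <- as.character(symbols)
  dup <- unique(symbols[duplicated(symbols)])
  if (length(dup))
    stop("gene_list '", name, "': duplicate symbol(s): ",
         paste(dup, collapse = ", "))
  structure(list(name = name, symbols = symbols, criterion = criterion),
            class = "gene_list")
}

#' @export
length.gene_list <- function(x) length(x$symbols)

#' @export
as.character.gene_list <- function(x, ...) x$symbols

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list> %s (%d genes)\n", x$name, length(x$symbols)))
  if (nzchar(x$criterion)) cat("  criterion: ", x$criterion, "\n", sep = "")
  cat("  ", paste(x$symbols, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Read / write a gene list as one-symbol-per-line text
#'
#' @param path File path.
#' @param name List name (defaults to the file name without extension).
#' @param criterion Free-text provenance.
#' @return A `gene_list`.
#' @export
read_gene_list <- function(path, name = NULL, criterion = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  syms <- readLines(path)
  syms <- syms[nzchar(trimws(syms))]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_list(name, trimws(syms), criterion)
}

#' @param x A `gene_list`.
#' @rdname read_gene_list
#' @export
write_gene_list <- function(x, path) {
  writeLines(x$symbols, path)
  invisible(path)
}

#' Intersect gene lists
#'
#' Returns the symbols present in every list, ordered by their appearance in
#' the first list. Any empty input list yields an empty result.
#'
#' @param lists A list of `gene_list` objects (at least one).
#' @param name Name for the resulting list.
#' @return A `gene_list`.
#' @export
intersect_gene_lists <- function(lists, name = "intersection") {
  if (length(lists) < 1) stop("intersect_gene_lists: need at least one list")
  syms <- lists[[1]]$symbols
  for (l in lists[-1]) syms <- syms[syms %in% l$symbols]
  gene_list(name, syms,
            criterion = paste("intersection of",
                              paste(vapply(lists, `[[`, "", "name"),
                                    collapse = ", ")))
}

#' The packaged published six-list fixture
#'
#' Loads the six criterion gene lists distilled from 43 marker-associated
#' DEGs in TNBC cohorts: GL1 genomic alteration rate > 10% (TNBC), GL2
#' amplification > 1% (metastatic cohort), GL3 basal-subtype maximal
#' expression, GL4 TNBC-enriched expression, GL5 poor OS and DMFS
#' association, GL6 over-expression in COX-2-inhibitor less-sensitive cell
#' lines. Their intersection contains the 10 prioritized candidates.
#'
#' @return Named list of six `gene_list` objects (GL1..GL6).
#' @export
table1_gene_lists <- function() {
  criteria <- c(
    GL1 = "genetic alteration rate > 10% in TNBC cohort",
    GL2 = "copy-number amplification > 1% in metastatic cohort",
    GL3 = "highest mean expression in PAM50 basal subtype",
    GL4 = "significantly higher expression in TNBC vs non-TNBC",
    GL5 = "high expression associated with poor OS and DMFS",
    GL6 = "higher expression in less-sensitive cell lines")
  out <- lapply(seq_len(6), function(i) {
    path <- system.file("extdata", sprintf("table1_gl%d.txt", i),
                        package = "coxmine", mustWork = TRUE)
    read_gene_list(path, name = names(criteria)[i],
                   criterion = unname(criteria[i]))
  })
  names(out) <- names(criteria)
  out
}

#' Serialize gene lists (with provenance) to JSON
#'
#' @param lists A list of `gene_list` objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gene_lists_json <- function(lists, path) {
  payload <- lapply(lists, function(l)
    list(name = l$name, criterion = l$criterion, symbols = l$symbols))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
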