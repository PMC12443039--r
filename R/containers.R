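#' Expression and count containers
#'
#' Lightweight containers for gene x sample data. A `count_matrix` holds raw
#' non-negative integer read counts; an `expr_matrix` holds non-negative
#' normalized values (the matrix V fed to NMF). Both carry unique gene and
#' sample identifiers as dimnames and a per-gene mitochondrial flag.
#'
#' @param values numeric gene x sample matrix with rownames (gene ids) and
#'   colnames (sample ids). Counts must be non-negative integers; expression
#'   values non-negative reals.
#' @param is_mito logical vector, one entry per gene (recycled from a single
#'   `FALSE` if omitted). Names, if present, must match the gene ids.
#' @return An object of class `count_matrix` or `expr_matrix`: a list with
#'   elements `values` (the matrix) and `is_mito` (named logical).
#' @export
count_matrix <- function(values, is_mito = FALSE) {
  obj <- .check_genes_samples(values, is_mito)
  if (any(obj$values < 0)) stop("counts must be non-negative")
  if (any(obj$values != round(obj$values))) stop("counts must be integral")
  class(obj) <- "count_matrix"
  obj
}

#' @rdname count_matrix
#' @export
expr_matrix <- function(values, is_mito = FALSE) {
  obj <- .check_genes_samples(values, is_mito)
  if (any(obj$values < 0)) stop("expression values must be non-negative")
  class(obj) <- "expr_matrix"
  obj
}

.check_genes_samples <- function(values, is_mito) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(is_mito) == 1L) is_mito <- rep(is_mito, nrow(values))
  if (length(is_mito) != nrow(values))
    stop("is_mito must have one entry per gene")
  if (!is.null(names(is_mito)) && !identical(names(is_mito), rownames(values)))
    is_mito <- is_mito[rownames(values)]
  names(is_mito) <- rownames(values)
  list(values = values, is_mito = is_mito)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d mitochondrial)\n",
              nrow(x$values), ncol(x$values), sum(x$is_mito)))
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d mitochondrial)\n",
              nrow(x$values), ncol(x$values), sum(x$is_mito)))
  invisible(x)
}

#' Read / write gene x sample tables
#'
#' TSV layout: first column `gene_id`, remaining columns one per sample.
#' The gene annotation table has columns `gene_id`, `is_mito` and
#' (optionally) `lineage_set`.
#'
#' @param path file path.
#' @param annotation optional annotation data frame (or path) providing
#'   `is_mito`; genes absent from it are taken as non-mitochondrial.
#' @param what `"counts"` or `"expression"`.
#' @return `read_matrix_tsv` returns a `count_matrix` or `expr_matrix`.
#' @export
read_matrix_tsv <- function(path, annotation = NULL, what = c("counts", "expression")) {
  what <- match.arg(what)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  is_mito <- rep(FALSE, nrow(m))
  names(is_mito) <- rownames(m)
  if (!is.null(annotation)) {
    if (is.character(annotation)) annotation <- read.delim(annotation, stringsAsFactors = FALSE)
    hit <- match(rownames(m), annotation$gene_id)
    is_mito[!is.na(hit)] <- as.logical(annotation$is_mito[hit[!is.na(hit)]])
  }
  if (what == "counts") count_matrix(m, is_mito) else expr_matrix(m, is_mito)
}

#' @param x a `count_matrix` or `expr_matrix`.
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
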