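#' Histological lineage scores and the mix-lineage score
#'
#' For three disjoint lineage marker sets (conventionally LUAD, LUSC, NET),
#' a sample's score for a lineage is the total expression of that lineage's
#' markers divided by the total expression of all markers, so the three
#' scores are non-negative and sum to one. The mix-lineage score
#' S_mix = 1 - max(S) is 0 for a pure-lineage sample and maximal (2/3 for
#' three lineages) when the scores are equal; high values indicate lineage
#' infidelity. All scores are invariant to rescaling a sample's expression.
#'
#' @param expr an [expr_matrix()].
#' @param sets named list of three non-empty, pairwise disjoint gene id
#'   vectors; each must have at least one gene present in `expr`.
#' @return Data frame with `sample_id`, one score column per lineage set,
#'   and `mix`. Samples with zero total marker expression get `NaN` scores
#'   and are reported in the `flagged` attribute.
#' @export
lineage_score <- function(expr, sets) {
  if (length(sets) != 3 || is.null(names(sets)))
    stop("sets must be a named list of three gene sets")
  if (any(lengths(sets) == 0)) stop("every lineage set must be non-empty")
  all_genes <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_genes)) stop("lineage sets must be pairwise disjoint")
  m <- expr$values
  present <- lapply(sets, intersect, x = rownames(m))
  if (any(lengths(present) == 0))
    stop("every lineage set needs at least one gene present in expr")
  totals <- vapply(present, function(g)
    colSums(m[g, , drop = FALSE]), numeric(ncol(m)))
  if (ncol(m) == 1) totals <- matrix(totals, nrow = 1,
                                     dimnames = list(colnames(m), names(sets)))
  denom <- rowSums(totals)
  flagged <- denom <= 0
  if (any(flagged))
    warning(sum(flagged), " sample(s) with zero total marker expression flagged")
  s <- totals / ifelse(denom == 0, NA_real_, denom)
  s[flagged, ] <- NaN
  out <- data.frame(sample_id = colnames(m), s,
                    mix = 1 - apply(s, 1, max),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "flagged") <- colnames(m)[flagged]
  out
}

#' Read lineage gene sets
#'
#' Accepts either a JSON file of named gene lists or a gene annotation TSV
#' with columns `gene_id` and `lineage_set` (non-marker genes blank or NA).
#'
#' @param path file path (`.json` or a TSV).
#' @return Named list of gene id vectors.
#' @export
read_lineage_sets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    sets <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(sets, as.character))
  }
  ann <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "lineage_set") %in% names(ann)))
    stop("annotation TSV needs gene_id and lineage_set columns")
  ann <- ann[!is.na(ann$lineage_set) & ann$lineage_set != "", ]
  split(ann$gene_id, ann$lineage_set)
}
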