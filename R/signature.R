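.label_vector <- function(labels) {
  if (inherits(labels, "subtype_assignment")) labels <- labels$labels
  as.integer(labels)
}

#' Class-versus-rest t-statistics
#'
#' For every class c and gene g, the standard two-sample t-statistic
#' comparing samples in c against all other samples:
#' t = (mean_in - mean_out) / (s_pooled * sqrt(1/n_in + 1/n_out)),
#' with the usual pooled variance. Genes with zero pooled variance get a
#' signed infinity (so a perfectly clean marker ranks above every finite
#' value), or 0 when the means are also equal.
#'
#' @param expr an [expr_matrix()].
#' @param labels a `subtype_assignment` or integer vector of class labels
#'   (one per sample, every class with >= 2 samples).
#' @return A class x gene numeric matrix of t-statistics.
#' @export
class_t_statistics <- function(expr, labels) {
  m <- expr$values
  lab <- .label_vector(labels)
  if (length(lab) != ncol(m)) stop("labels must match the number of samples")
  classes <- sort(unique(lab))
  if (any(table(lab) < 2)) stop("every class needs at least 2 samples")
  n <- ncol(m)
  out <- matrix(NA_real_, length(classes), nrow(m),
                dimnames = list(as.character(classes), rownames(m)))
  tot_sum <- rowSums(m)
  tot_sq <- rowSums(m^2)
  for (i in seq_along(classes)) {
    idx <- lab == classes[i]
    n1 <- sum(idx); n2 <- n - n1
    s1 <- rowSums(m[, idx, drop = FALSE])
    q1 <- rowSums(m[, idx, drop = FALSE]^2)
    m1 <- s1 / n1
    m2 <- (tot_sum - s1) / n2
    ss1 <- q1 - n1 * m1^2
    ss2 <- (tot_sq - q1) - n2 * m2^2
    sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
    denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
    t <- (m1 - m2) / denom
    zero <- sp2 <= 0
    t[zero] <- sign(m1[zero] - m2[zero]) * Inf
    t[zero & m1 == m2] <- 0
    out[i, ] <- t
  }
  out
}

#' Build a nearest-centroid gene signature
#'
#' ClaNC-style construction: every gene is provisionally owned by the class
#' maximizing |t| (class-vs-rest statistics from [class_t_statistics()]);
#' within each class the top `n_per_class` owned genes by |t| are selected,
#' giving k disjoint gene sets of size N and a signature of k * N genes.
#' Centroids are the per-class means of the selected genes over the
#' training samples; per-gene training mean and sd are stored for the
#' optional standardized classification mode.
#'
#' @inheritParams class_t_statistics
#' @param n_per_class number of genes selected per class (N).
#' @return An object of class `centroid_signature`: list with `classes`,
#'   `n_per_class`, `genes` (ordered k * N gene ids), `class_of_gene`,
#'   `centroids` (class x gene matrix) and `training_stats` (data frame of
#'   per-gene mean/sd over all training samples).
#' @export
build_signature <- function(expr, labels, n_per_class = 20) {
  lab <- .label_vector(labels)
  tmat <- class_t_statistics(expr, lab)
  classes <- as.integer(rownames(tmat))
  at <- abs(tmat)
  owner <- apply(at, 2, which.max)      # ties: first (lowest) class
  genes <- character(0); class_of_gene <- integer(0)
  for (i in seq_along(classes)) {
    owned <- which(owner == i)
    if (length(owned) < n_per_class)
      stop(sprintf("class %d owns only %d genes; choose n_per_class <= %d",
                   classes[i], length(owned), length(owned)))
    ord <- owned[order(-at[i, owned], colnames(at)[owned])]
    sel <- colnames(at)[ord[seq_len(n_per_class)]]
    genes <- c(genes, sel)
    class_of_gene <- c(class_of_gene, rep(classes[i], n_per_class))
  }
  m <- expr$values[genes, , drop = FALSE]
  centroids <- matrix(NA_real_, length(classes), length(genes),
                      dimnames = list(as.character(classes), genes))
  for (i in seq_along(classes))
    centroids[i, ] <- rowMeans(m[, lab == classes[i], drop = FALSE])
  stats <- data.frame(gene_id = genes,
                      mean = rowMeans(m),
                      sd = apply(m, 1, sd),
                      stringsAsFactors = FALSE)
  rownames(stats) <- NULL
  structure(list(classes = classes, n_per_class = as.integer(n_per_class),
                 genes = genes, class_of_gene = setNames(class_of_gene, genes),
                 centroids = centroids, training_stats = stats),
            class = "centroid_signature")
}

#' @export
print.centroid_signature <- function(x, ...) {
  cat(sprintf("centroid_signature: %d classes x %d genes each (%d total)\n",
              length(x$classes), x$n_per_class, length(x$genes)))
  invisible(x)
}

.signature_values <- function(sig, expr, standardize) {
  missing <- setdiff(sig$genes, rownames(expr$values))
  if (length(missing))
    stop("signature genes missing from expression matrix: ",
         paste(head(missing, 10), collapse = ", "))
  x <- expr$values[sig$genes, , drop = FALSE]
  if (any(!is.finite(x))) stop("non-finite expression values")
  cen <- sig$centroids
  if (standardize) {
    mu <- sig$training_stats$mean
    sdv <- pmax(sig$training_stats$sd, 1e-12)
    x <- (x - mu) / sdv
    cen <- sweep(sweep(cen, 2, mu, `-`), 2, sdv, `/`)
  }
  list(x = x, centroids = cen)
}

#' Classify samples by nearest centroid
#'
#' Euclidean distance in the signature-gene space; each sample is assigned
#' to the class with the smallest distance (ties to the first class in
#' order). With `standardize = TRUE`, genes are z-scored using the
#' signature's training statistics before measuring distance.
#'
#' @param sig a `centroid_signature`.
#' @param expr an [expr_matrix()] containing all signature genes.
#' @param standardize use the stored training mean/sd to z-score genes.
#' @return List with `labels` (named integer vector) and `distances`
#'   (sample x class matrix).
#' @export
classify_nearest_centroid <- function(sig, expr, standardize = FALSE) {
  sv <- .signature_values(sig, expr, standardize)
  d2 <- outer(colSums(sv$x^2), rowSums(sv$centroids^2), `+`) -
    2 * t(sv$x) %*% t(sv$centroids)
  d <- sqrt(pmax(d2, 0))
  dimnames(d) <- list(colnames(sv$x), as.character(sig$classes))
  labels <- sig$classes[apply(d, 1, which.min)]
  names(labels) <- rownames(d)
  list(labels = labels, distances = d)
}

#' Distances to subtype centroids as prognostic features
#'
#' Per-sample Euclidean distances (d1, ..., dk) from the signature-gene
#' vector to each class centroid; used as continuous covariates in the
#' survival risk models.
#'
#' @inheritParams classify_nearest_centroid
#' @return Sample x class matrix of distances, columns named `d1..dk`.
#' @export
centroid_distance_features <- function(sig, expr, standardize = FALSE) {
  d <- classify_nearest_centroid(sig, expr, standardize)$distances
  colnames(d) <- paste0("d", seq_along(sig$classes))
  d
}

#' Classify samples by correlation to centroids
#'
#' Median-centers every gene across the samples of `expr`, then assigns
#' each sample to the class whose centroid has the highest Pearson
#' correlation with the sample's (centered) signature-gene vector. Samples
#' with zero variance across the shared genes are flagged unclassified
#' (`NA` label). Because Pearson correlation is invariant to affine
#' rescaling of a sample, the assignment depends only on the sample's
#' expression profile shape (given a fixed centering vector).
#'
#' @param centroids class x gene numeric matrix, or a
#'   `centroid_signature` (its centroids are used).
#' @param expr an [expr_matrix()]; at least 3 centroid genes must be
#'   present.
#' @param center per-gene median centering: `TRUE` (compute medians from
#'   `expr`, the default), `FALSE` (no centering), or a named numeric
#'   vector of precomputed per-gene centers (e.g. from a reference
#'   cohort).
#' @return List with `labels` (integer class per sample, `NA` when
#'   unclassified) and `correlations` (sample x class matrix).
#' @export
classify_by_correlation <- function(centroids, expr, center = TRUE) {
  if (inherits(centroids, "centroid_signature")) {
    classes <- centroids$classes
    centroids <- centroids$centroids
  } else {
    centroids <- as.matrix(centroids)
    classes <- if (is.null(rownames(centroids))) seq_len(nrow(centroids))
               else suppressWarnings(as.integer(rownames(centroids)))
    if (any(is.na(classes))) classes <- seq_len(nrow(centroids))
  }
  shared <- intersect(colnames(centroids), rownames(expr$values))
  if (length(shared) < 3) stop("need at least 3 shared genes")
  x <- expr$values[shared, , drop = FALSE]
  if (isTRUE(center)) {
    x <- x - apply(x, 1, median)        # per-gene median centering
  } else if (is.numeric(center)) {
    if (is.null(names(center)) || !all(shared %in% names(center)))
      stop("numeric 'center' must be named and cover the shared genes")
    x <- x - center[shared]
  }
  cen <- centroids[, shared, drop = FALSE]
  r <- matrix(NA_real_, ncol(x), nrow(cen),
              dimnames = list(colnames(x), rownames(cen)))
  ok <- apply(x, 2, sd) > 0
  cen_ok <- apply(cen, 1, sd) > 0
  if (any(ok))
    r[ok, cen_ok] <- cor(x[, ok, drop = FALSE], t(cen[cen_ok, , drop = FALSE]))
  labels <- rep(NA_integer_, ncol(x))
  labels[ok] <- classes[apply(r[ok, , drop = FALSE], 1, which.max)]
  names(labels) <- colnames(x)
  list(labels = labels, correlations = r)
}

#' Cross-validated selection of the signature size
#'
#' Repeats a stratified 70/30 split of the samples; on each training part
#' it builds signatures for every N in `N_range` and measures the
#' misclassification rate (against the input labels) on the training and
#' held-out parts. Reports the mean train/test error per N over all
#' repeats and picks `chosen_N` as the smallest N whose mean test error is
#' within one standard error of the minimum (parsimony rule).
#'
#' @inheritParams class_t_statistics
#' @param N_range candidate per-class signature sizes.
#' @param repeats number of random splits.
#' @param train_fraction fraction of each class assigned to training.
#' @param seed RNG seed for the splits.
#' @param standardize passed to [classify_nearest_centroid()].
#' @return An object of class `cv_report`: list with `n_repeats`,
#'   `train_fraction`, `per_N_errors` (data frame: N, train_error,
#'   test_error, test_se) and `chosen_N`.
#' @export
cross_validate_signature <- function(expr, labels, N_range = 1:30,
                                     repeats = 100, train_fraction = 0.7,
                                     seed = 1L, standardize = FALSE) {
  lab <- .label_vector(labels)
  m <- expr$values
  classes <- sort(unique(lab))
  by_class <- split(seq_along(lab), lab)
  if (any(vapply(by_class, length, integer(1)) < 2))
    stop("every class needs >= 2 samples for stratified splitting")
  set.seed(seed)
  train_err <- test_err <- matrix(NA_real_, repeats, length(N_range))
  for (r in seq_len(repeats)) {
    tr <- unlist(lapply(by_class, function(idx) {
      ntr <- max(1, round(train_fraction * length(idx)))
      ntr <- min(ntr, length(idx) - 1)  # keep every class in the test part
      sample(idx, ntr)
    }))
    te <- setdiff(seq_along(lab), tr)
    expr_tr <- expr_matrix(m[, tr, drop = FALSE], expr$is_mito)
    expr_te <- expr_matrix(m[, te, drop = FALSE], expr$is_mito)
    for (j in seq_along(N_range)) {
      sig <- build_signature(expr_tr, lab[tr], n_per_class = N_range[j])
      pr_tr <- classify_nearest_centroid(sig, expr_tr, standardize)$labels
      pr_te <- classify_nearest_centroid(sig, expr_te, standardize)$labels
      train_err[r, j] <- mean(pr_tr != lab[tr])
      test_err[r, j] <- mean(pr_te != lab[te])
    }
  }
  per_N <- data.frame(N = N_range,
                      train_error = colMeans(train_err),
                      test_error = colMeans(test_err),
                      test_se = apply(test_err, 2, sd) / sqrt(repeats))
  i_min <- which.min(per_N$test_error)
  thresh <- per_N$test_error[i_min] + per_N$test_se[i_min]
  chosen <- min(per_N$N[per_N$test_error <= thresh])
  structure(list(n_repeats = repeats, train_fraction = train_fraction,
                 per_N_errors = per_N, chosen_N = as.integer(chosen)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d repeats, train fraction %.2f, chosen N = %d\n",
              x$n_repeats, x$train_fraction, x$chosen_N))
  invisible(x)
}

#' Serialize / load a centroid signature as JSON
#'
#' @param sig a `centroid_signature`.
#' @param path JSON file path.
#' @param seed optional provenance seed recorded in the file.
#' @return `write_signature_json` invisibly returns the path;
#'   `read_signature_json` returns the `centroid_signature`.
#' @export
write_signature_json <- function(sig, path, seed = NULL) {
  stopifnot(inherits(sig, "centroid_signature"))
  obj <- list(classes = sig$classes,
              n_per_class = sig$n_per_class,
              genes = sig$genes,
              class_of_gene = unname(sig$class_of_gene),
              centroids = apply(sig$centroids, 1, as.list, simplify = FALSE),
              training_stats = sig$training_stats,
              provenance = list(seed = seed,
                                software = paste0("nmfsubtypes ",
                                  as.character(utils::packageVersion("nmfsubtypes")))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cen <- do.call(rbind, lapply(obj$centroids, unlist))
  rownames(cen) <- as.character(obj$classes)
  colnames(cen) <- obj$genes
  structure(list(classes = as.integer(obj$classes),
                 n_per_class = as.integer(obj$n_per_class),
                 genes = obj$genes,
                 class_of_gene = setNames(as.integer(obj$class_of_gene), obj$genes),
                 centroids = cen,
                 training_stats = as.data.frame(obj$training_stats)),
            class = "centroid_signature")
}
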