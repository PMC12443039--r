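#' Brunet NMF by multiplicative KL-divergence updates
#'
#' Factorizes a non-negative matrix V (genes x samples) as V ~ W H with the
#' classic multiplicative updates for the generalized Kullback-Leibler
#' divergence:
#' H <- H * (W' (V/WH)) / (W' 1) and W <- W * ((V/WH) H') / (1 H'),
#' with an epsilon guard inside divisions. W and H are initialized i.i.d.
#' Uniform(0,1) and rescaled so that mean(WH) matches mean(V); the seed
#' fully determines the initialization.
#'
#' Iteration stops when the sample connectivity matrix (co-membership under
#' argmax of H columns) has been unchanged for `conn_stop` consecutive
#' checks (one check every `conn_interval` iterations), or at `max_iter`.
#' Set `conn_stop = 0` to disable the connectivity criterion and always run
#' `max_iter` iterations (useful when chasing a tight objective value).
#'
#' @param V an [expr_matrix()] or non-negative numeric matrix.
#' @param rank factorization rank k (number of programs / clusters).
#' @param seed RNG seed for the initialization.
#' @param max_iter maximum number of update sweeps.
#' @param conn_stop consecutive unchanged connectivity checks required to
#'   declare convergence; 0 disables the criterion.
#' @param conn_interval iterations between connectivity checks.
#' @param trace_every record the KL divergence every this many iterations
#'   (1 = every iteration; the initial and final values are always kept).
#' @param eps epsilon guard for divisions and logs.
#' @param precision `"double"` (default) or `"single"`: arithmetic
#'   precision of the update loop. Single precision roughly halves the
#'   cost of large consensus scans; cluster connectivity is unaffected for
#'   practical purposes, but use double precision when the objective trace
#'   itself is of interest.
#' @return An object of class `nmf_fit`: list with `W` (genes x rank), `H`
#'   (rank x samples), `rank`, `objective_trace`, `trace_iterations`,
#'   `iterations`, `converged`, `seed`.
#' @export
fit_nmf_brunet <- function(V, rank, seed = 1L, max_iter = 2000L,
                           conn_stop = 10L, conn_interval = 10L,
                           trace_every = 10L, eps = 1e-12,
                           precision = c("double", "single")) {
  precision <- match.arg(precision)
  m <- if (inherits(V, "expr_matrix")) V$values else as.matrix(V)
  if (any(m < 0)) stop("V must be non-negative")
  if (any(colSums(m) == 0)) stop("V has an all-zero column")
  if (rank < 1 || rank > min(dim(m)))
    stop("rank must lie in [1, min(dim(V))]")

  set.seed(seed)
  scale <- sqrt(mean(m) / (rank * 0.25))
  W <- matrix(runif(nrow(m) * rank), nrow(m), rank) * scale
  H <- matrix(runif(rank * ncol(m)), rank, ncol(m)) * scale

  res <- .nmf_brunet_cpp(m, W, H, as.integer(max_iter), as.integer(conn_stop),
                         as.integer(conn_interval), as.integer(trace_every), eps,
                         precision == "single")
  rownames(res$W) <- rownames(m)
  colnames(res$H) <- colnames(m)
  structure(list(W = res$W, H = res$H, rank = as.integer(rank),
                 objective_trace = res$objective_trace,
                 trace_iterations = res$trace_iterations,
                 iterations = res$iterations, converged = res$converged,
                 seed = seed),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("nmf_fit: rank %d, %d x %d, %d iterations (%s), final KL = %.4g\n",
              x$rank, nrow(x$W), ncol(x$H), x$iterations,
              if (x$converged) "converged" else "max_iter",
              x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Consensus matrix over repeated NMF runs
#'
#' Runs [fit_nmf_brunet()] `n_runs` times with seeds
#' `base_seed + 1, ..., base_seed + n_runs` and records, for every pair of
#' samples, the fraction of runs in which they share an argmax-H cluster.
#' The cophenetic coefficient of the consensus matrix and three silhouette
#' summaries (on 1 - consensus, on the best run's H columns and W rows) are
#' computed, and the run with the lowest final KL divergence is kept as the
#' representative factorization for downstream use.
#'
#' The repeated runs only contribute argmax-H cluster labels and a final
#' divergence, so the scan itself uses single-precision updates for speed;
#' the winning run is refit in double precision before being returned.
#'
#' @inheritParams fit_nmf_brunet
#' @param n_runs number of independent NMF runs (>= 2).
#' @param base_seed offset for the per-run seeds.
#' @param ... passed to [fit_nmf_brunet()] (e.g. `max_iter`, `conn_stop`).
#' @return An object of class `nmf_consensus`: list with `rank`,
#'   `consensus` (sample x sample in `[0,1]`), `cophenetic`,
#'   `silhouette_consensus`, `silhouette_coef`, `silhouette_basis`,
#'   `n_runs`, `best_fit` (an `nmf_fit`), `run_divergences`.
#' @export
consensus_over_runs <- function(V, rank, n_runs = 80L, base_seed = 1L, ...) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  m <- if (inherits(V, "expr_matrix")) V$values else as.matrix(V)
  n <- ncol(m)
  co <- matrix(0, n, n)
  best <- NULL
  divs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- tryCatch(
      fit_nmf_brunet(V, rank, seed = base_seed + r, precision = "single", ...),
      error = function(e) stop(sprintf("NMF run %d failed: %s", r, conditionMessage(e)),
                               call. = FALSE))
    lab <- apply(fit$H, 2, which.max)
    co <- co + outer(lab, lab, `==`)
    divs[r] <- fit$objective_trace[length(fit$objective_trace)]
  }
  best <- fit_nmf_brunet(V, rank, seed = base_seed + which.min(divs),
                         precision = "double", ...)
  consensus <- co / n_runs
  dimnames(consensus) <- list(colnames(m), colnames(m))

  coph <- cophenetic_coefficient(consensus)
  sil_cons <- .mean_silhouette(.consensus_cut(consensus, rank),
                               as.dist(1 - consensus))
  hlab <- apply(best$H, 2, which.max)
  sil_coef <- .mean_silhouette(hlab, stats::dist(t(best$H)))
  wlab <- apply(best$W, 1, which.max)
  sil_basis <- .mean_silhouette(wlab, stats::dist(best$W))

  structure(list(rank = as.integer(rank), consensus = consensus,
                 cophenetic = coph,
                 silhouette_consensus = sil_cons,
                 silhouette_coef = sil_coef,
                 silhouette_basis = sil_basis,
                 n_runs = as.integer(n_runs),
                 best_fit = best, run_divergences = divs),
            class = "nmf_consensus")
}

# average-linkage cut of the consensus dissimilarity into k groups
.consensus_cut <- function(consensus, k) {
  hc <- hclust(as.dist(1 - consensus), method = "average")
  cutree(hc, k = k)
}

.mean_silhouette <- function(labels, d) {
  if (length(unique(labels)) < 2) return(NA_real_)
  mean(cluster::silhouette(as.integer(labels), d)[, "sil_width"])
}

#' @export
print.nmf_consensus <- function(x, ...) {
  cat(sprintf("nmf_consensus: rank %d, %d runs, cophenetic = %.4f\n",
              x$rank, x$n_runs, x$cophenetic))
  invisible(x)
}

#' Cophenetic coefficient of a consensus matrix
#'
#' Treats 1 - consensus as a dissimilarity, builds an average-linkage
#' dendrogram, and returns the Pearson correlation between the original
#' pairwise dissimilarities and the dendrogram's cophenetic distances.
#' Values near 1 indicate a stable, nearly ultrametric consensus.
#'
#' @param consensus symmetric sample x sample matrix in `[0,1]` with unit
#'   diagonal.
#' @return A single correlation in `[-1, 1]`, or `NaN` (with a warning)
#'   when the dissimilarities are constant.
#' @export
cophenetic_coefficient <- function(consensus) {
  consensus <- as.matrix(consensus)
  if (!isSymmetric(unname(consensus), tol = 1e-8))
    stop("consensus must be symmetric")
  if (any(consensus < -1e-12) || any(consensus > 1 + 1e-12))
    stop("consensus entries must lie in [0, 1]")
  d <- as.dist(1 - consensus)
  if (sd(d) == 0) {
    warning("constant consensus dissimilarities; cophenetic coefficient undefined")
    return(NaN)
  }
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (sd(cd) == 0) {
    warning("degenerate dendrogram; cophenetic coefficient undefined")
    return(NaN)
  }
  cor(d, cd)
}

#' Select the factorization rank from consensus stability
#'
#' Given consensus results for several candidate ranks, returns the rank
#' with the largest cophenetic coefficient; ties go to the smallest rank.
#' Ranks whose coefficient is `NaN` are excluded with a warning.
#'
#' @param results list of `nmf_consensus` objects (>= 2 distinct ranks).
#' @return A list of class `rank_selection` with `rank` (the chosen
#'   integer) and `curve` (data frame of rank, cophenetic and silhouette
#'   summaries, for reporting).
#' @export
select_rank <- function(results) {
  if (length(results) < 2) stop("need consensus results for at least 2 ranks")
  curve <- data.frame(
    rank = vapply(results, `[[`, integer(1), "rank"),
    cophenetic = vapply(results, `[[`, numeric(1), "cophenetic"),
    silhouette_consensus = vapply(results, `[[`, numeric(1), "silhouette_consensus"),
    silhouette_coef = vapply(results, `[[`, numeric(1), "silhouette_coef"),
    silhouette_basis = vapply(results, `[[`, numeric(1), "silhouette_basis"))
  curve <- curve[order(curve$rank), , drop = FALSE]
  ok <- is.finite(curve$cophenetic)
  if (!all(ok))
    warning("excluding ranks with undefined cophenetic coefficient: ",
            paste(curve$rank[!ok], collapse = ", "))
  if (!any(ok)) stop("no rank has a defined cophenetic coefficient")
  cand <- curve[ok, ]
  best <- cand$rank[which.max(cand$cophenetic)]  # which.max: first max = smallest rank
  structure(list(rank = as.integer(best), curve = curve),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat(sprintf("rank_selection: chosen rank %d\n", x$rank))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Assign samples to subtypes from a fitted factorization
#'
#' Each sample is labeled by the program with the largest coefficient in
#' its H column (ties to the lowest index); the membership profile is the
#' column of H normalized to sum to 1.
#'
#' @param fact an `nmf_fit`.
#' @return An object of class `subtype_assignment`: list with `labels`
#'   (named integer vector in 1..k) and `membership` (rank x sample matrix
#'   with unit column sums).
#' @export
assign_clusters <- function(fact) {
  stopifnot(inherits(fact, "nmf_fit"))
  H <- fact$H
  cs <- colSums(H)
  if (any(cs == 0)) stop("H has an all-zero column; cannot assign")
  labels <- apply(H, 2, which.max)
  membership <- sweep(H, 2, cs, `/`)
  names(labels) <- colnames(H)
  structure(list(labels = labels, membership = membership, k = fact$rank),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("subtype_assignment: %d samples over %d subtypes (%s)\n",
              length(x$labels), x$k,
              paste(sprintf("%d: n=%d", seq_len(x$k),
                            tabulate(x$labels, x$k)), collapse = ", ")))
  invisible(x)
}

#' Entropy-based basis-specificity score
#'
#' For gene i with basis row W\[i, \], let p(i, q) = W\[i, q\] / sum_q W\[i, q\]
#' be the probability that the gene contributes to program q. The
#' specificity score is
#' S_i = 1 + (1 / log2 k) * sum_q p(i, q) log2 p(i, q),
#' i.e. one minus the normalized entropy of the profile: 0 for a uniform
#' profile, 1 for a gene loading on a single program. Genes with an
#' all-zero basis row get `NaN` and are flagged.
#'
#' @param fact an `nmf_fit` with rank >= 2.
#' @return An object of class `gene_specificity`: list with `score` (named
#'   per-gene S_i), `profile` (gene x rank matrix of p(i, q)), `cluster`
#'   (argmax program per gene) and `flagged` (genes with all-zero rows).
#' @export
basis_specificity <- function(fact) {
  stopifnot(inherits(fact, "nmf_fit"))
  k <- fact$rank
  if (k < 2) stop("specificity requires rank >= 2")
  W <- fact$W
  rs <- rowSums(W)
  flagged <- rs == 0
  p <- W / ifelse(rs == 0, NA_real_, rs)
  plp <- p * log2(p)
  plp[p == 0] <- 0                      # 0 * log2(0) := 0
  score <- 1 + rowSums(plp) / log2(k)
  score[flagged] <- NaN
  cluster <- max.col(replace(p, is.na(p), -Inf), ties.method = "first")
  names(score) <- names(cluster) <- rownames(W)
  structure(list(score = score, profile = p, cluster = cluster,
                 flagged = flagged, k = k),
            class = "gene_specificity")
}

#' @export
print.gene_specificity <- function(x, ...) {
  cat(sprintf("gene_specificity: %d genes over %d programs (%d flagged), median S = %.3f\n",
              length(x$score), x$k, sum(x$flagged),
              median(x$score, na.rm = TRUE)))
  invisible(x)
}

#' Top subtype-specific genes by specificity score
#'
#' Ranks genes by S_i within the program they load on most and returns the
#' top `m` per program.
#'
#' @param specificity a `gene_specificity`.
#' @param m genes to report per program.
#' @return Data frame with columns `cluster`, `gene_id`, `score`.
#' @export
top_specific_genes <- function(specificity, m = 50) {
  stopifnot(inherits(specificity, "gene_specificity"))
  out <- lapply(seq_len(specificity$k), function(q) {
    idx <- which(specificity$cluster == q & !specificity$flagged)
    idx <- idx[order(-specificity$score[idx], names(specificity$score)[idx])]
    idx <- head(idx, m)
    data.frame(cluster = q, gene_id = names(specificity$score)[idx],
               score = unname(specificity$score[idx]))
  })
  do.call(rbind, out)
}
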