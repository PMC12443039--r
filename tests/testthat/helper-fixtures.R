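# Small in-code fixtures shared across test files.

# compact synthetic cohort for unit tests (fast to generate and to factorize)
small_config <- function(seed = 1L, ...) {
  args <- list(n_subtypes = 3, samples_per_subtype = 15, n_genes = 300,
               n_signature_genes_per_subtype = 30, signature_log2fc = 2,
               nb_dispersion = 0.2, n_mito_genes = 5,
               lineage_set_sizes = c(10, 10, 10), seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

# noise-free, perfectly separable expression matrix: each class has
# `markers_per_class` exclusive genes at `high` in its own samples and 0
# elsewhere, on top of a constant background.
separable_expr <- function(n_per_class = 10, k = 3, markers_per_class = 30,
                           background_genes = 20, high = 10) {
  n <- n_per_class * k
  labels <- rep(seq_len(k), each = n_per_class)
  g <- k * markers_per_class + background_genes
  m <- matrix(1, g, n)
  for (cl in seq_len(k)) {
    rows <- (cl - 1) * markers_per_class + seq_len(markers_per_class)
    m[rows, ] <- 0
    m[rows, labels == cl] <- high
  }
  dimnames(m) <- list(sprintf("G%03d", seq_len(g)), sprintf("S%03d", seq_len(n)))
  list(expr = expr_matrix(m), labels = labels)
}

# hand-built nmf_fit for functions that only need W/H
fake_fit <- function(W, H, rank = ncol(W)) {
  structure(list(W = W, H = H, rank = as.integer(rank),
                 objective_trace = c(1, 0.5), trace_iterations = c(0, 1),
                 iterations = 1L, converged = TRUE, seed = 0L),
            class = "nmf_fit")
}

# brute-force Harrell c-index by explicit pair enumeration (the oracle the
# vectorized implementation must match exactly)
cindex_bruteforce <- function(risk, time, event) {
  n <- length(risk)
  num <- den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  if (den == 0) NaN else num / den
}

# independent UPGMA + cophenetic-correlation oracle (no hclust/cophenetic)
cophenetic_oracle <- function(consensus) {
  d <- 1 - consensus
  n <- nrow(d)
  cd <- matrix(0, n, n)
  active <- lapply(seq_len(n), identity)      # clusters as index sets
  dd <- d
  diag(dd) <- Inf
  while (length(active) > 1) {
    # average-linkage distance between current clusters
    m <- length(active)
    cl_d <- matrix(Inf, m, m)
    for (a in seq_len(m - 1)) for (b in (a + 1):m)
      cl_d[a, b] <- mean(d[active[[a]], active[[b]]])
    ij <- which(cl_d == min(cl_d), arr.ind = TRUE)[1, ]
    h <- cl_d[ij[1], ij[2]]
    for (x in active[[ij[1]]]) for (y in active[[ij[2]]]) {
      cd[x, y] <- h
      cd[y, x] <- h
    }
    merged <- c(active[[ij[1]]], active[[ij[2]]])
    active <- c(active[-c(ij[1], ij[2])], list(merged))
  }
  lower <- lower.tri(d)
  cor(d[lower], cd[lower])
}
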