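test_that("rank-1 factorization recovers an outer product", {
  V <- matrix(c(3, 6, 4, 8), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fit <- fit_nmf_brunet(V, rank = 1, seed = 1, max_iter = 5000,
                        conn_stop = 0, trace_every = 1)
  expect_lt(max(abs(fit$W %*% fit$H - V) / V), 1e-8)
})

test_that("multiplicative updates keep the objective monotone and factors non-negative", {
  set.seed(3)
  V <- matrix(rexp(40 * 20), 40, 20)
  dimnames(V) <- list(paste0("g", 1:40), paste0("s", 1:20))
  for (seed in 1:3) {
    fit <- fit_nmf_brunet(V, rank = 3, seed = seed, max_iter = 300,
                          conn_stop = 0, trace_every = 1)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-10 * pmax(tr[-length(tr)], 1)))
    expect_true(all(fit$W >= 0))
    expect_true(all(fit$H >= 0))
  }
})

test_that("invalid NMF inputs are rejected", {
  V <- matrix(1, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  V2 <- V; V2[1, 1] <- -1
  expect_error(fit_nmf_brunet(V2, 2), "non-negative")
  V3 <- V; V3[, 2] <- 0
  expect_error(fit_nmf_brunet(V3, 2), "all-zero")
  expect_error(fit_nmf_brunet(V, 9), "rank")
})

test_that("consensus of well-separated clusters is a 0/1 block matrix", {
  sep <- separable_expr(n_per_class = 8, high = 50)
  res <- consensus_over_runs(sep$expr, rank = 3, n_runs = 4, base_seed = 10)
  expect_true(all(res$consensus %in% c(0, 1)))
  expect_true(isSymmetric(unname(res$consensus)))
  expect_true(all(diag(res$consensus) == 1))
  # block structure follows the planted grouping
  same <- outer(sep$labels, sep$labels, `==`)
  expect_equal(res$consensus[same], rep(1, sum(same)))
  expect_equal(res$consensus[!same], rep(0, sum(!same)))
  expect_equal(res$cophenetic, 1)
})

test_that("consensus is equivariant under sample permutation", {
  ds <- generate_dataset(small_config(seed = 4))
  sel <- select_genes(normalize_counts(ds$counts), n_top = 100)
  res <- consensus_over_runs(sel, rank = 2, n_runs = 4, base_seed = 5)
  perm <- rev(seq_len(ncol(sel$values)))
  sel_p <- expr_matrix(sel$values[, perm], sel$is_mito)
  res_p <- consensus_over_runs(sel_p, rank = 2, n_runs = 4, base_seed = 5)
  expect_equal(res_p$consensus, res$consensus[perm, perm], tolerance = 1e-12)
})

test_that("cophenetic coefficient is 1 for ultrametric consensus and matches an independent UPGMA oracle", {
  # ideal two-block consensus
  ideal <- kronecker(diag(2), matrix(1, 3, 3))
  expect_equal(cophenetic_coefficient(ideal), 1)
  # two-level consensus (0.9 within, 0.1 between) is still ultrametric
  soft <- matrix(0.1, 4, 4)
  soft[1:2, 1:2] <- 0.9; soft[3:4, 3:4] <- 0.9; diag(soft) <- 1
  expect_equal(cophenetic_coefficient(soft), 1)
  # random symmetric consensus vs a from-scratch average-linkage oracle
  set.seed(8)
  r <- matrix(runif(36), 6, 6)
  cons <- (r + t(r)) / 2
  diag(cons) <- 1
  expect_equal(cophenetic_coefficient(cons), cophenetic_oracle(cons),
               tolerance = 1e-12)
  # constant dissimilarities are flagged undefined
  flat <- matrix(0.5, 3, 3); diag(flat) <- 1
  expect_warning(cc <- cophenetic_coefficient(flat), "undefined")
  expect_true(is.nan(cc))
})

test_that("rank selection maximizes cophenetic with smallest-rank tie-break", {
  mk <- function(rank, coph) structure(
    list(rank = as.integer(rank), cophenetic = coph,
         silhouette_consensus = NA_real_, silhouette_coef = NA_real_,
         silhouette_basis = NA_real_),
    class = "nmf_consensus")
  expect_equal(select_rank(list(mk(2, 0.95), mk(3, 0.99), mk(4, 0.90)))$rank, 3)
  expect_equal(select_rank(list(mk(2, 0.99), mk(3, 0.99)))$rank, 2)
  expect_warning(rs <- select_rank(list(mk(2, NaN), mk(3, 0.8), mk(4, 0.7))),
                 "excluding")
  expect_equal(rs$rank, 3)
})

test_that("cluster assignment takes the argmax coefficient with low-index tie-break", {
  H <- cbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0))
  colnames(H) <- c("s1", "s2")
  W <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  a <- assign_clusters(fake_fit(W, H))
  expect_equal(unname(a$labels), c(2, 1))
  expect_equal(unname(a$membership[, "s1"]), c(0.1, 0.7, 0.2))
  expect_equal(colSums(a$membership), c(s1 = 1, s2 = 1))
  H0 <- H; H0[, 2] <- 0
  expect_error(assign_clusters(fake_fit(W, H0)), "all-zero")
})

test_that("basis specificity hits the entropy endpoints and is scale-invariant", {
  W <- rbind(uniform = c(1, 1, 1) / 3,
             onehot = c(1, 0, 0),
             half = c(0.5, 0.5, 0),
             zero = c(0, 0, 0))
  H <- matrix(1, 3, 2, dimnames = list(NULL, c("s1", "s2")))
  sp <- basis_specificity(fake_fit(W, H))
  expect_equal(unname(sp$score["uniform"]), 0, tolerance = 1e-12)
  expect_equal(unname(sp$score["onehot"]), 1, tolerance = 1e-12)
  expect_equal(unname(sp$score["half"]), 1 - 1 / log2(3), tolerance = 1e-12)
  expect_true(is.nan(sp$score["zero"]))
  expect_true(sp$flagged["zero"])
  # profiles of non-flagged genes sum to one
  expect_equal(unname(rowSums(sp$profile[1:3, ])), rep(1, 3))
  # global rescaling of W leaves every score unchanged
  sp2 <- basis_specificity(fake_fit(17.3 * W, H))
  expect_equal(sp2$score, sp$score)
})

test_that("top specific genes are ranked within their own program", {
  set.seed(2)
  W <- matrix(runif(30), 10, 3, dimnames = list(paste0("g", 1:10), NULL))
  H <- matrix(1, 3, 4, dimnames = list(NULL, paste0("s", 1:4)))
  sp <- basis_specificity(fake_fit(W, H))
  top <- top_specific_genes(sp, m = 2)
  for (q in unique(top$cluster)) {
    ours <- top$score[top$cluster == q]
    all_q <- sort(sp$score[sp$cluster == q], decreasing = TRUE)
    expect_equal(ours, unname(head(all_q, length(ours))))
  }
})
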