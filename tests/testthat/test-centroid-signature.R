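test_that("class-vs-rest t-statistics match the pooled two-sample formula", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  lab <- c(1, 1, 1, 2, 2, 2)
  tmat <- class_t_statistics(expr_matrix(m), lab)
  expect_equal(unname(tmat["1", "g1"]), -3 / sqrt(2 / 3), tolerance = 1e-12)
  # swapping the two classes negates every statistic
  tmat2 <- class_t_statistics(expr_matrix(m), 3 - lab)
  expect_equal(unname(tmat2["2", "g1"]), unname(tmat["1", "g1"]))
  expect_equal(unname(tmat2["1", "g1"]), -unname(tmat["1", "g1"]))
})

test_that("degenerate genes get zero or infinite t as appropriate", {
  m <- rbind(flat = rep(5, 6),              # equal means, zero variance -> 0
             clean = c(9, 9, 9, 2, 2, 2))   # zero pooled variance -> +Inf
  colnames(m) <- paste0("s", 1:6)
  tmat <- class_t_statistics(expr_matrix(m), c(1, 1, 1, 2, 2, 2))
  expect_equal(unname(tmat["1", "flat"]), 0)
  expect_equal(unname(tmat["1", "clean"]), Inf)
  expect_equal(unname(tmat["2", "clean"]), -Inf)
})

test_that("signature construction selects disjoint class-owned genes with exact centroids", {
  sep <- separable_expr(n_per_class = 5, markers_per_class = 4, high = 7)
  sig <- build_signature(sep$expr, sep$labels, n_per_class = 3)
  expect_length(sig$genes, 9)
  expect_equal(anyDuplicated(sig$genes), 0L)
  # markers of class c are owned by class c
  for (cl in 1:3) {
    own <- sig$genes[sig$class_of_gene == cl]
    expect_true(all(own %in% sprintf("G%03d", (cl - 1) * 4 + 1:4)))
    # centroids equal the class means exactly
    expect_equal(unname(sig$centroids[as.character(cl), own]),
                 unname(rowMeans(sep$expr$values[own, sep$labels == cl])))
  }
  expect_error(build_signature(sep$expr, sep$labels, n_per_class = 10),
               "owns only")
})

test_that("a 20-per-class signature over 3 classes has 60 genes", {
  ds <- generate_dataset(small_config(seed = 12))
  sel <- select_genes(normalize_counts(ds$counts), n_top = 200)
  sig <- build_signature(sel, ds$true_labels, n_per_class = 20)
  expect_length(sig$genes, 60)
  expect_equal(as.vector(table(sig$class_of_gene)), rep(20L, 3))
})

test_that("signature selection equals the brute-force ownership oracle on a tiny instance", {
  set.seed(21)
  m <- matrix(rexp(9 * 12, 1 / 10), 9, 12,
              dimnames = list(paste0("g", 1:9), paste0("s", 1:12)))
  lab <- rep(1:3, each = 4)
  sig <- build_signature(expr_matrix(m), lab, n_per_class = 2)
  # oracle: recompute t per gene with t.test machinery, assign by max |t|,
  # then take the top 2 per class
  tor <- sapply(1:3, function(cl) apply(m, 1, function(x) {
    a <- x[lab == cl]; b <- x[lab != cl]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  }))
  owner <- apply(abs(tor), 1, which.max)
  expected <- unlist(lapply(1:3, function(cl) {
    own <- rownames(m)[owner == cl]
    own[order(-abs(tor[own, cl]), own)][1:2]
  }))
  expect_identical(sig$genes, expected)
})

test_that("nearest-centroid classification honors distance and tie rules", {
  cen <- rbind(`1` = c(0, 0), `2` = c(3, 4))
  colnames(cen) <- c("gA", "gB")
  sig <- structure(list(classes = 1:2, n_per_class = 1L,
                        genes = c("gA", "gB"),
                        class_of_gene = c(gA = 1L, gB = 2L),
                        centroids = cen,
                        training_stats = data.frame(gene_id = c("gA", "gB"),
                                                    mean = c(0, 0), sd = c(1, 1))),
                   class = "centroid_signature")
  m <- cbind(at1 = c(0, 0), at2 = c(3, 4), mid = c(1.5, 2))
  rownames(m) <- c("gA", "gB")
  res <- classify_nearest_centroid(sig, expr_matrix(m))
  expect_equal(unname(res$labels), c(1, 2, 1))   # tie -> first class
  expect_equal(unname(res$distances["at1", ]), c(0, 5))
  expect_equal(unname(res$distances["at2", ]), c(5, 0))
  # missing genes produce an informative error
  bad <- expr_matrix(matrix(1, 1, 1, dimnames = list("gA", "s")))
  expect_error(classify_nearest_centroid(sig, bad), "gB")
  # distances feed the risk models under d1..dk names
  d <- centroid_distance_features(sig, expr_matrix(m))
  expect_equal(colnames(d), c("d1", "d2"))
  expect_equal(unname(d[, "d1"]), unname(res$distances[, "1"]))
})

test_that("correlation classification matches exhaustive evaluation and affine invariance", {
  set.seed(31)
  cen <- matrix(rnorm(3 * 10), 3, 10,
                dimnames = list(1:3, paste0("g", 1:10)))
  m <- matrix(rexp(10 * 5, 1 / 5), 10, 5,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  res <- classify_by_correlation(cen, expr_matrix(m))
  # oracle: median-center then all correlations by brute force
  mc <- m - apply(m, 1, median)
  for (s in 1:5) {
    rr <- sapply(1:3, function(cl) cor(mc[, s], cen[cl, ]))
    expect_equal(unname(res$correlations[s, ]), rr)
    expect_equal(unname(res$labels[s]), which.max(rr))
  }
  # per-sample affine rescaling leaves correlations unchanged (fixed
  # centering vector, so the pure Pearson invariance applies)
  m2 <- sweep(sweep(m, 2, c(2, 3, 4, 5, 6), `*`), 2, c(1, 2, 3, 4, 5), `+`)
  r1 <- classify_by_correlation(cen, expr_matrix(m), center = FALSE)
  r2 <- classify_by_correlation(cen, expr_matrix(m2), center = FALSE)
  expect_equal(r2$correlations, r1$correlations, tolerance = 1e-12)
  expect_equal(r2$labels, r1$labels)
})

test_that("nearest-centroid distance is not shift-invariant (negative control)", {
  sep <- separable_expr(n_per_class = 4, markers_per_class = 3, high = 6)
  sig <- build_signature(sep$expr, sep$labels, n_per_class = 2)
  base <- classify_nearest_centroid(sig, sep$expr)
  shifted <- expr_matrix(sep$expr$values + 50, sep$expr$is_mito)
  res <- classify_nearest_centroid(sig, shifted)
  expect_false(isTRUE(all.equal(res$distances, base$distances)))
})

test_that("a zero-variance sample is flagged unclassified by correlation", {
  cen <- matrix(c(1, 2, 3, 3, 2, 1), 2, 3, byrow = TRUE,
                dimnames = list(1:2, paste0("g", 1:3)))
  # two identical flat samples: the per-gene medians equal their values, so
  # the centered vectors are constant zero and correlation is undefined
  m <- cbind(flat1 = c(5, 5, 5), flat2 = c(5, 5, 5), ok = c(1, 2, 3))
  rownames(m) <- paste0("g", 1:3)
  res <- classify_by_correlation(cen, expr_matrix(m))
  expect_true(is.na(res$labels["flat1"]))
  expect_true(is.na(res$labels["flat2"]))
  expect_false(is.na(res$labels["ok"]))
})

test_that("cross-validation is deterministic and exact on separable data", {
  sep <- separable_expr(n_per_class = 10, markers_per_class = 8, high = 9)
  cv <- cross_validate_signature(sep$expr, sep$labels, N_range = 1:5,
                                 repeats = 3, seed = 99)
  expect_equal(cv$per_N_errors$train_error, rep(0, 5))
  expect_equal(cv$per_N_errors$test_error, rep(0, 5))
  expect_equal(cv$chosen_N, 1L)   # parsimony at equal error
  cv2 <- cross_validate_signature(sep$expr, sep$labels, N_range = 1:5,
                                  repeats = 3, seed = 99)
  expect_identical(cv$per_N_errors, cv2$per_N_errors)
})

test_that("signatures survive a JSON round trip", {
  sep <- separable_expr(n_per_class = 5, markers_per_class = 4, high = 7)
  sig <- build_signature(sep$expr, sep$labels, n_per_class = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature_json(sig, path, seed = 123)
  back <- read_signature_json(path)
  expect_equal(back$genes, sig$genes)
  expect_equal(back$centroids, sig$centroids)
  expect_equal(back$class_of_gene, sig$class_of_gene)
  expect_equal(back$training_stats$mean, sig$training_stats$mean)
})
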