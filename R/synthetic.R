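#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set describing a synthetic bulk
#' RNA-seq cohort with `k` planted expression subtypes. Counts are negative
#' binomial around per-gene baseline means (log2 means ~ Normal(4, 2), a
#' realistic dynamic range that leaves most medians above 1); each subtype
#' over-expresses its own program genes by `signature_log2fc`; three
#' disjoint histological lineage marker sets (LUAD, LUSC, NET) receive a
#' subtype-dependent share of marker expression controlled by
#' `cross_lineage_fraction`; survival is exponential with a per-subtype
#' baseline hazard and independent exponential censoring calibrated to the
#' requested overall censoring fraction; tumor stage I is assigned with a
#' per-subtype probability, the remaining mass split evenly over II-IV.
#'
#' The negative binomial is parameterized by mean and dispersion with
#' variance = mu + dispersion * mu^2 (i.e. `size = 1/dispersion` in
#' [stats::rnbinom()]).
#'
#' @param n_subtypes number of planted subtypes k.
#' @param samples_per_subtype integer vector of group sizes (recycled to k).
#' @param n_genes total number of genes (including mitochondrial and
#'   lineage marker genes).
#' @param n_signature_genes_per_subtype size of each subtype's private
#'   over-expressed gene program.
#' @param signature_log2fc log2 fold-change of a subtype's program genes in
#'   its own subtype relative to all others.
#' @param nb_dispersion negative binomial dispersion (> 0).
#' @param library_size_range min/max of the uniform per-sample library-size
#'   multiplier.
#' @param n_mito_genes number of mitochondrial genes; these get high
#'   baseline means (log2 means ~ Normal(9, 1)) so the mitochondrial
#'   exclusion rule has bite.
#' @param lineage_set_sizes sizes of the LUAD, LUSC and NET marker sets.
#' @param cross_lineage_fraction per-subtype fraction of marker expression
#'   carried by the two off-lineage (LUSC + NET) sets; high values emulate
#'   a lineage-infidelity ("chaotic-like") subtype.
#' @param baseline_hazards per-subtype exponential hazard (per month).
#' @param censoring_rate target overall fraction of censored samples.
#' @param stage_subtype_odds per-subtype probability of stage I.
#' @param mutation_rates named list of per-subtype probabilities for the
#'   optional driver flags (TP53, EGFR, KRAS, ALK_fusion) used by the risk
#'   model registry.
#' @param grade_probs k x 3 matrix of per-subtype probabilities over
#'   histologic grades 1-3.
#' @param seed integer RNG seed for the per-sample draws (counts, survival,
#'   clinical covariates); the whole dataset is reproducible from
#'   `seed` + `gene_seed`.
#' @param gene_seed RNG seed for the gene-level parameters (baseline
#'   means). It defaults to a fixed constant, deliberately separate from
#'   `seed`: two cohorts generated with different `seed`s then share the
#'   same transcriptome blueprint — as two real cohorts share gene-level
#'   baseline expression — so signatures trained on one transfer to the
#'   other.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subtypes = 3,
                             samples_per_subtype = 50,
                             n_genes = 2000,
                             n_signature_genes_per_subtype = 200,
                             signature_log2fc = 2,
                             nb_dispersion = 0.2,
                             library_size_range = c(0.7, 1.3),
                             n_mito_genes = 20,
                             lineage_set_sizes = c(30, 30, 30),
                             cross_lineage_fraction = c(0.05, 0.15, 0.5),
                             baseline_hazards = c(0.010, 0.025, 0.060),
                             censoring_rate = 0.3,
                             stage_subtype_odds = c(0.70, 0.50, 0.35),
                             mutation_rates = list(
                               TP53 = c(0.15, 0.55, 0.35),
                               EGFR = c(0.45, 0.25, 0.25),
                               KRAS = c(0.10, 0.10, 0.15),
                               ALK_fusion = c(0.05, 0.10, 0.05)),
                             grade_probs = rbind(c(0.6, 0.3, 0.1),
                                                 c(0.2, 0.4, 0.4),
                                                 c(0.1, 0.3, 0.6)),
                             seed = 1L,
                             gene_seed = 1000003L) {
  k <- as.integer(n_subtypes)
  if (k < 2) stop("n_subtypes must be >= 2")
  rec <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, k)
    if (length(x) != k) stop(sprintf("%s must have length 1 or k", what))
    x
  }
  samples_per_subtype <- rec(as.integer(samples_per_subtype), "samples_per_subtype")
  cross_lineage_fraction <- rec(cross_lineage_fraction, "cross_lineage_fraction")
  baseline_hazards <- rec(baseline_hazards, "baseline_hazards")
  stage_subtype_odds <- rec(stage_subtype_odds, "stage_subtype_odds")
  mutation_rates <- lapply(mutation_rates, rec, what = "mutation_rates")
  grade_probs <- matrix(grade_probs, nrow = k)

  if (any(samples_per_subtype < 1)) stop("samples_per_subtype must be positive")
  if (n_genes < n_mito_genes + sum(lineage_set_sizes) + k * n_signature_genes_per_subtype)
    stop("n_genes too small for the requested mito, lineage and program genes")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (length(library_size_range) != 2 || any(library_size_range <= 0) ||
      diff(library_size_range) < 0)
    stop("library_size_range must be an increasing pair of positive values")
  if (length(lineage_set_sizes) != 3 || any(lineage_set_sizes < 1))
    stop("lineage_set_sizes must be three positive integers")
  in01 <- function(x) all(x >= 0 & x <= 1)
  if (!in01(cross_lineage_fraction) || !in01(censoring_rate) ||
      !in01(stage_subtype_odds) || !in01(unlist(mutation_rates)))
    stop("probabilities must lie in [0, 1]")
  if (any(baseline_hazards <= 0)) stop("baseline_hazards must be > 0")

  cfg <- list(n_subtypes = k,
              samples_per_subtype = samples_per_subtype,
              n_genes = as.integer(n_genes),
              n_signature_genes_per_subtype = as.integer(n_signature_genes_per_subtype),
              signature_log2fc = signature_log2fc,
              nb_dispersion = nb_dispersion,
              library_size_range = library_size_range,
              n_mito_genes = as.integer(n_mito_genes),
              lineage_set_sizes = as.integer(lineage_set_sizes),
              cross_lineage_fraction = cross_lineage_fraction,
              baseline_hazards = baseline_hazards,
              censoring_rate = censoring_rate,
              stage_subtype_odds = stage_subtype_odds,
              mutation_rates = mutation_rates,
              grade_probs = grade_probs,
              seed = as.integer(seed),
              gene_seed = as.integer(gene_seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic cohort with planted subtypes and survival
#'
#' Draws a complete dataset from the generative model described in
#' [synthetic_config()]: a counts matrix, the true subtype labels, a
#' clinical/survival table, the three lineage marker gene sets and the
#' per-subtype program gene lists.
#'
#' @param config a `synthetic_config`.
#' @return A list of class `synthetic_dataset` with elements `counts`
#'   (a [count_matrix()]), `true_labels` (named integer vector in 1..k),
#'   `survival` (data frame: sample_id, time, event, age, sex, stage,
#'   driver flags, grade), `lineage_sets` (named list of gene id vectors)
#'   and `program_genes` (per-subtype gene id lists), plus the config.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- config$n_subtypes
  n <- sum(config$samples_per_subtype)
  labels <- rep(seq_len(k), config$samples_per_subtype)
  sample_ids <- sprintf("S%03d", seq_len(n))
  names(labels) <- sample_ids

  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  is_mito <- rep(FALSE, config$n_genes)
  if (config$n_mito_genes > 0) {
    mito_idx <- seq_len(config$n_mito_genes)
    gene_ids[mito_idx] <- sprintf("MT-G%03d", mito_idx)
    is_mito[mito_idx] <- TRUE
  }
  names(is_mito) <- gene_ids

  # gene role assignment: [mito | LUAD | LUSC | NET | programs 1..k | rest]
  cursor <- config$n_mito_genes
  take <- function(m) {
    idx <- cursor + seq_len(m)
    cursor <<- cursor + m
    idx
  }
  lineage_idx <- list(LUAD = take(config$lineage_set_sizes[1]),
                      LUSC = take(config$lineage_set_sizes[2]),
                      NET  = take(config$lineage_set_sizes[3]))
  program_idx <- lapply(seq_len(k), function(s)
    take(config$n_signature_genes_per_subtype))

  # gene-level parameters come from their own seed so that cohorts drawn
  # with different sample seeds share the same transcriptome blueprint
  set.seed(config$gene_seed)
  base_mean <- 2^rnorm(config$n_genes, mean = 4, sd = 2)
  base_mean[is_mito] <- 2^rnorm(sum(is_mito), mean = 9, sd = 1)
  set.seed(config$seed)

  # lineage markers keep their gene-specific baselines but are modulated by
  # the subtype's lineage shares, so that within a sample the expected split
  # of marker expression across the three sets follows those shares (the
  # off-lineage share equals cross_lineage_fraction) while marker genes stay
  # in the same dynamic range as the rest of the transcriptome.
  lineage_share <- function(f) c(LUAD = 1 - f, LUSC = f / 2, NET = f / 2)

  mu <- matrix(base_mean, nrow = config$n_genes, ncol = n)
  fc <- 2^config$signature_log2fc
  for (s in seq_len(k)) {
    cols <- which(labels == s)
    mu[program_idx[[s]], cols] <- mu[program_idx[[s]], cols] * fc
    sh <- lineage_share(config$cross_lineage_fraction[s])
    for (ln in names(lineage_idx)) {
      mu[lineage_idx[[ln]], cols] <-
        3 * sh[[ln]] * base_mean[lineage_idx[[ln]]]
    }
  }
  lib <- runif(n, config$library_size_range[1], config$library_size_range[2])
  mu <- sweep(mu, 2, lib, `*`)

  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                   nrow = config$n_genes,
                   dimnames = list(gene_ids, sample_ids))

  survival <- .simulate_survival(labels, config)

  structure(list(counts = count_matrix(counts, is_mito),
                 true_labels = labels,
                 survival = survival,
                 lineage_sets = lapply(lineage_idx, function(i) gene_ids[i]),
                 program_genes = lapply(program_idx, function(i) gene_ids[i]),
                 config = config),
            class = "synthetic_dataset")
}

# Exponential survival by subtype hazard; independent exponential censoring
# with its rate calibrated (by root finding) so the expected censored
# fraction matches censoring_rate.
.simulate_survival <- function(labels, config) {
  n <- length(labels)
  haz <- config$baseline_hazards[labels]
  time_event <- rexp(n, rate = haz)
  if (config$censoring_rate > 0) {
    target <- min(config$censoring_rate, 0.99)
    expected_cens <- function(r) mean(r / (r + haz)) - target
    r <- uniroot(expected_cens, c(1e-9, 1e6), tol = 1e-10)$root
    cens <- rexp(n, rate = r)
  } else {
    cens <- rep(Inf, n)
  }
  event <- as.integer(time_event <= cens)
  time <- pmin(time_event, cens)

  k <- config$n_subtypes
  p1 <- config$stage_subtype_odds[labels]
  u <- runif(n)
  stage <- ifelse(u < p1, 1L, 1L + sample.int(3, n, replace = TRUE))

  df <- data.frame(sample_id = names(labels),
                   time = time,
                   event = event,
                   age = round(rnorm(n, 65, 10)),
                   sex = rbinom(n, 1, 0.5),
                   stage = stage,
                   stringsAsFactors = FALSE)
  for (mname in names(config$mutation_rates))
    df[[mname]] <- rbinom(n, 1, config$mutation_rates[[mname]][labels])
  gp <- config$grade_probs
  df$grade <- vapply(labels, function(s)
    sample.int(ncol(gp), 1, prob = gp[s, ]), integer(1))
  rownames(df) <- NULL
  df
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d genes x %d samples, k = %d planted subtypes\n",
    nrow(x$counts$values), ncol(x$counts$values), x$config$n_subtypes))
  invisible(x)
}

#' Exactly factorizable non-negative matrix
#'
#' Returns V = W0 H0 for strictly positive random W0 (genes x rank) and H0
#' (rank x samples), so an exact NMF of the stated rank exists. Used as an
#' oracle input when testing factorization code.
#'
#' @param n_genes,n_samples dimensions of V.
#' @param rank inner dimension (must not exceed either dimension).
#' @param seed RNG seed.
#' @return An [expr_matrix()] with strictly positive entries.
#' @export
generate_factorizable_matrix <- function(n_genes, n_samples, rank, seed = 1L) {
  if (rank > min(n_genes, n_samples))
    stop("rank must not exceed min(n_genes, n_samples)")
  set.seed(seed)
  W0 <- matrix(runif(n_genes * rank, 0.5, 2), n_genes, rank)
  H0 <- matrix(runif(rank * n_samples, 0.5, 2), rank, n_samples)
  V <- W0 %*% H0
  dimnames(V) <- list(sprintf("G%05d", seq_len(n_genes)),
                      sprintf("S%03d", seq_len(n_samples)))
  expr_matrix(V)
}

#' Write a synthetic dataset to disk
#'
#' Writes the counts (gene x sample TSV), gene annotation TSV
#' (gene_id, is_mito, lineage_set), clinical/survival TSV and a JSON file
#' with the ground truth (labels, program genes, lineage sets).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             annotation = file.path(dir, "gene_annotation.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_matrix_tsv(dataset$counts, paths[["counts"]])

  gene_ids <- rownames(dataset$counts$values)
  lin <- rep(NA_character_, length(gene_ids))
  for (ln in names(dataset$lineage_sets))
    lin[gene_ids %in% dataset$lineage_sets[[ln]]] <- ln
  write.table(data.frame(gene_id = gene_ids,
                         is_mito = unname(dataset$counts$is_mito),
                         lineage_set = lin),
              paths[["annotation"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$survival, paths[["clinical"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(true_labels = as.list(dataset$true_labels),
                            program_genes = dataset$program_genes,
                            lineage_sets = dataset$lineage_sets),
                       paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
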