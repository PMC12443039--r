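#' Default pipeline configuration
#'
#' Returns the full nested configuration understood by [run_pipeline()],
#' with every option at its default. Unknown keys in a user configuration
#' are rejected by name during validation.
#'
#' @return Nested named list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "pipeline_out",
    simulate = list(enabled = TRUE),    # extra keys = synthetic_config() args
    inputs = list(counts = NULL, annotation = NULL, clinical = NULL,
                  lineage_sets = NULL),
    normalization = list(method = "median_ratio", n_top = 5000,
                         median_min = 1, log_scale = FALSE),
    nmf = list(ranks = 2:6, n_runs = 30, max_iter = 2000,
               conn_stop = 10, conn_interval = 10),
    signature = list(N_range = 1:30, repeats = 100, train_fraction = 0.7,
                     n_per_class = NULL, standardize = FALSE),
    survival = list(models = c("A", "B", "C", "D", "E", "F", "G", "H", "I"),
                    horizon = NULL))
}

.validate_config <- function(config) {
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(config), names(defaults))) {
    if (!is.list(defaults[[sec]]) || sec == "simulate") next
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad))
      stop(sprintf("unknown configuration key(s) in '%s': %s",
                   sec, paste(bad, collapse = ", ")))
  }
  extra_sim <- setdiff(names(config$simulate),
                       c("enabled", names(formals(synthetic_config))))
  if (length(extra_sim))
    stop("unknown configuration key(s) in 'simulate': ",
         paste(extra_sim, collapse = ", "))
  cfg <- defaults
  for (sec in names(config)) {
    if (is.list(defaults[[sec]]) && !is.null(names(config[[sec]])))
      cfg[[sec]] <- modifyList(defaults[[sec]], config[[sec]])
    else cfg[[sec]] <- config[[sec]]
  }
  cfg
}

#' Read a pipeline configuration file
#'
#' @param path YAML or JSON configuration file.
#' @return The validated configuration (defaults filled in).
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  .validate_config(cfg)
}

.stage_order <- c("simulate", "normalize", "subtype", "signature",
                  "lineage", "risk")

#' Run the subtype discovery and risk-modeling pipeline
#'
#' Executes, in order: simulate (optional) -> normalize/select ->
#' consensus NMF over the configured ranks with rank selection ->
#' cluster assignment and basis specificity -> centroid signature with
#' cross-validated size selection -> lineage scores -> survival risk
#' models. Every artifact is written under `output_dir` and listed, with
#' an MD5 checksum, in `manifest.json` together with the effective
#' configuration, so two runs with identical configuration and seed
#' produce bitwise-identical manifests.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML/JSON file.
#' @param stages subset of stages to run; earlier stages' outputs are read
#'   back from `output_dir`.
#' @return Invisibly, the manifest (named list with `files`, `config`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = .stage_order) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- .validate_config(config)
  stages <- match.arg(stages, .stage_order, several.ok = TRUE)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  note <- function(p) files <<- unique(c(files, p))
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  path <- function(...) file.path(out, ...)

  run_stage("simulate", function() {
    if (!isTRUE(cfg$simulate$enabled)) return(NULL)
    args <- cfg$simulate[setdiff(names(cfg$simulate), "enabled")]
    if (is.null(args$seed)) args$seed <- cfg$seed
    ds <- generate_dataset(do.call(synthetic_config, args))
    p <- write_dataset(ds, path("synthetic"))
    for (f in p) note(f)
    state$counts <- ds$counts
    state$clinical <- ds$survival
    state$lineage_sets <- ds$lineage_sets
  })

  get_counts <- function() {
    if (is.null(state$counts)) {
      src <- cfg$inputs$counts
      if (is.null(src)) src <- path("synthetic", "counts.tsv")
      ann <- cfg$inputs$annotation
      if (is.null(ann) && file.exists(path("synthetic", "gene_annotation.tsv")))
        ann <- path("synthetic", "gene_annotation.tsv")
      state$counts <- read_matrix_tsv(src, annotation = ann, what = "counts")
    }
    state$counts
  }
  get_clinical <- function() {
    if (is.null(state$clinical)) {
      src <- cfg$inputs$clinical
      if (is.null(src)) src <- path("synthetic", "clinical.tsv")
      state$clinical <- read.delim(src, stringsAsFactors = FALSE)
    }
    state$clinical
  }
  get_lineage_sets <- function() {
    if (is.null(state$lineage_sets)) {
      src <- cfg$inputs$lineage_sets
      if (is.null(src)) src <- cfg$inputs$annotation
      if (is.null(src)) src <- path("synthetic", "gene_annotation.tsv")
      state$lineage_sets <- read_lineage_sets(src)
    }
    state$lineage_sets
  }

  run_stage("normalize", function() {
    expr <- normalize_counts(get_counts(), method = cfg$normalization$method)
    sel <- select_genes(expr, n_top = cfg$normalization$n_top,
                        median_min = cfg$normalization$median_min,
                        log_scale = cfg$normalization$log_scale)
    state$expr <- expr
    state$selected <- sel
    note(write_matrix_tsv(sel, path("selected_expression.tsv")))
  })
  get_selected <- function() {
    if (is.null(state$selected))
      state$selected <- read_matrix_tsv(path("selected_expression.tsv"),
                                        what = "expression")
    state$selected
  }

  run_stage("subtype", function() {
    sel <- get_selected()
    results <- lapply(cfg$nmf$ranks, function(k) {
      res <- consensus_over_runs(sel, rank = k, n_runs = cfg$nmf$n_runs,
                                 base_seed = cfg$seed + 1000 * k,
                                 max_iter = cfg$nmf$max_iter,
                                 conn_stop = cfg$nmf$conn_stop,
                                 conn_interval = cfg$nmf$conn_interval)
      cm <- data.frame(sample_id = rownames(res$consensus), res$consensus,
                       check.names = FALSE)
      f <- path(sprintf("consensus_rank%d.tsv", k))
      write.table(cm, f, sep = "\t", quote = FALSE, row.names = FALSE)
      note(f)
      res
    })
    rs <- select_rank(results)
    f <- path("rank_selection.tsv")
    write.table(rs$curve, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
    best <- results[[match(rs$rank, vapply(results, `[[`, integer(1), "rank"))]]$best_fit
    assign <- assign_clusters(best)
    f <- path("subtype_assignments.tsv")
    write.table(data.frame(sample_id = names(assign$labels),
                           subtype = assign$labels),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
    for (nm in c("W", "H")) {
      f <- path(sprintf("nmf_%s.tsv", nm))
      mat <- best[[nm]]
      df <- data.frame(id = if (nm == "W") rownames(mat) else paste0("program", seq_len(nrow(mat))),
                       mat, check.names = FALSE)
      write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      note(f)
    }
    spec <- basis_specificity(best)
    f <- path("gene_specificity.tsv")
    write.table(data.frame(gene_id = names(spec$score),
                           score = unname(spec$score),
                           cluster = unname(spec$cluster)),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
    state$assignment <- assign
    state$rank <- rs$rank
  })
  get_labels <- function() {
    if (is.null(state$assignment)) {
      tab <- read.delim(path("subtype_assignments.tsv"), stringsAsFactors = FALSE)
      state$assignment <- list(labels = setNames(tab$subtype, tab$sample_id))
    }
    state$assignment$labels
  }

  run_stage("signature", function() {
    sel <- get_selected()
    lab <- get_labels()
    cv <- cross_validate_signature(sel, lab, N_range = cfg$signature$N_range,
                                   repeats = cfg$signature$repeats,
                                   train_fraction = cfg$signature$train_fraction,
                                   seed = cfg$seed,
                                   standardize = cfg$signature$standardize)
    f <- path("cv_report.tsv")
    write.table(cv$per_N_errors, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
    n_final <- cfg$signature$n_per_class
    if (is.null(n_final)) n_final <- cv$chosen_N
    sig <- build_signature(sel, lab, n_per_class = n_final)
    note(write_signature_json(sig, path("signature.json"), seed = cfg$seed))
    state$signature <- sig
  })
  get_signature <- function() {
    if (is.null(state$signature))
      state$signature <- read_signature_json(path("signature.json"))
    state$signature
  }

  run_stage("lineage", function() {
    if (is.null(state$expr)) state$expr <- normalize_counts(get_counts(),
                                       method = cfg$normalization$method)
    sc <- lineage_score(state$expr, get_lineage_sets())
    f <- path("lineage_scores.tsv")
    write.table(sc, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
  })

  run_stage("risk", function() {
    sel <- get_selected()
    clin <- get_clinical()
    clin <- clin[match(colnames(sel$values), clin$sample_id), ]
    if (!is.null(cfg$survival$horizon))
      clin <- truncate_followup(clin, cfg$survival$horizon)
    cohort <- list(expr = sel, survival = clin)
    reg <- run_model_registry(cohort, cohort, get_signature(),
                              models = cfg$survival$models)
    f <- path("risk_models.tsv")
    write.table(reg, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
    km <- kaplan_meier(clin, get_labels()[clin$sample_id])
    f <- path("km_curves.tsv")
    write.table(km, f, sep = "\t", quote = FALSE, row.names = FALSE)
    note(f)
  })

  manifest <- list(
    package = paste0("nmfsubtypes ",
                     as.character(utils::packageVersion("nmfsubtypes"))),
    config = cfg,
    files = lapply(sort(files), function(f)
      list(path = sub(paste0("^", out, "/"), "", f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
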