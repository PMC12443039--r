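.check_survival <- function(data, needed = c("time", "event")) {
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop("survival table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(data$time <= 0)) stop("survival times must be positive")
  used <- data[needed]
  if (anyNA(used)) stop("missing values in required survival columns")
  invisible(data)
}

#' Administrative censoring at a follow-up horizon
#'
#' Converts follow-up beyond `horizon` (e.g. 120 months for a 10-year
#' analysis) to censoring at the horizon: times are capped and events after
#' the horizon become non-events. A horizon beyond the last observed time
#' changes nothing.
#'
#' @param data survival data frame with `time` and `event` columns.
#' @param horizon positive time (same units as `time`).
#' @return The data frame with truncated `time`/`event`.
#' @export
truncate_followup <- function(data, horizon) {
  .check_survival(data)
  if (horizon <= 0) stop("horizon must be positive")
  over <- data$time > horizon
  data$event[over] <- 0L
  data$time[over] <- horizon
  data
}

#' Harrell's concordance index
#'
#' Over all pairs comparable under right censoring — the member with the
#' earlier time has an observed event (at tied times, one event and one
#' censored observation count as comparable, with the event first) — the
#' fraction in which the earlier failure carries the higher risk score;
#' pairs tied on risk contribute 0.5.
#'
#' @param risk numeric risk scores (higher = shorter expected survival).
#' @param data survival data frame with `time` and `event`.
#' @return The c-index in `[0, 1]`, or `NaN` (with a warning) when no pair
#'   is comparable.
#' @export
concordance_index <- function(risk, data) {
  .check_survival(data)
  if (length(risk) != nrow(data)) stop("risk and data lengths differ")
  if (any(!is.finite(risk))) stop("risk scores must be finite")
  t <- data$time; e <- data$event
  # comparable[i, j]: i fails first and the ordering is observable
  comp <- (outer(t, t, `<`) & e == 1) |
    (outer(t, t, `==`) & outer(e == 1, e == 0, `&`))
  conc <- outer(risk, risk, `>`)
  tied <- outer(risk, risk, `==`)
  n_comp <- sum(comp)
  if (n_comp == 0) {
    warning("no comparable pairs; c-index undefined")
    return(NaN)
  }
  (sum(conc & comp) + 0.5 * sum(tied & comp)) / n_comp
}

#' Fit a Cox proportional-hazards model
#'
#' Thin wrapper around [survival::coxph()] (Efron ties by default) taking
#' the covariates as a named data frame aligned with the survival table.
#' Reports the coefficient table, the partial log-likelihoods, the
#' training c-index of the linear predictor ([concordance_index()]) and the
#' per-sample risk score. Constant covariates are dropped with a warning
#' (recorded in `dropped`). Non-convergence (e.g. monotone likelihood or a
#' singular design) is flagged; when flagged, a refit with a small ridge
#' penalty is attempted and reported as such.
#'
#' @param data survival data frame with `time` and `event`.
#' @param features data frame or matrix of covariates (one row per sample).
#' @param ties tie-handling method passed to [survival::coxph()].
#' @param ridge_theta ridge penalty used only in the fallback refit.
#' @return An object of class `cox_fit`: list with `coefficients` (data
#'   frame: term, coef, se, z, p), `loglik` (null, fitted), `cindex_train`,
#'   `risk` (linear predictor), `converged`, `ridged`, and the underlying
#'   `coxph` object as `fit`.
#' @export
fit_cox <- function(data, features, ties = "efron", ridge_theta = 0.1) {
  .check_survival(data)
  features <- as.data.frame(features)
  if (nrow(features) != nrow(data)) stop("features and data row counts differ")
  if (anyNA(features)) stop("missing values in model covariates")
  constant <- vapply(features, function(x) length(unique(x)) < 2, logical(1))
  dropped <- names(features)[constant]
  if (all(constant)) stop("all covariates are constant")
  if (any(constant)) {
    warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
    features <- features[!constant]
  }
  df <- cbind(data[c("time", "event")], features)
  terms <- names(features)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|out of iterations",
                conditionMessage(w), ignore.case = TRUE))
        flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (anyNA(stats::coef(fit))) flagged <- TRUE   # singular design
  ridged <- FALSE
  if (flagged) {
    fml_r <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ survival::ridge(",
      paste(terms, collapse = ", "), ", theta = ", ridge_theta, ")"))
    fit <- suppressWarnings(survival::coxph(fml_r, data = df, ties = ties))
    ridged <- TRUE
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm),
                      coef = sm[, "coef"],
                      se = sm[, if ("se(coef)" %in% colnames(sm)) "se(coef)" else "se2"],
                      p = sm[, ncol(sm)],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  lp <- unname(fit$linear.predictors)
  structure(list(coefficients = coefs,
                 loglik = fit$loglik,
                 cindex_train = concordance_index(lp, data),
                 risk = lp,
                 converged = !flagged,
                 ridged = ridged,
                 terms = terms,
                 dropped = dropped,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: %d covariates, train c-index %.3f%s\n",
              length(x$terms), x$cindex_train,
              if (x$ridged) " (ridge fallback)" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test between nested Cox fits
#'
#' @param full,nested `cox_fit` objects fitted to the same samples, with
#'   the nested model's covariates a subset of the full model's. `nested`
#'   may be `NULL` to test against the null (intercept-only) model.
#' @return List with `statistic`, `df`, `p`.
#' @export
cox_lrt <- function(full, nested = NULL) {
  ll_full <- full$loglik[2]
  if (is.null(nested)) {
    ll_nested <- full$loglik[1]
    df <- length(full$terms)
  } else {
    ll_nested <- nested$loglik[2]
    df <- length(full$terms) - length(nested$terms)
  }
  stat <- 2 * (ll_full - ll_nested)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

# covariate groups of the nine prognostic risk models
.registry_models <- list(
  A = list(desc = "stage",                       groups = "stage"),
  B = list(desc = "mutations/fusions",           groups = "mutations"),
  C = list(desc = "expression subtype",          groups = "subtype"),
  D = list(desc = "histologic grade",            groups = "grade"),
  E = list(desc = "stage + mutations",           groups = c("stage", "mutations")),
  F = list(desc = "subtype + stage",             groups = c("subtype", "stage")),
  G = list(desc = "subtype + mutations",         groups = c("subtype", "mutations")),
  H = list(desc = "subtype + grade",             groups = c("subtype", "grade")),
  I = list(desc = "subtype + stage + mutations", groups = c("subtype", "stage", "mutations")))

.mutation_cols <- c("TP53", "EGFR", "KRAS", "ALK_fusion")

.registry_features <- function(survival_df, dists, groups) {
  cols <- list()
  for (g in groups) {
    cols[[g]] <- switch(g,
      stage = {
        if (!"stage" %in% names(survival_df)) return(NULL)
        data.frame(stage = as.numeric(survival_df$stage))
      },
      mutations = {
        if (!all(.mutation_cols %in% names(survival_df))) return(NULL)
        survival_df[.mutation_cols]
      },
      grade = {
        if (!"grade" %in% names(survival_df) || anyNA(survival_df$grade)) return(NULL)
        data.frame(grade = as.numeric(survival_df$grade))
      },
      subtype = as.data.frame(dists))
  }
  out <- do.call(cbind, cols)
  names(out) <- unlist(lapply(cols, names), use.names = FALSE)
  out
}

#' Run the nine-model prognostic risk registry
#'
#' Trains Cox models A-I on the training cohort — (A) stage, (B) driver
#' mutations/fusions, (C) expression subtype encoded as the Euclidean
#' distances to the k subtype centroids, (D) histologic grade, and the
#' combinations (E) stage+mutations, (F) subtype+stage,
#' (G) subtype+mutations, (H) subtype+grade, (I) subtype+stage+mutations —
#' then applies the trained coefficients to the test cohort and reports
#' Harrell's c-index in both. For each single-modality model a
#' likelihood-ratio p-value for adding the expression-subtype distances is
#' reported (A vs F, B vs G, D vs H; model C is tested against the null).
#' Models whose variables are absent from a cohort are evaluated where
#' possible (e.g. train-only when the test cohort lacks grade) or skipped
#' with a reason.
#'
#' @param train,test lists with elements `expr` (an [expr_matrix()]) and
#'   `survival` (a data frame with `time`, `event`, `stage`, optional
#'   mutation flags and `grade`).
#' @param sig a `centroid_signature` used for the distance features.
#' @param models subset of model ids to run.
#' @param standardize passed to [centroid_distance_features()].
#' @return Data frame with one row per model: `model_id`, `description`,
#'   `cindex_train`, `cindex_test`, `lrt_p`, `note`. The fitted `cox_fit`
#'   objects are attached as the `fits` attribute.
#' @export
run_model_registry <- function(train, test, sig, models = names(.registry_models),
                               standardize = FALSE) {
  d_train <- centroid_distance_features(sig, train$expr, standardize)
  d_test <- centroid_distance_features(sig, test$expr, standardize)
  fits <- list()
  rows <- lapply(models, function(id) {
    spec <- .registry_models[[id]]
    x_tr <- .registry_features(train$survival, d_train, spec$groups)
    if (is.null(x_tr))
      return(data.frame(model_id = id, description = spec$desc,
                        cindex_train = NA_real_, cindex_test = NA_real_,
                        lrt_p = NA_real_, note = "missing variables in train"))
    fit <- suppressWarnings(fit_cox(train$survival, x_tr))
    fits[[id]] <<- fit
    x_te <- .registry_features(test$survival, d_test, spec$groups)
    note <- if (fit$ridged) "ridge fallback" else ""
    if (is.null(x_te)) {
      ci_te <- NA_real_
      note <- paste0(note, if (nzchar(note)) "; ",
                     "missing variables in test; train-only")
    } else {
      beta <- fit$coefficients$coef
      risk_te <- as.numeric(as.matrix(x_te[fit$terms]) %*% beta)
      ci_te <- concordance_index(risk_te, test$survival)
    }
    data.frame(model_id = id, description = spec$desc,
               cindex_train = fit$cindex_train, cindex_test = ci_te,
               lrt_p = NA_real_, note = note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  lrt_pairs <- list(A = "F", B = "G", D = "H")
  for (single in names(lrt_pairs)) {
    combined <- lrt_pairs[[single]]
    if (!is.null(fits[[single]]) && !is.null(fits[[combined]]) &&
        fits[[single]]$converged && fits[[combined]]$converged)
      out$lrt_p[out$model_id == single] <-
        cox_lrt(fits[[combined]], fits[[single]])$p
  }
  if (!is.null(fits[["C"]]))
    out$lrt_p[out$model_id == "C"] <- cox_lrt(fits[["C"]])$p
  attr(out, "fits") <- fits
  out
}

#' Kaplan-Meier survival curves by group
#'
#' Product-limit estimates per group, returned as step-function
#' coordinates. Every curve starts at S(0) = 1 and is non-increasing and
#' right-continuous.
#'
#' @param data survival data frame with `time` and `event`.
#' @param groups per-sample group labels (any atomic type).
#' @return Data frame with `group`, `time`, `surv`, `n_risk`, `n_event`
#'   (the time-0 row included for each group).
#' @export
kaplan_meier <- function(data, groups) {
  .check_survival(data)
  if (length(groups) != nrow(data)) stop("groups must match data rows")
  if (any(table(groups) == 0)) stop("every group must be non-empty")
  df <- data.frame(time = data$time, event = data$event, group = factor(groups))
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (is.null(sf$strata)) {
    strata <- setNames(length(sf$time), paste0("group=", levels(df$group)[1]))
  } else strata <- sf$strata
  idx <- rep(names(strata), strata)
  out <- data.frame(group = sub("^group=", "", idx),
                    time = sf$time, surv = sf$surv,
                    n_risk = sf$n.risk, n_event = sf$n.event,
                    stringsAsFactors = FALSE)
  zero <- data.frame(group = unique(out$group), time = 0, surv = 1,
                     n_risk = NA_integer_, n_event = 0L)
  zero$n_risk <- as.integer(table(df$group)[zero$group])
  out <- rbind(zero, out)
  out[order(out$group, out$time), , drop = FALSE]
}
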