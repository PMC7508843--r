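#' Patient-level stratified cross-validation folds
#'
#' Partitions patients into `k` disjoint folds, stratified by progressor
#' status so each fold carries the same proportion of progressing eyes
#' (within one patient). All observations of a patient share a fold —
#' validation is completely isolated from training.
#'
#' @param x a `cohort` or list of `eye_history`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the shuffled assignment.
#' @return a `fold_plan`: list with `folds` (list of patient-id character
#'   vectors), `progressor_proportion` per fold, and `patient_status`.
#' @export
make_folds <- function(x, k = 10L, seed = 1L) {
  histories <- if (inherits(x, "cohort")) x$histories else x
  pat <- vapply(histories, function(h) h$patient_id, "")
  conv <- vapply(histories, function(h) !is.na(h$event_month), TRUE)
  status <- tapply(conv, pat, any)
  prog <- names(status)[status]
  nonprog <- names(status)[!status]
  assert_that(length(prog) >= k,
              sprintf("need at least %d progressor patients for %d folds",
                      k, k),
              class = "drusenseq_degenerate")
  set.seed(seed)
  assign_stratum <- function(ids) {
    ids <- sample(ids)
    split(ids, rep_len(seq_len(k), length(ids)))
  }
  fp <- assign_stratum(prog)
  fn <- assign_stratum(nonprog)
  folds <- lapply(seq_len(k), function(i) sort(c(fp[[i]], fn[[i]])))
  prop <- vapply(folds, function(f) mean(status[f]), 0)
  structure(list(folds = folds, progressor_proportion = prop,
                 patient_status = status, k = k, seed = seed),
            class = "fold_plan")
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC, computed via the rank (Mann-Whitney) identity, which
#' equals the probability that a random positive scores above a random
#' negative (ties counted 1/2). Invariant under monotone transforms of the
#' scores. `NA` when only one class is present.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 (or logical) outcomes.
#' @return scalar in `[0, 1]`, or `NA`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall curve
#'
#' Precision and recall at every distinct score threshold (descending). The
#' curve's no-skill baseline equals the positive prevalence, attached as
#' attribute `prevalence`.
#'
#' @inheritParams roc_auc
#' @return data.frame `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE)   # one point per distinct threshold
  npos <- sum(y)
  out <- data.frame(
    threshold = s[last],
    recall = tp[last] / npos,
    precision = tp[last] / (tp[last] + fp[last])
  )
  attr(out, "prevalence") <- mean(labels)
  out
}

youden_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  thr <- sort(unique(scores))
  j <- vapply(thr, function(th) {
    sens <- mean(scores[labels == 1L] >= th)
    spec <- mean(scores[labels == 0L] < th)
    sens + spec - 1
  }, 0)
  thr[which.max(j)]
}

train_fold_models <- function(sequences, fold_plan, horizon, config, seed,
                              verbose = FALSE) {
  pats <- vapply(sequences, function(s) s$patient_id, "")
  lapply(seq_len(fold_plan$k), function(i) {
    hold <- fold_plan$folds[[i]]
    cfg <- config
    cfg$horizon_k <- as.integer(horizon)
    cfg$seed <- derive_seed(seed, 100L + i)
    train_seq <- sequences[!(pats %in% hold)]
    if (verbose) message(sprintf("fold %d/%d (horizon %d): %d training eyes",
                                 i, fold_plan$k, horizon, length(train_seq)))
    train_deep_sequence(train_seq, cfg)
  })
}

score_heldout <- function(sequences, fold_plan, models, horizon) {
  # score every observation of every eye with the model whose fold held the
  # eye's patient out; returns one row per non-censored observation
  hcol <- paste0("h", horizon)
  pats <- vapply(sequences, function(s) s$patient_id, "")
  rows <- list()
  for (i in seq_len(fold_plan$k)) {
    hold <- fold_plan$folds[[i]]
    for (s in sequences[pats %in% hold]) {
      stopifnot(!(s$patient_id %in% models[[i]]$train_patients))  # leakage guard
      risks <- predict_sequence(models[[i]], s$visits)
      n <- nrow(s$visits)
      kept <- (n - length(risks) + 1L):n       # most recent l visits
      lab <- s$labels[kept, hcol]
      ok <- lab != 2L
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        eye_id = s$eye_id, patient_id = s$patient_id, fold = i,
        obs_month = s$obs_months[kept][ok],
        score = risks[ok], label = lab[ok], stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

fold_auc_summary <- function(scored) {
  fa <- vapply(sort(unique(scored$fold)), function(i) {
    roc_auc(scored$score[scored$fold == i], scored$label[scored$fold == i])
  }, 0)
  list(fold_auc = fa, auc_mean = mean(fa, na.rm = TRUE),
       auc_sd = stats::sd(fa[!is.na(fa)]),
       pooled_auc = roc_auc(scored$score, scored$label))
}

#' Overall tenfold cross-validated performance
#'
#' Every non-censored observation is scored exactly once, by the fold model
#' that held its patient out (an eye with ten observations contributes ten
#' predictions). Reports per-horizon AUC as mean +/- sd over folds (matching
#' error bars derived from the folds) alongside the pooled-score AUC, plus
#' pooled precision-recall curves.
#'
#' @param cohort a `cohort` (or list of `labeled_sequence` via `sequences`).
#' @param horizons horizons (months) to evaluate.
#' @param config a [model_config()] (its `horizon_k`/`seed` are overridden
#'   per horizon and fold).
#' @param k folds.
#' @param seed experiment seed.
#' @param return_models keep the trained fold models in the report (needed to
#'   reuse them for the visit-variant setting).
#' @param verbose progress messages.
#' @return an `evaluation_report`: `per_horizon` (list with fold AUCs,
#'   mean/sd, pooled AUC, PR curve, scored-observation table), `folds`,
#'   `audit` and optionally `models`.
#' @export
overall_cv <- function(cohort, horizons = default_horizons(), config = model_config(),
                       k = 10L, seed = 1L, return_models = FALSE,
                       verbose = FALSE) {
  sequences <- build_labeled_sequences(cohort, horizons)
  fold_plan <- make_folds(cohort, k, derive_seed(seed, 7L))
  per_h <- list(); audits <- list(); models_out <- list()
  for (h in horizons) {
    models <- train_fold_models(sequences, fold_plan, h, config, seed,
                                verbose)
    scored <- score_heldout(sequences, fold_plan, models, h)
    sm <- fold_auc_summary(scored)
    per_h[[paste0("h", h)]] <- c(
      sm, list(pr = pr_curve(scored$score, scored$label), scored = scored)
    )
    audits[[paste0("h", h)]] <- data.frame(
      horizon = h, patient_id = scored$patient_id, fold = scored$fold,
      stringsAsFactors = FALSE
    )
    if (return_models) models_out[[paste0("h", h)]] <- models
  }
  rep <- structure(
    list(setting = "overall_cv", per_horizon = per_h, folds = fold_plan,
         audit = do.call(rbind, audits),
         models = if (return_models) models_out else NULL,
         horizons = horizons),
    class = "evaluation_report"
  )
  assert_no_leakage(rep)
  rep
}

#' Visit-variant performance
#'
#' For each visit count `v` (current + `v - 1` historic), scores eyes having
#' at least `v` visits at their `v`-th visit, using only the first `v`
#' visits, under the same patient-level fold models. Shows how performance
#' depends on the available history.
#'
#' @inheritParams overall_cv
#' @param n_visits visit counts to evaluate (default 2, 4, ..., 16).
#' @param fold_models optional `models` element of an [overall_cv()] report
#'   run with the same `seed` and `k` (avoids retraining).
#' @return an `evaluation_report` whose `per_horizon[[h]]$by_visits` table
#'   has one row per visit count (`NA` AUC for empty strata).
#' @export
visit_variant <- function(cohort, horizons = c(3L, 6L, 9L, 12L),
                          n_visits = seq(2L, 16L, by = 2L),
                          config = model_config(), k = 10L, seed = 1L,
                          fold_models = NULL, verbose = FALSE) {
  sequences <- build_labeled_sequences(cohort, horizons)
  fold_plan <- make_folds(cohort, k, derive_seed(seed, 7L))
  pats <- vapply(sequences, function(s) s$patient_id, "")
  per_h <- list(); audits <- list()
  for (h in horizons) {
    hcol <- paste0("h", h)
    models <- fold_models[[paste0("h", h)]] %||%
      train_fold_models(sequences, fold_plan, h, config, seed, verbose)
    rows <- list()
    for (i in seq_len(fold_plan$k)) {
      hold <- fold_plan$folds[[i]]
      for (s in sequences[pats %in% hold]) {
        stopifnot(!(s$patient_id %in% models[[i]]$train_patients))
        vmax <- min(nrow(s$visits), max(n_visits))
        if (vmax < min(n_visits)) next
        risks <- predict_sequence(models[[i]],
                                  s$visits[seq_len(vmax), , drop = FALSE])
        for (v in n_visits[n_visits <= vmax]) {
          lab <- s$labels[v, hcol]
          if (lab == 2L) next
          rows[[length(rows) + 1L]] <- data.frame(
            eye_id = s$eye_id, patient_id = s$patient_id, fold = i,
            n_visits = v, score = risks[v], label = lab,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    scored <- do.call(rbind, rows)
    by_v <- data.frame(
      n_visits = n_visits,
      auc = vapply(n_visits, function(v) {
        sel <- scored$n_visits == v
        if (!any(sel)) NA_real_ else roc_auc(scored$score[sel],
                                             scored$label[sel])
      }, 0),
      n = vapply(n_visits, function(v) sum(scored$n_visits == v), 0L)
    )
    per_h[[hcol]] <- list(by_visits = by_v, scored = scored)
    audits[[hcol]] <- data.frame(horizon = h, patient_id = scored$patient_id,
                                 fold = scored$fold, stringsAsFactors = FALSE)
  }
  rep <- structure(
    list(setting = "visit_variant", per_horizon = per_h, folds = fold_plan,
         audit = do.call(rbind, audits), horizons = horizons),
    class = "evaluation_report"
  )
  assert_no_leakage(rep)
  rep
}

#' Train one full-data model per horizon
#'
#' Used before external-cohort testing: a single model per horizon trained on
#' the complete internal cohort (early stopping still uses its internal 20%
#' validation split).
#'
#' @inheritParams overall_cv
#' @return named list of `deep_sequence_model` (names `"h3"`, ...).
#' @export
train_full <- function(cohort, horizons = default_horizons(),
                       config = model_config(), seed = 1L) {
  sequences <- build_labeled_sequences(cohort, horizons)
  out <- list()
  for (h in horizons) {
    cfg <- config
    cfg$horizon_k <- as.integer(h)
    cfg$seed <- derive_seed(seed, 500L + h)
    out[[paste0("h", h)]] <- train_deep_sequence(sequences, cfg)
  }
  out
}

#' External-cohort test
#'
#' Scores an independent cohort with models trained elsewhere: no refitting,
#' the training cohort's encoder schema and scaler are reused, and
#' demographics absent from the external table encode to the missing level.
#'
#' @param models named list from [train_full()].
#' @param cohort_b the external `cohort` (or visit table/histories compatible
#'   with [build_labeled_sequences()]).
#' @return an `evaluation_report` with per-horizon pooled AUC and PR curves.
#' @export
external_test <- function(models, cohort_b) {
  horizons <- as.integer(sub("^h", "", names(models)))
  sequences <- build_labeled_sequences(cohort_b, horizons)
  per_h <- list()
  for (h in horizons) {
    hcol <- paste0("h", h)
    model <- models[[hcol]]
    rows <- list()
    for (s in sequences) {
      risks <- predict_sequence(model, s$visits)
      n <- nrow(s$visits)
      kept <- (n - length(risks) + 1L):n
      lab <- s$labels[kept, hcol]
      ok <- lab != 2L
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        eye_id = s$eye_id, patient_id = s$patient_id,
        score = risks[ok], label = lab[ok], stringsAsFactors = FALSE
      )
    }
    scored <- do.call(rbind, rows)
    per_h[[hcol]] <- list(
      pooled_auc = roc_auc(scored$score, scored$label),
      pr = pr_curve(scored$score, scored$label), scored = scored
    )
  }
  structure(
    list(setting = "external_test", per_horizon = per_h, horizons = horizons),
    class = "evaluation_report"
  )
}

#' Patient-level fixed-visit performance
#'
#' One prediction per eye from its first `n_first` visits (eyes with fewer
#' use all they have), under patient-level cross-validation. The operating
#' threshold is chosen per fold by Youden's J on the training-fold
#' predictions; sensitivity and specificity are pooled over the held-out
#' predictions.
#'
#' @inheritParams overall_cv
#' @param n_first number of initial visits used (default 5).
#' @return an `evaluation_report`; `$table` has one row per horizon with
#'   `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
patient_level <- function(cohort, horizons = default_horizons(),
                          config = model_config(), n_first = 5L, k = 10L,
                          seed = 1L, fold_models = NULL, verbose = FALSE) {
  sequences <- build_labeled_sequences(cohort, horizons)
  fold_plan <- make_folds(cohort, k, derive_seed(seed, 7L))
  pats <- vapply(sequences, function(s) s$patient_id, "")
  eye_pred <- function(model, s, hcol) {
    v <- min(n_first, nrow(s$visits))
    lab <- s$labels[v, hcol]
    if (lab == 2L) return(NULL)
    list(score = predict_risk(model, s$visits[seq_len(v), , drop = FALSE]),
         label = lab)
  }
  tab <- list(); per_h <- list(); audits <- list()
  for (h in horizons) {
    hcol <- paste0("h", h)
    models <- fold_models[[hcol]] %||%
      train_fold_models(sequences, fold_plan, h, config, seed, verbose)
    rows <- list()
    for (i in seq_len(fold_plan$k)) {
      hold <- fold_plan$folds[[i]]
      train_scores <- list()
      for (s in sequences[!(pats %in% hold)]) {
        p <- eye_pred(models[[i]], s, hcol)
        if (!is.null(p)) train_scores[[length(train_scores) + 1L]] <- p
      }
      ts <- vapply(train_scores, `[[`, 0, "score")
      tl <- vapply(train_scores, `[[`, 0L, "label")
      thr <- youden_threshold(ts, tl)
      for (s in sequences[pats %in% hold]) {
        stopifnot(!(s$patient_id %in% models[[i]]$train_patients))
        p <- eye_pred(models[[i]], s, hcol)
        if (is.null(p)) next
        rows[[length(rows) + 1L]] <- data.frame(
          eye_id = s$eye_id, patient_id = s$patient_id, fold = i,
          score = p$score, label = p$label, threshold = thr,
          stringsAsFactors = FALSE
        )
      }
    }
    scored <- do.call(rbind, rows)
    pred_pos <- scored$score >= scored$threshold
    tab[[hcol]] <- data.frame(
      horizon = h,
      sensitivity = mean(pred_pos[scored$label == 1L]),
      specificity = mean(!pred_pos[scored$label == 0L]),
      n_pos = sum(scored$label == 1L), n_neg = sum(scored$label == 0L)
    )
    per_h[[hcol]] <- list(scored = scored)
    audits[[hcol]] <- data.frame(horizon = h, patient_id = scored$patient_id,
                                 fold = scored$fold, stringsAsFactors = FALSE)
  }
  rep <- structure(
    list(setting = "patient_level", per_horizon = per_h,
         table = do.call(rbind, tab), folds = fold_plan,
         audit = do.call(rbind, audits), horizons = horizons),
    class = "evaluation_report"
  )
  assert_no_leakage(rep)
  rep
}

#' Assert patient-level train/test separation
#'
#' Programmatic no-leakage audit: every scored observation's patient must lie
#' in its scoring fold's held-out set and outside every training set used for
#' that fold. Errors on violation; invisibly TRUE otherwise. Run
#' automatically by the cross-validated evaluation settings.
#'
#' @param report an `evaluation_report` carrying `audit` and `folds`.
#' @export
assert_no_leakage <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  if (is.null(report$audit) || is.null(report$folds)) return(invisible(TRUE))
  folds <- report$folds$folds
  for (i in seq_along(folds)) {
    rows <- report$audit[report$audit$fold == i, , drop = FALSE]
    if (!nrow(rows)) next
    train_pats <- unlist(folds[-i])
    if (!all(rows$patient_id %in% folds[[i]])) {
      stop_drusenseq("leakage: scored patient not in its held-out fold",
                     "drusenseq_leakage")
    }
    if (any(rows$patient_id %in% train_pats)) {
      stop_drusenseq("leakage: scored patient appears in a training fold",
                     "drusenseq_leakage")
    }
  }
  invisible(TRUE)
}

#' Cross-validated last-visit logistic baseline
#'
#' A no-history reference model: per fold, a plain logistic regression on the
#' encoded features of each single observation, trained on the training
#' folds' non-censored observations and scored on the held-out ones. Used to
#' show the sequence model's gain from visit history.
#'
#' @inheritParams overall_cv
#' @param horizon single horizon in months.
#' @param fold_plan optional pre-built [make_folds()] plan (use the same plan
#'   as the sequence model for a paired comparison).
#' @return list with `pooled_auc`, `fold_auc`, and the scored table.
#' @export
baseline_last_visit_cv <- function(cohort, horizon = 3L, k = 10L, seed = 1L,
                                   fold_plan = NULL) {
  sequences <- build_labeled_sequences(cohort, horizon)
  fold_plan <- fold_plan %||% make_folds(cohort, k, derive_seed(seed, 7L))
  hcol <- paste0("h", horizon)
  pats <- vapply(sequences, function(s) s$patient_id, "")
  rows <- list()
  for (i in seq_len(fold_plan$k)) {
    hold <- fold_plan$folds[[i]]
    tr <- sequences[!(pats %in% hold)]
    te <- sequences[pats %in% hold]
    schema <- fit_encoder(do.call(rbind, lapply(tr, `[[`, "visits")))
    stack <- function(ss) {
      X <- do.call(rbind, lapply(ss, function(s) encode_visits(schema, s$visits)))
      y <- unlist(lapply(ss, function(s) s$labels[, hcol]))
      pid <- unlist(lapply(ss, function(s) rep(s$patient_id, nrow(s$visits))))
      keep <- y != 2L
      list(X = cbind(1, X[keep, , drop = FALSE]), y = y[keep],
           pid = pid[keep])
    }
    trd <- stack(tr); ted <- stack(te)
    fit <- suppressWarnings(
      stats::glm.fit(trd$X, trd$y, family = stats::binomial())
    )
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    sc <- as.vector(1 / (1 + exp(-(ted$X %*% beta))))
    rows[[i]] <- data.frame(patient_id = ted$pid, fold = i, score = sc,
                            label = ted$y, stringsAsFactors = FALSE)
  }
  scored <- do.call(rbind, rows)
  c(fold_auc_summary(scored), list(scored = scored))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> setting: %s\n", x$setting))
  for (h in names(x$per_horizon)) {
    ph <- x$per_horizon[[h]]
    if (!is.null(ph$auc_mean)) {
      cat(sprintf("  %s: AUC %.3f +/- %.3f (pooled %.3f)\n", h, ph$auc_mean,
                  ph$auc_sd, ph$pooled_auc))
    } else if (!is.null(ph$pooled_auc)) {
      cat(sprintf("  %s: AUC %.3f (pooled)\n", h, ph$pooled_auc))
    } else if (!is.null(ph$by_visits)) {
      cat(sprintf("  %s: AUC by visits %s\n", h,
                  paste(sprintf("%d:%.2f", ph$by_visits$n_visits,
                                ph$by_visits$auc), collapse = " ")))
    }
  }
  if (!is.null(x$table)) {
    print(x$table, row.names = FALSE)
  }
  invisible(x)
}
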