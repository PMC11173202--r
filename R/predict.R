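#' Per-user predictor table for one training window
#'
#' Runs the full estimation chain on a single window's cascade log —
#' diffusion network, contagion rates, IS scores (gauge-normalized),
#' centralities — and assembles one row per user in the window's network
#' with the predictors:
#'
#' * `influence`, `susceptibility` — the reconstructed IS scores;
#' * `total_susceptibility` (`TS_i = sum_j A_ij * S_j`), `total_influence`
#'   (`TI_i = sum_j A_ij * I_j`) — sums over the users i influenced;
#' * `is_total` (`TIS_i = sum_j A_ij * I_i * S_j = I_i * TS_i`) — the node's
#'   total expected high-contagion outflow;
#' * `out_contagion` (`f_hat`), `in_contagion` (`g_hat`);
#' * `k_in`, `k_out`, `pagerank`, `kcore`;
#' * `past_success` — mean size (events, root included) of the cascades the
#'   user initiated in this window; 0 when the user initiated none.
#'
#' @param window_log A non-empty event-log data frame for one window.
#' @param is_opts List of arguments passed on to [run_is()].
#' @return A `feature_table` tibble with attribute `converged` recording the
#'   IS convergence flag (a warning is raised, and features still emitted,
#'   on non-convergence).
#' @export
compute_features <- function(window_log, is_opts = list()) {
  events <- validate_event_log(window_log)
  if (nrow(events) == 0) {
    abort("Window log is empty.")
  }
  net <- build_diffusion_network(events)
  rates <- estimate_contagion_rates(events, net)
  scores <- do.call(run_is, c(list(rates = rates, quiet = TRUE), is_opts))
  if (!scores$meta$converged) {
    warn("IS estimation did not converge on this window; features emitted anyway.")
  }
  scores <- gauge_normalize(scores)
  sc <- tidy(scores)
  cents <- centralities(net)

  edges <- tibble::as_tibble(net)[c("from", "to")]
  s_of <- stats::setNames(sc$susceptibility, as.character(sc$user_id))
  i_of <- stats::setNames(sc$influence, as.character(sc$user_id))
  sums <- edges |>
    mutate(s_to = s_of[as.character(.data$to)],
           i_to = i_of[as.character(.data$to)]) |>
    group_by(.data$from) |>
    summarise(total_susceptibility = sum(.data$s_to),
              total_influence = sum(.data$i_to), .groups = "drop")

  past <- cascade_summary(events) |>
    group_by(user_id = .data$root_user) |>
    summarise(past_success = mean(.data$size), .groups = "drop")

  tbl <- sc |>
    left_join(sums, by = c("user_id" = "from")) |>
    left_join(tidy(rates)[c("user_id", "f_hat", "g_hat")], by = "user_id") |>
    left_join(cents, by = "user_id") |>
    left_join(past, by = "user_id") |>
    mutate(
      total_susceptibility = tidyr::replace_na(.data$total_susceptibility, 0),
      total_influence = tidyr::replace_na(.data$total_influence, 0),
      is_total = .data$influence * .data$total_susceptibility,
      past_success = tidyr::replace_na(.data$past_success, 0)
    ) |>
    rename(out_contagion = "f_hat", in_contagion = "g_hat") |>
    select("user_id", "influence", "susceptibility", "total_susceptibility",
           "total_influence", "is_total", "out_contagion", "in_contagion",
           "k_in", "k_out", "pagerank", "kcore", "past_success")
  attr(tbl, "converged") <- scores$meta$converged
  tbl
}

# Feature sets of the predictive model families.
feature_sets <- list(
  behavior_is = c("influence", "susceptibility", "total_susceptibility",
                  "total_influence", "is_total"),
  behavior_cr = c("out_contagion", "in_contagion"),
  structure = c("k_in", "k_out", "pagerank", "kcore"),
  combined = c("influence", "susceptibility", "total_susceptibility",
               "total_influence", "is_total", "out_contagion", "in_contagion",
               "k_in", "k_out", "pagerank", "kcore", "past_success"),
  random = character(0)
)

#' Label the superspreaders of the following window
#'
#' Scores every candidate by the mean size (events, root included) of the
#' cascades it initiated in the next window (0 when it initiated none) and
#' labels the top `ceiling(z% * n_candidates)` candidates positive. Ties at
#' the boundary are broken deterministically by (score descending, user id
#' ascending); if every candidate scored 0, a degenerate-label warning is
#' raised (the labels are then the lowest-id candidates).
#'
#' @param next_window_log Event log of window `t + 1` (may be empty, with a
#'   warning).
#' @param candidates User ids of the training-window cohort.
#' @param z Selectivity threshold in percent (default 5; 0 < z < 100).
#' @return A tibble `user_id`, `score`, `label` (0/1 integer).
#' @export
label_superspreaders <- function(next_window_log, candidates, z = 5) {
  if (length(candidates) == 0) {
    abort("`candidates` must be non-empty.")
  }
  if (z <= 0 || z >= 100) {
    abort("`z` must lie strictly between 0 and 100.")
  }
  events <- validate_event_log(next_window_log)
  if (nrow(events) == 0) {
    warn("Next window is empty: all candidate scores are 0.")
    score <- stats::setNames(rep(0, length(candidates)),
                             as.character(candidates))
  } else {
    cs <- cascade_summary(events) |>
      group_by(.data$root_user) |>
      summarise(mean_size = mean(.data$size), .groups = "drop")
    score <- stats::setNames(
      cs$mean_size[match(as.character(candidates),
                         as.character(cs$root_user))],
      as.character(candidates))
    score[is.na(score)] <- 0
  }
  n_pos <- ceiling(z / 100 * length(candidates))
  positives <- top_m_by(candidates, as.numeric(score), n_pos)
  if (all(score == 0) && nrow(events) > 0) {
    warn("Degenerate labels: no candidate initiated a cascade in the next window.")
  }
  tibble::tibble(
    user_id = candidates,
    score = as.numeric(score),
    label = as.integer(candidates %in% positives)
  )
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision of a ranking: items are sorted by score descending
#' (ties broken stably by input order), and the precision at the rank of
#' every positive is averaged. For a random ranking this concentrates at the
#' positive-class rate; a perfect ranking scores 1.
#'
#' @param scores Numeric ranking scores (higher = more likely positive).
#' @param labels 0/1 (or logical) true labels.
#' @return A scalar in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal length.")
  }
  if (sum(labels) == 0) {
    abort("No positive labels.")
  }
  ord <- order(-scores, seq_along(scores))
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec * y) / sum(y)
}

#' Precision among the top-k ranked items
#'
#' With `k` equal to the number of true positives (the default), this equals
#' recall at the same operating point and is the natural precision figure
#' for "identifying the superspreaders".
#'
#' @inheritParams pr_auc
#' @param k Number of top-ranked items to consider.
#' @return A scalar in `[0, 1]`.
#' @export
precision_at_k <- function(scores, labels, k = sum(as.logical(labels))) {
  labels <- as.integer(as.logical(labels))
  ord <- order(-scores, seq_along(scores))
  mean(labels[ord][seq_len(min(k, length(labels)))])
}

#' Fit and evaluate one superspreader prediction model
#'
#' Joins a window's feature table with the next window's labels, fits a
#' random forest (500 trees, class weights inversely proportional to class
#' frequency, impurity importances) on the chosen feature set, and evaluates
#' on a held-out stratified fraction of the cohort with AUPRC and
#' precision-at-k (k = number of held-out positives). The
#' `"random"` feature set is the baseline: a seeded uniform ranking of the
#' held-out users.
#'
#' @param features A `feature_table` from [compute_features()].
#' @param labels A label tibble from [label_superspreaders()].
#' @param feature_set One of `"behavior_is"`, `"behavior_cr"`,
#'   `"structure"`, `"combined"`, `"random"`.
#' @param drop_features Optional feature names to exclude from the set.
#' @param n_trees Number of trees.
#' @param holdout Held-out fraction (stratified by class).
#' @param in_sample If `TRUE`, train and evaluate on the full cohort
#'   instead of holding out.
#' @param seed Optional seed controlling split, forest and baseline; the
#'   same seed reproduces the identical report, and the identical split
#'   across feature sets.
#' @return An `eval_report` object; `glance()` gives the metrics row,
#'   `tidy()` the feature importances (non-random models).
#' @export
train_eval <- function(features, labels,
                       feature_set = c("behavior_is", "behavior_cr",
                                       "structure", "combined", "random"),
                       drop_features = NULL, n_trees = 500L, holdout = 0.3,
                       in_sample = FALSE, seed = NULL) {
  feature_set <- match.arg(feature_set)
  dat <- inner_join(features, labels[c("user_id", "label")], by = "user_id") |>
    arrange(.data$user_id)
  y <- dat$label
  if (length(unique(y)) < 2) {
    abort("Labels are single-class; cannot fit or evaluate.")
  }
  cols <- setdiff(feature_sets[[feature_set]], drop_features)

  with_seed_if(seed, {
    if (in_sample) {
      train_idx <- seq_len(nrow(dat))
      test_idx <- train_idx
    } else {
      test_idx <- sort(unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, floor(holdout * length(idx))))
      })))
      train_idx <- setdiff(seq_len(nrow(dat)), test_idx)
    }
    y_test <- y[test_idx]
    if (sum(y_test) == 0 || sum(y[train_idx]) == 0) {
      abort("Split left a side without positives; enlarge the cohort.")
    }

    importance <- NULL
    if (feature_set == "random") {
      pred <- runif(length(test_idx))
    } else {
      x <- as.data.frame(dat[cols])
      y_fac <- factor(y, levels = c(0, 1))
      cw <- 1 / table(y[train_idx])
      cw <- cw / sum(cw)
      fit <- randomForest::randomForest(
        x = x[train_idx, , drop = FALSE], y = y_fac[train_idx],
        ntree = n_trees, classwt = as.numeric(cw), importance = FALSE
      )
      pred <- stats::predict(fit, x[test_idx, , drop = FALSE],
                             type = "prob")[, "1"]
      imp <- randomForest::importance(fit, type = 2)
      importance <- tibble::tibble(
        feature = rownames(imp),
        importance = as.numeric(imp[, 1]) / sum(imp[, 1])
      ) |> arrange(desc(.data$importance))
    }
    metrics <- tibble::tibble(
      model = feature_set,
      auprc = pr_auc(pred, y_test),
      precision_at_k = precision_at_k(pred, y_test),
      n_train = length(train_idx),
      n_test = length(test_idx),
      n_pos_test = sum(y_test)
    )
  })
  structure(list(metrics = metrics, importance = importance,
                 feature_set = feature_set),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("# Superspreader prediction (%s model)\n", x$feature_set))
  print(x$metrics, ...)
  if (!is.null(x$importance)) {
    cat("# Feature importances:\n")
    print(x$importance, ...)
  }
  invisible(x)
}

#' @rdname tidy-spreadis
#' @export
tidy.eval_report <- function(x, ...) {
  x$importance %||%
    tibble::tibble(feature = character(), importance = numeric())
}

#' @rdname tidy-spreadis
#' @export
glance.eval_report <- function(x, ...) {
  x$metrics
}

#' Rolling windowed prediction experiment
#'
#' For every consecutive window pair, builds the feature table from the
#' training window, labels from the following window (cohort = users in the
#' training window's network), and evaluates every requested model on the
#' identical stratified split (the split is a function of the seed and the
#' cohort, not of the feature set).
#'
#' @param logs A list of at least two window event logs (e.g. from
#'   [split_by_window()] or [simulate_windows()]).
#' @param z Superspreader selectivity threshold in percent.
#' @param models Feature sets to evaluate.
#' @param seeds Integer seeds; each seed yields one split/fit/baseline
#'   replicate per window pair and model.
#' @param is_opts Passed to [compute_features()].
#' @param ... Passed to [train_eval()].
#' @return A tibble `window`, `model`, `seed`, `auprc`, `precision_at_k`,
#'   `n_test`, `n_pos_test` with one row per (window pair, model, seed).
#' @export
rolling_experiment <- function(logs, z = 5,
                               models = c("behavior_is", "behavior_cr",
                                          "structure", "combined", "random"),
                               seeds = 1L, is_opts = list(), ...) {
  if (length(logs) < 2) {
    abort("Need at least 2 windows.")
  }
  purrr::map_dfr(seq_len(length(logs) - 1L), function(t) {
    feats <- compute_features(logs[[t]], is_opts = is_opts)
    labs <- label_superspreaders(logs[[t + 1]], feats$user_id, z = z)
    purrr::map_dfr(seeds, function(s) {
      purrr::map_dfr(models, function(mod) {
        rep <- train_eval(feats, labs, feature_set = mod, seed = s, ...)
        glance(rep) |>
          mutate(window = t, seed = s, .before = 1) |>
          select("window", "model", "seed", "auprc", "precision_at_k",
                 "n_test", "n_pos_test")
      })
    })
  })
}
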