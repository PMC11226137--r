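#' Multi-label ensemble of one-vs-all sub-classifiers
#'
#' The ensemble holds one trained binary CNN per Gleason grade plus a score
#' threshold per grade. A patch's multi-label hypothesis is the set of
#' grades whose sub-classifier score exceeds its threshold; the NC label is
#' the empty set. [train_ensemble()] trains the three sub-classifiers and
#' selects thresholds on the validation folds.
#'
#' @param sub_models Named list (`G3`, `G4`, `G5`) of `gleason_cnn` models
#'   or `gleason_cnn_fit` objects.
#' @param thresholds Named per-grade thresholds in `[0, 1]` (default 0.5
#'   until selected).
#' @return A `gleason_ensemble`.
#' @export
gleason_ensemble <- function(sub_models, thresholds = c(G3 = 0.5, G4 = 0.5, G5 = 0.5)) {
  if (!setequal(names(sub_models), gleason_grades())) {
    abort("sub_models must be named G3, G4, G5")
  }
  sub_models <- purrr::map(sub_models, function(m) {
    if (inherits(m, "gleason_cnn_fit")) m$model else m # functions allowed as stubs
  })
  if (any(thresholds < 0 | thresholds > 1)) abort("thresholds must lie in [0, 1]")
  structure(
    list(sub_models = sub_models[gleason_grades()], thresholds = thresholds[gleason_grades()]),
    class = "gleason_ensemble"
  )
}

#' @export
print.gleason_ensemble <- function(x, ...) {
  cat("<gleason_ensemble> one-vs-all CNNs for G3/G4/G5; thresholds:",
      paste(sprintf("%s=%.3f", names(x$thresholds), x$thresholds), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname gleason_ensemble
#' @param manifest Manifest tibble.
#' @param policy A [label_policy()].
#' @param config A [train_config()].
#' @param train_folds,val_folds Folds used for fitting and for
#'   threshold selection / early stopping.
#' @return `train_ensemble()`: a `gleason_ensemble` with selected
#'   thresholds; the per-grade fits are kept in attribute `fits`.
#' @export
train_ensemble <- function(manifest, policy = label_policy(), config = train_config(),
                           train_folds = c("Val1", "Val2", "Val3"), val_folds = "Val4") {
  fits <- purrr::map(setNames(gleason_grades(), gleason_grades()), function(g) {
    cfg <- config
    cfg$seed <- config$seed + grade_code(g) # distinct but derived seeds
    train_sub_classifier(manifest, g, policy, cfg, train_folds, val_folds)
  })
  ens <- gleason_ensemble(fits)
  ens <- select_thresholds(ens, manifest %>% dplyr::filter(.data$fold %in% val_folds), policy,
                           input_size = config$input_size)
  attr(ens, "fits") <- fits
  ens
}

#' Per-grade detection scores for patches
#'
#' Runs each sub-classifier on the (resized) patch images and returns the
#' softmax probability of its positive class. Scores are independent across
#' grades and need not sum to one.
#'
#' @param ensemble A [gleason_ensemble()].
#' @param patches Patch image paths, a manifest tibble (its `patch_path`
#'   column is used), or an `H x W x 3 x N` array.
#' @param input_size Network input side; defaults to the patch size given.
#' @return Tibble with columns `score_g3`, `score_g4`, `score_g5` (plus
#'   `patch_path` when paths were given).
#' @export
predict_scores <- function(ensemble, patches, input_size = NULL) {
  paths <- NULL
  if (is.data.frame(patches)) {
    paths <- patches$patch_path
  } else if (is.character(patches)) {
    paths <- patches
  }
  if (!is.null(paths)) {
    if (is.null(input_size)) abort("input_size is required when loading patches from paths")
    x <- load_patch_array(paths, input_size)
  } else {
    x <- patches
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    if (length(dim(x)) != 4L || dim(x)[3] != 3L) abort("malformed image array")
    if (!is.null(input_size) && dim(x)[1] != input_size) {
      x <- resize_batch(x, input_size)
    }
  }
  out <- tibble::tibble(
    score_g3 = model_scores(ensemble$sub_models$G3, x),
    score_g4 = model_scores(ensemble$sub_models$G4, x),
    score_g5 = model_scores(ensemble$sub_models$G5, x)
  )
  if (!is.null(paths)) out <- dplyr::bind_cols(tibble::tibble(patch_path = paths), out)
  out
}

resize_batch <- function(x, size) {
  n <- dim(x)[4]
  out <- array(0, c(size, size, 3L, n))
  for (i in seq_len(n)) {
    out[, , , i] <- cpp_bilinear_resize(x[, , , i, drop = TRUE], as.integer(size), as.integer(size))
  }
  out
}

#' Multi-label decision from scores
#'
#' A grade is asserted when its score strictly exceeds its threshold (ties
#' are negative); the NC flag is true exactly when no grade is asserted.
#' Raising any threshold can only remove grades (monotone decision rule).
#'
#' @param scores Tibble with `score_g3`, `score_g4`, `score_g5` (as from
#'   [predict_scores()]), or a named numeric vector for a single patch.
#' @param thresholds Named per-grade thresholds covering G3, G4, G5.
#' @return Tibble with logical columns `g3`, `g4`, `g5`, `nc`.
#' @export
predict_multilabel <- function(scores, thresholds) {
  if (!all(gleason_grades() %in% names(thresholds))) {
    abort("thresholds must be set for all of G3, G4, G5")
  }
  if (is.numeric(scores)) {
    scores <- tibble::tibble(
      score_g3 = scores[["G3"]], score_g4 = scores[["G4"]], score_g5 = scores[["G5"]]
    )
  }
  out <- tibble::tibble(
    g3 = scores$score_g3 > thresholds[["G3"]],
    g4 = scores$score_g4 > thresholds[["G4"]],
    g5 = scores$score_g5 > thresholds[["G5"]]
  )
  out$nc <- !(out$g3 | out$g4 | out$g5)
  out
}

#' Precision-recall curve with F1-optimal threshold
#'
#' Sweeps the decision threshold over every unique score plus sentinels
#' below the minimum and above the maximum (so the curve spans recall 1
#' down to 0); at each threshold a patch is predicted positive when
#' `score > threshold`. Precision is `TP/(TP+FP)` (0 when no positives are
#' predicted), recall `TP/(TP+FN)`, `F1 = 2PR/(P+R)` (0 when `P+R = 0`).
#' `best_threshold` is the threshold with maximal F1, the lowest such
#' threshold on ties.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical or 0/1); both classes must be present.
#' @return A `pr_curve`: tibble (`threshold`, `precision`, `recall`, `f1`)
#'   with attributes `best_threshold`, `best_f1`.
#' @examples
#' pr <- pr_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' attr(pr, "best_f1") # 1
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (all(labels) || !any(labels)) abort("labels must contain both classes")
  u <- sort(unique(scores))
  eps <- max(diff(range(u)), 1) * 1e-6
  thresholds <- c(u[1] - eps, u, u[length(u)] + eps)
  npos <- sum(labels)
  rows <- purrr::map_dfr(thresholds, function(t) {
    pred <- scores > t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- tp / npos
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble::tibble(threshold = t, precision = prec, recall = rec, f1 = f1)
  })
  best <- which.max(rows$f1) # which.max takes the first (lowest threshold) tie
  structure(
    rows, class = c("pr_curve", class(rows)),
    best_threshold = rows$threshold[best], best_f1 = rows$f1[best]
  )
}

#' @rdname pr_curve
#' @param object A `pr_curve`.
#' @param ... Unused.
#' @export
autoplot.pr_curve <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_point(
      data = d[which.max(d$f1), ],
      colour = "firebrick", size = 2
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("PR curve (best F1 = %.3f)", attr(object, "best_f1")),
      x = "recall", y = "precision"
    ) +
    ggplot2::theme_minimal()
}

#' Select per-grade thresholds from validation PR curves
#'
#' Scores the validation patches with each sub-classifier, builds the PR
#' curve against the reference multilabels, and stores each curve's
#' F1-optimal threshold in the ensemble.
#'
#' @param ensemble A [gleason_ensemble()].
#' @param manifest Validation manifest (relabelled on the fly if needed).
#' @param policy A [label_policy()].
#' @param input_size Network input side used for scoring.
#' @return The ensemble with updated `thresholds`; the per-grade curves are
#'   kept in attribute `pr_curves`.
#' @export
select_thresholds <- function(ensemble, manifest, policy = label_policy(),
                              input_size = 224L) {
  ref <- ensure_relabelled(manifest, policy) %>%
    dplyr::filter(.data$excluded == 0L)
  if (!nrow(ref)) abort("no eligible validation patches")
  scores <- predict_scores(ensemble, ref, input_size = input_size)
  curves <- list()
  for (g in gleason_grades()) {
    lab <- ref[[tolower(g)]] == 1L
    if (all(lab) || !any(lab)) {
      abort(paste0("validation set lacks positives or negatives for ", g))
    }
    curves[[g]] <- pr_curve(scores[[paste0("score_", tolower(g))]], lab)
    ensemble$thresholds[[g]] <- attr(curves[[g]], "best_threshold")
  }
  attr(ensemble, "pr_curves") <- curves
  ensemble
}

ensure_relabelled <- function(manifest, policy) {
  if (all(c("g3", "g4", "g5", "nc", "excluded") %in% names(manifest))) {
    manifest
  } else {
    relabel_manifest(manifest, policy)
  }
}

#' Evaluate the ensemble against reference multilabels
#'
#' Computes, over the eligible (non-excluded) patches: per-class F1 for NC,
#' G3, G4 and G5 treated as four binary presence/absence problems; their
#' macro average; macro-averaged per-problem binary accuracy; and subset
#' (exact-match) accuracy. Reference labels come from the masks under
#' `tau_test` (defaults to the policy's training `tau`). Excluded patches
#' are omitted and counted.
#'
#' @param ensemble A [gleason_ensemble()] with thresholds selected.
#' @param manifest Manifest of the evaluation fold(s).
#' @param policy A [label_policy()].
#' @param tau_test Optional evaluation-time pixel threshold.
#' @param input_size Network input side used for scoring.
#' @return A `gleason_eval`: list with `per_class` tibble, `macro_f1`,
#'   `accuracy`, `subset_accuracy`, `n`, `n_excluded`, and the prediction
#'   table.
#' @export
evaluate_ensemble <- function(ensemble, manifest, policy = label_policy(),
                              tau_test = NULL, input_size = 224L) {
  pol <- policy
  if (!is.null(tau_test)) pol$tau <- tau_test
  ref <- relabel_manifest(manifest, pol)
  n_excluded <- sum(ref$excluded == 1L)
  ref <- ref %>% dplyr::filter(.data$excluded == 0L)
  if (!nrow(ref)) abort("no eligible patches to evaluate")
  scores <- predict_scores(ensemble, ref, input_size = input_size)
  pred <- predict_multilabel(scores, ensemble$thresholds)
  res <- evaluate_multilabels(pred, ref[, c("g3", "g4", "g5", "nc")])
  res$n_excluded <- n_excluded
  res$predictions <- dplyr::bind_cols(
    ref[, c("patch_path", "fold", "g3", "g4", "g5", "nc")],
    scores[, c("score_g3", "score_g4", "score_g5")],
    dplyr::rename_with(pred, ~ paste0("pred_", .x))
  )
  res
}

#' @rdname evaluate_ensemble
#' @param pred,ref Data frames with logical/0-1 columns `g3`, `g4`, `g5`,
#'   `nc` — predicted and reference multilabels. Exposed separately so
#'   metric arithmetic can be checked on hand-worked tables.
#' @export
evaluate_multilabels <- function(pred, ref) {
  stopifnot(nrow(pred) == nrow(ref))
  cls <- c("nc", "g3", "g4", "g5")
  per_class <- purrr::map_dfr(cls, function(cl) {
    p <- as.logical(pred[[cl]]); r <- as.logical(ref[[cl]])
    tibble::tibble(
      class = toupper(cl), f1 = binary_f1(p, r), accuracy = mean(p == r),
      tp = sum(p & r), fp = sum(p & !r), fn = sum(!p & r), tn = sum(!p & !r)
    )
  })
  exact <- rowSums(sapply(cls, function(cl) as.logical(pred[[cl]]) == as.logical(ref[[cl]]))) == length(cls)
  structure(
    list(
      per_class = per_class,
      macro_f1 = mean(per_class$f1),
      accuracy = mean(per_class$accuracy),
      subset_accuracy = mean(exact),
      n = nrow(pred)
    ),
    class = "gleason_eval"
  )
}

#' @export
print.gleason_eval <- function(x, ...) {
  cat("<gleason_eval> n =", x$n)
  if (!is.null(x$n_excluded)) cat(" (", x$n_excluded, "excluded)")
  cat("\n  accuracy:", round(x$accuracy, 3),
      " macro F1:", round(x$macro_f1, 3),
      " subset accuracy:", round(x$subset_accuracy, 3), "\n")
  pc <- x$per_class
  cat("  per-class F1:", paste(sprintf("%s=%.3f", pc$class, pc$f1), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname evaluate_ensemble
#' @param x A `gleason_eval`.
#' @param ... Unused.
#' @export
tidy.gleason_eval <- function(x, ...) x$per_class

#' @rdname evaluate_ensemble
#' @param object A `gleason_eval`.
#' @export
glance.gleason_eval <- function(object, ...) {
  tibble::tibble(
    accuracy = object$accuracy, macro_f1 = object$macro_f1,
    subset_accuracy = object$subset_accuracy, n = object$n,
    n_excluded = object$n_excluded %||% 0L
  )
}

#' Save or load an ensemble checkpoint
#'
#' The checkpoint is an RDS archive with a versioned layout: `version`,
#' `ensemble` (weights, BN state, thresholds), and optional `fits`
#' (histories and configs).
#'
#' @param ensemble A [gleason_ensemble()].
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(ensemble, path) {
  saveRDS(list(version = 1L, ensemble = ensemble, fits = attr(ensemble, "fits")), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != 1L) abort("unsupported checkpoint version")
  ens <- ck$ensemble
  attr(ens, "fits") <- ck$fits
  ens
}
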