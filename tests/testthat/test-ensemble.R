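test_that("multi-label decisions follow strict score > threshold with derived NC", {
  thr <- c(G3 = 0.5, G4 = 0.5, G5 = 0.5)
  one <- predict_multilabel(c(G3 = 0.9, G4 = 0.2, G5 = 0.1), thr)
  expect_true(one$g3); expect_false(one$g4); expect_false(one$nc)
  none <- predict_multilabel(c(G3 = 0.4, G4 = 0.1, G5 = 0.5), thr) # tie is negative
  expect_false(any(none$g3, none$g4, none$g5))
  expect_true(none$nc)
  all3 <- predict_multilabel(c(G3 = 0.6, G4 = 0.7, G5 = 0.55), thr)
  expect_true(all(all3$g3, all3$g4, all3$g5))
  expect_error(predict_multilabel(c(G3 = 0.6, G4 = 0.7, G5 = 0.55), c(G3 = 0.5)), "thresholds")
})

test_that("raising any threshold never adds a grade (monotone decision rule)", {
  set.seed(50)
  for (i in 1:100) {
    s <- tibble::tibble(score_g3 = runif(1), score_g4 = runif(1), score_g5 = runif(1))
    t1 <- runif(3); t2 <- pmin(t1 + runif(3, 0, 0.5), 1)
    m1 <- predict_multilabel(s, setNames(t1, gleason_grades()))
    m2 <- predict_multilabel(s, setNames(t2, gleason_grades()))
    expect_true(all(unlist(m2[, c("g3", "g4", "g5")]) <= unlist(m1[, c("g3", "g4", "g5")])))
  }
})

test_that("PR curves handle separable and degenerate score sets", {
  pr <- pr_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(attr(pr, "best_f1"), 1)
  expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  expect_true(all(diff(pr$recall) <= 0)) # recall non-increasing in threshold
  expect_equal(pr$f1, ifelse(pr$precision + pr$recall == 0, 0,
                             2 * pr$precision * pr$recall / (pr$precision + pr$recall)))
  # the sweep spans recall 1 down to 0
  expect_equal(pr$recall[1], 1)
  expect_equal(pr$recall[nrow(pr)], 0)

  # all-equal scores: the informative operating point has precision = prevalence
  tied <- pr_curve(rep(0.4, 5), c(1, 0, 1, 0, 0))
  expect_equal(tied$precision[1], 0.4)
  expect_equal(tied$recall[1], 1)

  expect_error(pr_curve(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("PR curve agrees with the brute-force confusion-table oracle on short inputs", {
  set.seed(60)
  grid <- seq(0.1, 0.9, by = 0.2) # coarse grid forces heavy score ties
  for (rep in 1:150) {
    n <- sample(2:8, 1)
    repeat {
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (any(labels) && !all(labels)) break
    }
    scores <- sample(grid, n, replace = TRUE)
    got <- pr_curve(scores, labels)
    ref <- brute_pr_best(scores, labels)
    expect_equal(attr(got, "best_f1"), ref$best_f1)
    expect_equal(attr(got, "best_threshold"), ref$best_threshold)
    expect_equal(as.matrix(tibble::as_tibble(got)), ref$table, ignore_attr = TRUE)
  }
})

test_that("the selected threshold tracks the F1-optimum of planted Gaussian scores", {
  set.seed(71)
  n <- 2000
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  scores <- ifelse(labels, rnorm(n, 0.7, 0.1), rnorm(n, 0.35, 0.1))
  scores <- pmin(pmax(scores, 0), 1)
  got <- attr(pr_curve(scores, labels), "best_threshold")
  # numeric oracle: F1 maximized over a fine fixed grid
  grid <- seq(0, 1, by = 0.002)
  f1s <- vapply(grid, function(t) {
    tp <- sum(scores > t & labels); fp <- sum(scores > t & !labels)
    fn <- sum(scores <= t & labels)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  expect_lt(abs(got - grid[which.max(f1s)]), 0.01)
})

test_that("multi-label metrics match hand-worked confusion tables", {
  ref <- tibble::tibble(
    g3 = c(1, 1, 0, 0, 0, 0, 1, 0), g4 = c(0, 1, 1, 0, 0, 1, 0, 0),
    g5 = c(0, 0, 0, 1, 0, 0, 0, 0), nc = c(0, 0, 0, 0, 1, 0, 0, 1)
  )
  pred <- tibble::tibble(
    g3 = c(1, 0, 0, 0, 0, 0, 1, 1), g4 = c(0, 1, 1, 0, 0, 0, 0, 0),
    g5 = c(0, 0, 0, 0, 0, 0, 0, 0), nc = c(0, 0, 0, 1, 1, 1, 0, 0)
  )
  ev <- evaluate_multilabels(pred, ref)
  pc <- ev$per_class
  # hand-computed: G3 tp=2 fp=1 fn=1 -> F1 = 4/6; G4 tp=2 fp=0 fn=1 -> 4/5;
  # G5 tp=0 fp=0 fn=1 -> 0; NC tp=1 fp=2 fn=1 -> 2/5
  expect_equal(pc$f1[pc$class == "G3"], 2 * 2 / (2 * 2 + 1 + 1))
  expect_equal(pc$f1[pc$class == "G4"], 0.8)
  expect_equal(pc$f1[pc$class == "G5"], 0)
  expect_equal(pc$f1[pc$class == "NC"], 0.4)
  expect_equal(ev$macro_f1, mean(pc$f1))
  # per-problem accuracies: G3 6/8, G4 7/8, G5 7/8, NC 5/8
  expect_equal(ev$accuracy, mean(c(6, 7, 7, 5) / 8))
  # exact matches: rows 1, 3, 5, 7 -> 4/8
  expect_equal(ev$subset_accuracy, 0.5)

  perfect <- evaluate_multilabels(ref, ref)
  expect_true(all(perfect$per_class$f1 == 1))
  expect_equal(perfect$accuracy, 1)
  complement <- evaluate_multilabels(dplyr::mutate(ref, dplyr::across(dplyr::everything(), ~ 1 - .x)), ref)
  expect_true(all(complement$per_class$f1 == 0))
})

test_that("macro F1 equals the mean of per-class F1 to machine precision", {
  set.seed(81)
  for (i in 1:20) {
    ref <- tibble::as_tibble(setNames(
      lapply(1:4, function(j) sample(0:1, 30, replace = TRUE)), c("g3", "g4", "g5", "nc")
    ))
    pred <- tibble::as_tibble(setNames(
      lapply(1:4, function(j) sample(0:1, 30, replace = TRUE)), c("g3", "g4", "g5", "nc")
    ))
    ev <- evaluate_multilabels(pred, ref)
    expect_identical(ev$macro_f1, mean(ev$per_class$f1))
  }
})

test_that("ensemble scoring, threshold selection and checkpoints work end to end on a tiny fit", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(
    n_patients = 5L, slide_size = c(192L, 192L), patch_size = 64L,
    blob_scale = 64, seed = 5L
  )
  man <- generate_dataset(cfg, dir)
  tc <- train_config(max_epochs = 2L, batch_size = 16L, input_size = 24L,
                     augment = FALSE, seed = 3L)
  ens <- train_ensemble(man, label_policy(), tc,
                        train_folds = c("Val1", "Val2", "Val3"), val_folds = "Val4")
  expect_s3_class(ens, "gleason_ensemble")
  expect_true(all(ens$thresholds >= 0 & ens$thresholds <= 1))
  sc <- predict_scores(ens, head(man, 4), input_size = 24L)
  expect_true(all(unlist(sc[, -1]) >= 0 & unlist(sc[, -1]) <= 1))
  # deterministic inference
  expect_identical(sc, predict_scores(ens, head(man, 4), input_size = 24L))
  # zeroed head gives exactly symmetric logits -> score 0.5
  z <- ens$sub_models$G3
  z$params$fc_w[] <- 0; z$params$fc_b[] <- 0
  x <- load_patch_array(man$patch_path[1], 24L)
  expect_equal(unname(mlgleason:::model_scores(z, x)), 0.5)
  ev <- evaluate_ensemble(ens, dplyr::filter(man, fold == "Test"), label_policy(),
                          input_size = 24L)
  expect_s3_class(glance(ev), "tbl_df")
  expect_equal(ev$macro_f1, mean(ev$per_class$f1))
  ck <- file.path(dir, "ens.rds")
  save_checkpoint(ens, ck)
  back <- load_checkpoint(ck)
  expect_equal(back$thresholds, ens$thresholds)
  expect_identical(
    predict_scores(back, head(man, 2), input_size = 24L),
    predict_scores(ens, head(man, 2), input_size = 24L)
  )
})
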