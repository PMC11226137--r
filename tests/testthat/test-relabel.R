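test_that("majority label follows pixel dominance, ignores background, breaks ties upward", {
  expect_equal(grade_name(majority_label(mask_with(10, G4 = 0.6, G3 = 0.4))), "G4")
  expect_equal(grade_name(majority_label(matrix(codes[["NC"]], 4, 4))), "NC")
  # exactly 50/50 G3-G5: the higher grade wins
  m <- matrix(c(rep(codes[["G3"]], 8), rep(codes[["G5"]], 8)), 4, 4)
  expect_equal(grade_name(majority_label(m)), "G5")
  # background pixels never vote
  m2 <- mask_with(10, G3 = 0.04, bg_fraction = 0.9)
  expect_equal(grade_name(majority_label(m2)), "G3")
  expect_error(majority_label(matrix(codes[["BG"]], 3, 3)), "background")
})

test_that("majority label agrees with a brute-force counter on exhaustive 2x2 tissue masks", {
  vals <- codes[c("NC", "G3", "G4", "G5")]
  grid <- expand.grid(vals, vals, vals, vals)
  for (i in seq_len(nrow(grid))) {
    m <- matrix(as.integer(unlist(grid[i, ])), 2, 2)
    expect_equal(grade_name(majority_label(m)), brute_majority(m))
  }
})

test_that("the 1% threshold on a 512x512 patch means 2621 pixels", {
  pol <- label_policy(tau = 0.01)
  expect_identical(mlgleason:::policy_count_threshold(pol, 512L * 512L), 2621)
  in_mask <- mask_with(512, G3 = 2622 / 262144)
  expect_equal(multilabel_from_mask(in_mask, pol)$grades, "G3")
  at_mask <- mask_with(512, G3 = 2621 / 262144)
  expect_equal(multilabel_from_mask(at_mask, pol)$grades, "G3")
  below <- mask_with(512, G3 = 2620 / 262144)
  ml <- multilabel_from_mask(below, pol)
  expect_equal(ml$grades, character(0))
  expect_false(ml$nc) # ambiguous, not benign
})

test_that("multi-labels capture minority grades and respect the NC rule", {
  pol <- label_policy()
  both <- multilabel_from_mask(mask_with(100, G4 = 0.98, G5 = 0.02), pol)
  expect_setequal(both$grades, c("G4", "G5"))
  expect_false(both$nc)
  pure_nc <- multilabel_from_mask(matrix(codes[["NC"]], 20, 20), pol)
  expect_true(pure_nc$nc)
  expect_length(pure_nc$grades, 0)
  # sub-threshold cancer: not NC, not labelled
  amb <- multilabel_from_mask(mask_with(100, G3 = 0.005), pol)
  expect_length(amb$grades, 0)
  expect_false(amb$nc)
  expect_error(multilabel_from_mask(matrix(codes[["BG"]], 4, 4), pol), "background")
})

test_that("multilabel and fractions agree with brute-force counting on random masks", {
  set.seed(402)
  pol_all <- label_policy(tau = 0.03)
  pol_tis <- label_policy(tau = 0.03, denominator = "tissue_pixels")
  for (i in seq_len(200)) {
    m <- random_mask(16)
    for (pol in list(pol_all, pol_tis)) {
      ml <- multilabel_from_mask(m, pol)
      ref <- brute_multilabel(m, pol$tau, pol$denominator)
      expect_setequal(ml$grades, ref$grades)
      expect_equal(ml$nc, as.logical(ref$nc))
    }
    fr <- misclassified_fractions(m)
    ref_fr <- brute_fractions(m)
    expect_equal(fr[sort(names(fr))], ref_fr[sort(names(ref_fr))])
  }
})

test_that("label-set properties hold: majority superset, tau monotonicity, count conservation", {
  set.seed(91)
  for (i in seq_len(60)) {
    m <- random_mask(12)
    counts <- grade_pixel_counts(m)
    expect_equal(sum(counts), length(m))
    maj <- grade_name(majority_label(m))
    taus <- c(0, 0.05, 0.2, 0.5, 1)
    sets <- lapply(taus, function(t) multilabel_from_mask(m, label_policy(tau = t))$grades)
    for (k in seq_len(length(taus) - 1)) {
      expect_true(all(sets[[k + 1]] %in% sets[[k]])) # higher tau never adds
    }
    if (maj %in% gleason_grades() && counts[maj] / length(m) >= 0.2) {
      expect_true(maj %in% sets[[3]]) # majority clears its own threshold
    }
  }
})

test_that("misclassified fractions report off-majority grades only", {
  fr <- misclassified_fractions(mask_with(100, G4 = 0.7, G3 = 0.3))
  expect_equal(fr[["G3"]], 0.3)
  expect_equal(fr[["G5"]], 0)
  expect_false("G4" %in% names(fr))
  expect_equal(unname(misclassified_fractions(matrix(codes[["NC"]], 8, 8))), c(0, 0, 0))
})

test_that("the inconsistency audit aggregates planted fractions exactly", {
  dir <- withr::local_tempdir()
  # per class: off-majority fractions 0.10 and 0.20 planted in G4-majority masks
  masks <- list( # size 80: all fractions are exact pixel counts (6400 px)
    mask_with(80, G4 = 0.6, G3 = 0.10), mask_with(80, G4 = 0.6, G3 = 0.20),
    mask_with(80, G3 = 0.6, G5 = 0.10), mask_with(80, G3 = 0.6, G5 = 0.20)
  )
  man <- write_planted_manifest(masks, rep("Val1", 4), dir)
  rep <- inconsistency_report(man)
  s <- rep$summary
  g3 <- s[s$class == "G3" & s$fold == "Val1", ]
  expect_equal(g3$mean_frac, 0.15)
  expect_equal(g3$max_frac, 0.20)
  expect_equal(g3$n, 2L)
  g5 <- s[s$class == "G5" & s$fold == "Val1", ]
  expect_equal(g5$mean_frac, 0.15)
  expect_equal(g5$max_frac, 0.20)
  # G4 never occurs off-majority here
  g4 <- s[s$class == "G4" & s$fold == "Val1", ]
  expect_equal(g4$mean_frac, 0)
  expect_equal(g4$max_frac, 0)
  expect_equal(g4$n, 0L)
  expect_error(inconsistency_report(man[0, ]), "empty")
  # histogram bins are 1 percentage point wide and count planted patches
  h <- rep$histogram
  expect_setequal(h$bin[h$class == "G3"], c(0.10, 0.20))
})

test_that("binary targets split positives, negatives and exclusions per grade", {
  dir <- withr::local_tempdir()
  masks <- list(
    mask_with(64, G4 = 0.5, G5 = 0.05), # G4+G5
    matrix(codes[["NC"]], 64, 64), # NC
    mask_with(64, G3 = 0.005) # sub-threshold: excluded
  )
  man <- write_planted_manifest(masks, rep("Val1", 3), dir)
  t4 <- binary_targets(man, label_policy(), "G4")
  expect_equal(as.character(t4$target), c("positive", "negative", "excluded"))
  t3 <- binary_targets(man, label_policy(), "G3")
  expect_equal(as.character(t3$target), c("negative", "negative", "excluded"))
  expect_error(binary_targets(man, label_policy(), "NC"), "G3")
})

test_that("relabelling a manifest recovers the planted label columns", {
  dir <- withr::local_tempdir()
  masks <- list(
    mask_with(32, G3 = 0.3), mask_with(32, G4 = 0.5, G5 = 0.1),
    matrix(codes[["NC"]], 32, 32)
  )
  man <- write_planted_manifest(masks, c("Val1", "Val2", "Test"), dir)
  rel <- relabel_manifest(man)
  expect_equal(rel$g3, c(1L, 0L, 0L))
  expect_equal(rel$g4, c(0L, 1L, 0L))
  expect_equal(rel$g5, c(0L, 1L, 0L))
  expect_equal(rel$nc, c(0L, 0L, 1L))
  expect_equal(rel$excluded, c(0L, 0L, 0L))
  expect_equal(rel$majority, c("G3", "G4", "NC"))
})
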