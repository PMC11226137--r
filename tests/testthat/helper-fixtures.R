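# Shared fixture builders. Everything is generated in code at test time.

codes <- grade_codes()

# mask from a named fraction spec laid out deterministically
mask_with <- function(size, ...) generate_patch_mask(size, c(...))

# brute-force label arithmetic, independent of the relabel module: plain
# table() counting and literal threshold comparison
brute_counts <- function(mask) {
  sapply(c(BG = 0L, NC = 1L, G3 = 2L, G4 = 3L, G5 = 4L), function(cd) sum(mask == cd))
}

brute_multilabel <- function(mask, tau, denom = "all_pixels", min_count = 1L) {
  ct <- brute_counts(mask)
  n <- if (denom == "all_pixels") length(mask) else sum(mask != 0L)
  thr <- max(min_count, floor(tau * n))
  g <- ct[c("G3", "G4", "G5")]
  list(grades = names(g)[g >= thr], nc = sum(g) == 0L)
}

brute_majority <- function(mask) {
  ct <- brute_counts(mask)[c("G3", "G4", "G5")]
  if (sum(ct) == 0L) return("NC")
  best <- max(ct)
  # higher grade wins ties
  rev(names(ct))[which(rev(ct) == best)[1]]
}

brute_fractions <- function(mask, denom = "all_pixels") {
  m <- brute_majority(mask)
  ct <- brute_counts(mask)
  n <- if (denom == "all_pixels") length(mask) else sum(mask != 0L)
  others <- setdiff(c("G3", "G4", "G5"), m)
  setNames(as.numeric(ct[others]) / n, others)
}

# random grade-code mask with at least one tissue pixel
random_mask <- function(size, p_codes = c(0.1, 0.3, 0.2, 0.25, 0.15)) {
  repeat {
    m <- matrix(sample(0:4, size * size, replace = TRUE, prob = p_codes), size, size)
    if (any(m != 0L)) return(m)
  }
}

# tiny on-disk manifest of planted masks; images are flat grey so the paths
# resolve (image content is irrelevant to relabelling)
write_planted_manifest <- function(masks, folds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(masks), function(i) {
    ip <- file.path(dir, sprintf("img%02d.png", i))
    mp <- file.path(dir, sprintf("mask%02d.png", i))
    write_patch(array(0.5, c(nrow(masks[[i]]), ncol(masks[[i]]), 3)), ip)
    write_mask(masks[[i]], mp)
    tibble::tibble(
      patch_path = ip, mask_path = mp,
      patient_id = sprintf("P%02d", i), slide_id = sprintf("S%02d", i),
      fold = folds[i]
    )
  })
  dplyr::bind_rows(rows)
}

# brute-force PR sweep: literal confusion table at every candidate threshold
brute_pr_best <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  eps <- max(diff(range(u)), 1) * 1e-6
  cand <- c(u[1] - eps, u, u[length(u)] + eps)
  best_f1 <- -1; best_t <- NA
  rows <- list()
  for (t in cand) {
    pred <- scores > t
    tp <- sum(pred & labels); fp <- sum(pred & !labels); fn <- sum(!pred & labels)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    rows[[length(rows) + 1]] <- c(t, prec, rec, f1)
    if (f1 > best_f1 + 1e-12) { best_f1 <- f1; best_t <- t }
  }
  list(best_f1 = best_f1, best_threshold = best_t,
       table = do.call(rbind, rows))
}

# the separable two-colour toy problem used by the quick training tests
toy_binary_data <- function(n, size = 16L, noise = 0.05, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 2L), length.out = n)
  x <- array(0, c(size, size, 3L, n))
  for (i in seq_len(n)) {
    base <- if (y[i] == 2L) c(0.4, 0.25, 0.45) else c(0.9, 0.72, 0.84)
    x[, , , i] <- pmin(pmax(
      array(rep(base, each = size * size), c(size, size, 3L)) +
        array(rnorm(size * size * 3L, 0, noise), c(size, size, 3L)),
      0), 1)
  }
  list(x = x, y = y)
}
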