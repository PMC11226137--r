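#' Configuration for the synthetic slide generator
#'
#' The generator emulates the structure of a pixel-annotated prostate-biopsy
#' patch dataset: H&E-like tissue on a white background, Gleason-grade
#' regions as contiguous blobs with class-distinct colour/texture, pixel
#' masks aligned with the painted regions, patient-exclusive five-fold
#' splits, square patches cut at fixed overlap, and a minimum-tissue filter.
#' Defaults follow the conventions of the real datasets this stands in for:
#' 512-pixel patches at 50% overlap and a 20% tissue threshold.
#'
#' @param n_patients Number of synthetic patients (>= 5, one per fold minimum).
#' @param slides_per_patient Slides generated per patient.
#' @param slide_size Integer `(H, W)` of each slide in pixels.
#' @param class_mixture Named target area fractions over `NC`, `G3`, `G4`,
#'   `G5` as fractions of the whole slide; must sum to <= 1, remainder is
#'   white background.
#' @param blob_scale Spatial scale of the blob noise fields in pixels.
#' @param noise_sd Pixel noise standard deviation in 8-bit units, applied to
#'   tissue only (background stays exactly white so empty patches are
#'   degenerate for the tissue detector).
#' @param patch_size Patch side in pixels.
#' @param overlap Patch overlap fraction in `[0, 1)`.
#' @param tissue_min_frac Minimum tissue fraction for a patch to survive.
#' @param seed Generator seed; all output is a pure function of
#'   (config, seed).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 10L, slides_per_patient = 1L,
                             slide_size = c(2048L, 2048L),
                             class_mixture = c(NC = 0.35, G3 = 0.10, G4 = 0.15, G5 = 0.05),
                             blob_scale = 64, noise_sd = 6,
                             patch_size = 512L, overlap = 0.5,
                             tissue_min_frac = 0.20, seed = 1L) {
  if (sum(class_mixture) > 1 + 1e-12) abort("class_mixture must sum to <= 1")
  if (any(class_mixture < 0)) abort("class_mixture fractions must be >= 0")
  if (patch_size < 32) abort("patch_size must be >= 32")
  if (overlap < 0 || overlap >= 1) abort("overlap must be in [0, 1)")
  miss <- setdiff(c("NC", "G3", "G4", "G5"), names(class_mixture))
  if (length(miss)) class_mixture[miss] <- 0
  structure(
    list(
      n_patients = as.integer(n_patients), slides_per_patient = as.integer(slides_per_patient),
      slide_size = as.integer(slide_size), class_mixture = class_mixture[c("NC", "G3", "G4", "G5")],
      blob_scale = blob_scale, noise_sd = noise_sd,
      patch_size = as.integer(patch_size), overlap = overlap,
      tissue_min_frac = tissue_min_frac, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# smooth random field in [0,1]: low-res gaussian noise upsampled bilinearly
smooth_field <- function(h, w, scale) {
  lh <- max(2L, ceiling(h / scale)); lw <- max(2L, ceiling(w / scale))
  low <- array(rnorm(lh * lw), c(lh, lw, 1L))
  f <- cpp_bilinear_resize(low, as.integer(h), as.integer(w))[, , 1L]
  (f - min(f)) / max(max(f) - min(f), 1e-12)
}

# per-class base colours (H&E-like pinks/purples, darker with grade) and
# texture stamps carrying the class signal
class_paint <- list(
  NC = list(rgb = c(0.87, 0.60, 0.77), stamp = "none"),
  G3 = list(rgb = c(0.68, 0.38, 0.58), stamp = "ring"),
  G4 = list(rgb = c(0.52, 0.42, 0.76), stamp = "dot"),
  G5 = list(rgb = c(0.34, 0.18, 0.38), stamp = "sheet")
)

stamp_offsets <- function(kind) {
  r <- 4
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d <- sqrt(g$dy^2 + g$dx^2)
  if (kind == "ring") g[d >= r - 1.5 & d <= r, ] else g[d <= 1.5, ]
}

#' Generate one synthetic slide with its annotation mask
#'
#' The slide starts as pure white; a smooth-noise field defines a contiguous
#' tissue region painted with an H&E-like pink base; Gleason-grade regions
#' are carved out of the tissue as blobs of the per-grade smooth fields with
#' exact planted pixel counts (top-k field values among unassigned tissue
#' pixels), then painted with class-distinct colour and stamped texture
#' (G3 sparse rings, G4 dense dots, G5 dark sheets). The returned mask is
#' pixel-aligned with the paint.
#'
#' @param config A [synthetic_config()].
#' @param seed Seed for this slide.
#' @return List with `image` (`H x W x 3` in `[0, 1]`), `mask` (integer
#'   matrix of grade codes) and `ground_truth` (tibble: class, pixels,
#'   fraction of slide area).
#' @export
generate_slide <- function(config, seed = config$seed) {
  h <- config$slide_size[1]; w <- config$slide_size[2]
  mix <- config$class_mixture
  if (sum(mix) > 1 + 1e-12) abort("class mixture infeasible within slide area")
  with_seed(seed, {
    npix <- h * w
    tissue_n <- round(sum(mix) * npix)
    tf <- smooth_field(h, w, config$blob_scale * 2)
    ord <- order(tf, decreasing = TRUE)
    tissue <- logical(npix); tissue[ord[seq_len(tissue_n)]] <- TRUE
    mask <- matrix(ifelse(tissue, grade_code("NC"), grade_code("BG")), h, w)
    avail <- which(tissue)
    for (g in c("G5", "G4", "G3")) {
      ng <- round(mix[[g]] * npix)
      if (ng == 0L) next
      if (ng > length(avail)) abort("class mixture infeasible within slide area")
      f <- smooth_field(h, w, config$blob_scale)
      pick <- avail[order(f[avail], decreasing = TRUE)[seq_len(ng)]]
      mask[pick] <- grade_code(g)
      avail <- setdiff(avail, pick)
    }
    img <- array(1, c(h, w, 3L))
    for (g in names(class_paint)) {
      sel <- which(mask == grade_code(g))
      if (!length(sel)) next
      col <- class_paint[[g]]$rgb
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- col[ch]
        img[, , ch] <- plane
      }
    }
    # texture stamps inside grade regions
    for (g in gleason_grades()) {
      sel <- which(mask == grade_code(g))
      if (!length(sel)) next
      kind <- class_paint[[g]]$stamp
      density <- c(ring = 1 / 150, dot = 1 / 60, sheet = 0)[[kind]]
      nstamp <- round(length(sel) * density)
      if (nstamp > 0) {
        centers <- sel[sample.int(length(sel), nstamp)]
        off <- stamp_offsets(kind)
        ci <- (centers - 1L) %% h + 1L
        cj <- (centers - 1L) %/% h + 1L
        for (k in seq_len(nrow(off))) {
          ii <- ci + off$dy[k]; jj <- cj + off$dx[k]
          ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
          lin <- ii[ok] + (jj[ok] - 1L) * h
          lin <- lin[mask[lin] == grade_code(g)] # clip stamps to the region
          for (ch in 1:3) {
            plane <- img[, , ch]
            plane[lin] <- plane[lin] * 0.4
            img[, , ch] <- plane
          }
        }
      }
    }
    if (config$noise_sd > 0) {
      tsel <- which(mask != grade_code("BG"))
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[tsel] <- plane[tsel] + rnorm(length(tsel), 0, config$noise_sd / 255)
        img[, , ch] <- plane
      }
      img <- pmin(pmax(img, 0), 1)
    }
    counts <- grade_pixel_counts(mask)
    gt <- tibble::tibble(
      class = names(counts), pixels = unname(counts),
      fraction = unname(counts) / npix
    )
    list(image = img, mask = mask, ground_truth = gt)
  })
}

#' Otsu threshold and tissue mask
#'
#' Converts the image to Rec. 601 luminance (`0.299 R + 0.587 G + 0.114 B`),
#' quantizes to 8 bits, and finds the threshold maximizing the between-class
#' variance of the two-way split. Tissue is the darker class (stained tissue
#' on a bright slide background). A constant image has no two-way split and
#' yields an all-background mask.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]` (or an `H x W` matrix
#'   treated as luminance).
#' @param threshold Optional precomputed 8-bit threshold (e.g. estimated on
#'   the whole slide); `NULL` estimates it from `image` itself.
#' @return `otsu_tissue_mask()`: logical matrix, `TRUE` = tissue.
#'   `otsu_threshold()`: the 8-bit threshold (pixels `<= t` are tissue), or
#'   `NA` for a constant image.
#' @export
otsu_tissue_mask <- function(image, threshold = NULL) {
  lum <- luminance8(image)
  t <- threshold %||% otsu_threshold_counts(tabulate(lum + 1L, nbins = 256L))
  if (is.na(t)) {
    matrix(FALSE, nrow(lum), ncol(lum))
  } else {
    lum <= t
  }
}

#' @rdname otsu_tissue_mask
#' @export
otsu_threshold <- function(image) {
  otsu_threshold_counts(tabulate(luminance8(image) + 1L, nbins = 256L))
}

luminance8 <- function(image) {
  if (length(dim(image)) == 3L) {
    lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    lum <- image
  }
  if (length(lum) == 0L) abort("empty image")
  matrix(as.integer(round(pmin(pmax(lum, 0), 1) * 255)), nrow(lum), ncol(lum))
}

# argmax of between-class variance over all 255 candidate splits of a
# 256-bin histogram; first (lowest) argmax on ties; NA when one class empty
otsu_threshold_counts <- function(counts) {
  stopifnot(length(counts) == 256L)
  counts <- as.numeric(counts)
  n <- sum(counts)
  lv <- 0:255
  w0 <- cumsum(counts)[1:255]
  w1 <- n - w0
  s0 <- cumsum(counts * lv)[1:255]
  mu0 <- s0 / w0
  mu1 <- (sum(counts * lv) - s0) / w1
  sb <- w0 * w1 * (mu0 - mu1)^2
  sb[!is.finite(sb)] <- -Inf
  if (all(sb <= 0)) return(NA_integer_)
  as.integer(which.max(sb) - 1L)
}

#' Cut a slide into overlapping patches
#'
#' Windows of `patch_size` pixels are placed row-major at stride
#' `patch_size * (1 - overlap)` over half-open windows
#' `[r, r + size) x [c, c + size)` with 0-based origins. A window survives
#' only if its own Otsu tissue mask covers at least `tissue_min_frac` of it.
#'
#' @param image Slide RGB array.
#' @param mask Slide grade-code mask (same spatial size).
#' @param config A [synthetic_config()] (supplies `patch_size`, `overlap`,
#'   `tissue_min_frac`).
#' @return Tibble with 0-based `origin_row`, `origin_col`, `tissue_frac` and
#'   list-columns `image`, `mask` holding the patch crops.
#' @export
extract_patches <- function(image, mask, config) {
  h <- dim(image)[1]; w <- dim(image)[2]
  ps <- config$patch_size
  if (h < ps || w < ps) abort("slide smaller than one patch")
  stride <- as.integer(round(ps * (1 - config$overlap)))
  rows <- seq(0L, h - ps, by = stride)
  cols <- seq(0L, w - ps, by = stride)
  grid <- expand.grid(origin_col = cols, origin_row = rows)[, c(2, 1)]
  # threshold estimated once on the slide (clearly bimodal: white background
  # vs stained tissue), then applied per window: a window that is entirely
  # tissue has no background mode of its own to calibrate on
  slide_t <- otsu_threshold(image)
  recs <- purrr::pmap(grid, function(origin_row, origin_col) {
    ri <- (origin_row + 1):(origin_row + ps)
    ci <- (origin_col + 1):(origin_col + ps)
    pimg <- image[ri, ci, , drop = FALSE]
    pmask <- mask[ri, ci]
    tf <- mean(otsu_tissue_mask(pimg, threshold = slide_t))
    list(
      origin_row = origin_row, origin_col = origin_col,
      tissue_frac = tf, image = pimg, mask = pmask
    )
  })
  out <- tibble::tibble(
    origin_row = purrr::map_int(recs, ~ as.integer(.x$origin_row)),
    origin_col = purrr::map_int(recs, ~ as.integer(.x$origin_col)),
    tissue_frac = purrr::map_dbl(recs, "tissue_frac"),
    image = purrr::map(recs, "image"),
    mask = purrr::map(recs, "mask")
  )
  out[out$tissue_frac >= config$tissue_min_frac, ]
}

#' Generate a full synthetic patch dataset on disk
#'
#' Generates `n_patients x slides_per_patient` slides, assigns each patient
#' to exactly one of the five folds (shuffled round-robin, so per-fold class
#' presence is balanced by construction), cuts and filters patches, and
#' writes `images/`, `masks/`, `manifest.csv` and `ground_truth.csv` under
#' `out_dir`. Ground truth records each patch's per-grade pixel counts and
#' the multi-label the generator itself derives from its planted mask — an
#' independent check for the relabelling stage.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param policy [label_policy()] used for the ground-truth multilabels.
#' @return The manifest tibble (invisibly also written to disk), with
#'   attribute `ground_truth`.
#' @export
generate_dataset <- function(config, out_dir, policy = label_policy()) {
  if (config$n_patients < 5L) abort("need at least 5 patients for 5 patient-exclusive folds")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  folds <- c("Val1", "Val2", "Val3", "Val4", "Test")
  rows <- list(); gts <- list()
  with_seed(config$seed, {
    patient_fold <- setNames(
      rep(folds, length.out = config$n_patients)[sample.int(config$n_patients)],
      sprintf("P%02d", seq_len(config$n_patients))
    )
    slide_seeds <- sample.int(.Machine$integer.max - 1L,
                              config$n_patients * config$slides_per_patient)
    k <- 0L
    for (p in names(patient_fold)) {
      for (s in seq_len(config$slides_per_patient)) {
        k <- k + 1L
        slide_id <- sprintf("%s_S%d", p, s)
        sl <- generate_slide(config, seed = slide_seeds[k])
        patches <- extract_patches(sl$image, sl$mask, config)
        for (i in seq_len(nrow(patches))) {
          pid <- sprintf("%s_r%04d_c%04d", slide_id,
                         patches$origin_row[i], patches$origin_col[i])
          ip <- file.path("images", paste0(pid, ".png"))
          mp <- file.path("masks", paste0(pid, ".png"))
          write_patch(patches$image[[i]], file.path(out_dir, ip))
          write_mask(patches$mask[[i]], file.path(out_dir, mp))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            patch_path = ip, mask_path = mp, patient_id = p,
            slide_id = slide_id, fold = patient_fold[[p]]
          )
          counts <- grade_pixel_counts(patches$mask[[i]])
          ml <- generator_multilabel(counts, policy)
          gts[[length(gts) + 1L]] <- tibble::tibble(
            patch_path = ip,
            bg = counts[["BG"]], nc_pixels = counts[["NC"]],
            g3_pixels = counts[["G3"]], g4_pixels = counts[["G4"]],
            g5_pixels = counts[["G5"]],
            g3 = ml[["g3"]], g4 = ml[["g4"]], g5 = ml[["g5"]], nc = ml[["nc"]]
          )
        }
      }
    }
  })
  manifest <- dplyr::bind_rows(rows)
  gt <- dplyr::bind_rows(gts)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  readr::write_csv(gt, file.path(out_dir, "ground_truth.csv"), progress = FALSE)
  out <- validate_manifest(manifest, dir = out_dir, check_paths = TRUE)
  attr(out, "ground_truth") <- gt
  out
}

# the generator's own label arithmetic, kept deliberately independent of
# multilabel_from_mask() so the two can cross-check each other
generator_multilabel <- function(counts, policy) {
  n <- if (policy$denominator == "all_pixels") sum(counts) else sum(counts) - counts[["BG"]]
  thr <- max(policy$min_count, floor(policy$tau * n))
  g <- counts[gleason_grades()]
  c(
    g3 = as.integer(g[["G3"]] >= thr), g4 = as.integer(g[["G4"]] >= thr),
    g5 = as.integer(g[["G5"]] >= thr), nc = as.integer(all(g == 0L))
  )
}

#' Plant a patch mask with exact class fractions
#'
#' Deterministically builds a mask whose per-grade pixel counts are exactly
#' `round(fraction * size^2)`, filling the remainder with NC tissue (and
#' optionally background). Grades are laid out as contiguous row bands, so
#' the planted off-majority fractions are recovered exactly by the audit —
#' this is the fixture generator for the label-noise statistics.
#'
#' @param size Patch side in pixels.
#' @param fractions Named fractions over any of `G3`, `G4`, `G5` (of the
#'   whole patch area).
#' @param bg_fraction Fraction of background pixels (default 0).
#' @return Integer grade-code matrix `size x size`.
#' @examples
#' m <- generate_patch_mask(64, c(G4 = 0.6, G3 = 0.3))
#' grade_name(majority_label(m)) # "G4"
#' @export
generate_patch_mask <- function(size, fractions = c(), bg_fraction = 0) {
  npix <- size * size
  if (sum(fractions) + bg_fraction > 1 + 1e-12) abort("fractions exceed patch area")
  mask <- matrix(grade_code("NC"), size, size)
  pos <- 1L
  for (g in intersect(c("G5", "G4", "G3"), names(fractions))) {
    ng <- round(fractions[[g]] * npix)
    if (ng > 0) {
      mask[pos:(pos + ng - 1L)] <- grade_code(g)
      pos <- pos + ng
    }
  }
  nbg <- round(bg_fraction * npix)
  if (nbg > 0) mask[(npix - nbg + 1L):npix] <- grade_code("BG")
  mask
}
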