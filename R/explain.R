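#' Grad-CAM heatmap for a sub-classifier decision
#'
#' Gradient-weighted class activation mapping on the last convolutional
#' feature maps (the output of the final ReLU before global average
#' pooling): each channel's weight is the spatial mean of the gradient of
#' the target logit (pre-softmax) with respect to that channel, the map is
#' the ReLU of the weighted channel sum, upsampled bilinearly to the input
#' size and normalized to max 1 (left all-zero if every value is zero).
#'
#' @param model A `gleason_cnn` (or `gleason_cnn_fit`).
#' @param image `H x W x 3` array in `[0, 1]` (resized to `input_size`).
#' @param target_class 1 (negative) or 2 (positive, default) — the logit to
#'   explain.
#' @param input_size Network input side.
#' @return A `gleason_heatmap`: the `input_size x input_size` map matrix
#'   with attributes `target_class` and `layer`.
#' @export
grad_cam <- function(model, image, target_class = 2L, input_size = dim(image)[1]) {
  if (inherits(model, "gleason_cnn_fit")) model <- model$model
  if (!target_class %in% c(1L, 2L)) abort("target_class must be 1 or 2")
  if (length(dim(image)) != 3L) abort("image must be H x W x 3")
  if (dim(image)[1] != input_size || dim(image)[2] != input_size) {
    image <- cpp_bilinear_resize(image, as.integer(input_size), as.integer(input_size))
  }
  x <- array(image, c(dim(image), 1L))
  fw <- cnn_forward(model, x, training = FALSE, cache = TRUE)
  feats <- fw$cache$o4[, , , 1L, drop = TRUE] # Hf x Wf x C
  # d(logit_k)/d(features) through the FC head and GAP: constant per channel
  hw <- dim(feats)[1] * dim(feats)[2]
  dgap <- model$params$fc_w[target_class, ] # d logit / d pooled feature
  grads <- rep(dgap / hw, each = hw)
  dim(grads) <- dim(feats)
  map <- grad_cam_core(feats, grads)
  map <- cpp_bilinear_resize(array(map, c(dim(map), 1L)),
                             as.integer(input_size), as.integer(input_size))[, , 1L]
  map <- pmax(map, 0)
  structure(normalize_max(map), class = "gleason_heatmap",
            target_class = target_class, layer = "block4_relu")
}

#' @rdname grad_cam
#' @param features `Hf x Wf x C` feature maps at the target layer.
#' @param gradients Array of the same shape: gradient of the target logit
#'   with respect to each feature value.
#' @return `grad_cam_core()`: the raw (un-resized, max-normalized)
#'   `Hf x Wf` map.
#' @export
grad_cam_core <- function(features, gradients) {
  stopifnot(identical(dim(features), dim(gradients)))
  ch <- dim(features)[3]
  alpha <- vapply(seq_len(ch), function(k) mean(gradients[, , k]), 0)
  wsum <- matrix(0, dim(features)[1], dim(features)[2])
  for (k in seq_len(ch)) wsum <- wsum + alpha[k] * features[, , k]
  normalize_max(pmax(wsum, 0))
}

normalize_max <- function(m) {
  mx <- max(m)
  if (mx > 0) m / mx else m
}

#' @export
print.gleason_heatmap <- function(x, ...) {
  cat("<gleason_heatmap>", paste(dim(x), collapse = "x"),
      "from", attr(x, "layer"), "- max", format(max(x), digits = 3), "\n")
  invisible(x)
}

#' @rdname grad_cam
#' @param object A `gleason_heatmap`.
#' @param ... Unused.
#' @export
autoplot.gleason_heatmap <- function(object, ...) {
  d <- tibble::tibble(
    row = rep(seq_len(nrow(object)), ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    value = as.vector(object)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Grad-CAM heatmap", fill = "activation") +
    ggplot2::theme_minimal()
}

#' Slide-level activation maps stitched from patches
#'
#' Paints each patch's contribution — its scalar detection score
#' (`mode = "score"`) or its Grad-CAM map (`mode = "gradcam"`) — onto its
#' window in slide coordinates, averaging overlapping contributions by
#' coverage count. Pixels never covered by a patch are `NA` (absent), not
#' zero. The result is the whole-slide view of where each sub-classifier
#' fires.
#'
#' @param ensemble A [gleason_ensemble()].
#' @param slide `H x W x 3` slide image.
#' @param patch_grid Tibble with 0-based `origin_row`, `origin_col` (e.g.
#'   from [extract_patches()]).
#' @param patch_size Patch window side in pixels.
#' @param input_size Network input side for scoring.
#' @param mode `"score"` or `"gradcam"`.
#' @return A `slide_activation_map`: list with per-grade matrices (`G3`,
#'   `G4`, `G5`; `NA` where uncovered) and the integer `coverage` matrix.
#' @export
slide_activation_map <- function(ensemble, slide, patch_grid, patch_size,
                                 input_size = 32L, mode = c("score", "gradcam")) {
  mode <- match.arg(mode)
  if (nrow(patch_grid) == 0L) abort("empty patch grid")
  h <- dim(slide)[1]; w <- dim(slide)[2]
  if (any(patch_grid$origin_row + patch_size > h) ||
      any(patch_grid$origin_col + patch_size > w)) {
    abort("patch window extends beyond the slide")
  }
  acc <- purrr::map(setNames(gleason_grades(), gleason_grades()),
                    ~ matrix(0, h, w))
  cover <- matrix(0L, h, w)
  for (i in seq_len(nrow(patch_grid))) {
    ri <- (patch_grid$origin_row[i] + 1):(patch_grid$origin_row[i] + patch_size)
    ci <- (patch_grid$origin_col[i] + 1):(patch_grid$origin_col[i] + patch_size)
    pimg <- slide[ri, ci, , drop = FALSE]
    for (g in gleason_grades()) {
      contrib <- if (mode == "score") {
        x <- resize_batch(array(pimg, c(dim(pimg)[1:3], 1L)), input_size)
        matrix(model_scores(ensemble$sub_models[[g]], x), length(ri), length(ci))
      } else {
        hm <- grad_cam(ensemble$sub_models[[g]], pimg[, , , drop = TRUE],
                       input_size = input_size)
        cpp_bilinear_resize(array(unclass(hm), c(dim(hm), 1L)),
                            length(ri), length(ci))[, , 1L]
      }
      acc[[g]][ri, ci] <- acc[[g]][ri, ci] + contrib
    }
    cover[ri, ci] <- cover[ri, ci] + 1L
  }
  maps <- purrr::map(acc, function(a) {
    out <- a / cover
    out[cover == 0L] <- NA_real_
    out
  })
  structure(list(maps = maps, coverage = cover), class = "slide_activation_map")
}

#' @export
print.slide_activation_map <- function(x, ...) {
  cat("<slide_activation_map>", paste(dim(x$coverage), collapse = "x"),
      "- covered fraction", format(mean(x$coverage > 0), digits = 3), "\n")
  invisible(x)
}

#' @rdname slide_activation_map
#' @param object A `slide_activation_map`.
#' @param ... Unused.
#' @export
autoplot.slide_activation_map <- function(object, ...) {
  d <- purrr::imap_dfr(object$maps, function(m, g) {
    tibble::tibble(
      grade = g,
      row = rep(seq_len(nrow(m)), ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(m)
    )
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "grey90") +
    ggplot2::facet_wrap(~grade) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Whole-slide activation maps", fill = "score") +
    ggplot2::theme_minimal()
}
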