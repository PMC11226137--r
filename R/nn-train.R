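#' Weighted cross-entropy loss
#'
#' `L = -w_y * log softmax(logits)_y`, averaged over the batch with weight
#' normalization (divided by the sum of the per-example weights), so uniform
#' weights reduce exactly to the unweighted mean cross-entropy. Class
#' weighting is how the one-vs-all training counteracts the inevitable
#' imbalance of the "all" class.
#'
#' @param logits `2 x N` matrix of logits (column per example).
#' @param target Integer vector of class indices in `{1, 2}` (1 = negative,
#'   2 = positive).
#' @param weights Length-2 positive class weights.
#' @param gradient Also return the gradient with respect to the logits.
#' @return The scalar loss; with `gradient = TRUE`, a list `(loss, dlogits)`.
#' @export
weighted_cross_entropy <- function(logits, target, weights = c(1, 1), gradient = FALSE) {
  if (!all(is.finite(logits))) abort("non-finite logits")
  if (any(weights <= 0)) abort("class weights must be positive")
  logits <- as.matrix(logits)
  n <- ncol(logits)
  p <- softmax_cols(logits)
  wy <- weights[target]
  picked <- p[cbind(target, seq_len(n))]
  loss <- sum(wy * -log(pmax(picked, 1e-300))) / sum(wy)
  if (!gradient) return(loss)
  onehot <- matrix(0, nrow(logits), n)
  onehot[cbind(target, seq_len(n))] <- 1
  dlogits <- sweep(p - onehot, 2, wy / sum(wy), "*")
  list(loss = loss, dlogits = dlogits)
}

#' Inverse-frequency class weights
#'
#' `w_c = n_total / (2 * n_c)` for the binary problem; the minority class is
#' up-weighted in proportion to its rarity. The expected weight over the
#' samples is 1 by construction, so the loss scale is unchanged.
#'
#' @param targets Integer (1/2), logical, or factor targets; both classes
#'   must be present.
#' @return Length-2 numeric weights `(negative, positive)`.
#' @examples
#' default_class_weights(c(1, 1, 1, 2)) # minority positive up-weighted
#' @export
default_class_weights <- function(targets) {
  t <- as.integer(as.factor(targets))
  n <- c(sum(t == 1L), sum(t == 2L))
  if (any(n == 0L)) abort("both classes must be present to compute class weights")
  sum(n) / (2 * n)
}

#' Learning rate at a given epoch
#'
#' The backbone rate starts at `base_lr` and drops by `lr_drop_factor` every
#' `lr_drop_every` epochs; the fully connected head always runs at
#' `head_lr_multiplier` times the backbone rate (fast head, slow pre-trained
#' backbone).
#'
#' @param config A [train_config()].
#' @param epoch 1-based epoch number.
#' @param layer_group `"backbone"` or `"head"`.
#' @return The learning rate.
#' @examples
#' lr_at_epoch(train_config(), 1) # 1e-3
#' lr_at_epoch(train_config(), 16) # 1e-4
#' lr_at_epoch(train_config(), 1, "head") # 1e-2
#' @export
lr_at_epoch <- function(config, epoch, layer_group = c("backbone", "head")) {
  layer_group <- match.arg(layer_group)
  if (epoch < 1) abort("epoch must be >= 1")
  lr <- config$base_lr * config$lr_drop_factor^((epoch - 1) %/% config$lr_drop_every)
  if (layer_group == "head") lr <- lr * config$head_lr_multiplier
  lr
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
  list(
    m = purrr::map(params, zero_like),
    v = purrr::map(params, zero_like),
    t = 0L
  )
}

# one Adam step; lr per parameter via lr_of(name); L2 added to the gradient
# of conv/FC weights only (not biases or BN parameters)
adam_step <- function(params, grads, state, lr_of, l2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    pname <- grad_to_param(nm)
    g <- grads[[nm]]
    if (is_weight_param(pname)) g <- g + l2 * params[[pname]]
    state$m[[pname]] <- beta1 * state$m[[pname]] + (1 - beta1) * g
    state$v[[pname]] <- beta2 * state$v[[pname]] + (1 - beta2) * g^2
    mhat <- state$m[[pname]] / (1 - beta1^t)
    vhat <- state$v[[pname]] / (1 - beta2^t)
    params[[pname]] <- params[[pname]] - lr_of(pname) * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# conv/projection/FC weights get the L2 penalty; biases and BN do not
is_weight_param <- function(name) grepl("^(conv|proj|fc)", name) && !grepl("_b$", name)

grad_to_param <- function(name) name

# gradients for BN arrive named bnX_g / bnX_b; fold them into a parameter
# list view so Adam treats every tensor uniformly
flatten_model_params <- function(model) {
  p <- model$params
  for (nm in names(model$bn)) {
    p[[paste0(nm, "_g")]] <- model$bn[[nm]]$gamma
    p[[paste0(nm, "_b")]] <- model$bn[[nm]]$beta
  }
  p
}

unflatten_model_params <- function(model, p) {
  for (nm in names(model$params)) model$params[[nm]] <- p[[nm]]
  for (nm in names(model$bn)) {
    model$bn[[nm]]$gamma <- as.numeric(p[[paste0(nm, "_g")]])
    model$bn[[nm]]$beta <- as.numeric(p[[paste0(nm, "_b")]])
  }
  model
}

# ---- data assembly and augmentation --------------------------------------

#' Load manifest patches into a network-ready array
#'
#' Reads each patch PNG and resizes it bilinearly to `input_size`.
#'
#' @param paths Patch image paths.
#' @param input_size Square side for the network input.
#' @return `input_size x input_size x 3 x N` array.
#' @export
load_patch_array <- function(paths, input_size) {
  n <- length(paths)
  x <- array(0, c(input_size, input_size, 3L, n))
  for (i in seq_len(n)) {
    img <- read_patch(paths[i])
    if (dim(img)[1] != input_size || dim(img)[2] != input_size) {
      img <- cpp_bilinear_resize(img, as.integer(input_size), as.integer(input_size))
    }
    x[, , , i] <- img
  }
  x
}

# random rotation / translation / flips for one (H,W,3) image; white fill
# matches the slide background
augment_image <- function(img, config) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (runif(1) < config$aug_flip) img <- img[h:1, , , drop = FALSE]
  if (runif(1) < config$aug_flip) img <- img[, w:1, , drop = FALSE]
  ang <- runif(1, -config$aug_rotate, config$aug_rotate)
  tx <- runif(1, -config$aug_translate, config$aug_translate) * w
  ty <- runif(1, -config$aug_translate, config$aug_translate) * h
  cpp_affine_warp(img, ang, tx, ty, 1.0)
}

augment_batch <- function(x, config) {
  for (i in seq_len(dim(x)[4])) {
    x[, , , i] <- augment_image(x[, , , i, drop = TRUE], config)
  }
  x
}

# ---- training loop -------------------------------------------------------

#' Train a binary CNN on in-memory arrays
#'
#' The full recipe: Adam with the stepped learning-rate schedule and 10x
#' head rate, weighted cross-entropy with (by default) inverse-frequency
#' class weights, L2 penalty on conv/FC weights, per-epoch augmentation of
#' the training set, and early stopping after `patience` consecutive epochs
#' of rising validation loss with restoration of the best-validation-loss
#' weights. Deterministic given `config$seed`.
#'
#' @param x_train,y_train Training array (`H x W x 3 x N`) and integer
#'   targets (1 = negative, 2 = positive).
#' @param x_val,y_val Validation array and targets (drive early stopping).
#' @param config A [train_config()].
#' @param model Optional starting model (default: fresh [build_model()]
#'   with `config$init`).
#' @return A `gleason_cnn_fit`: list with `model`, `history` (tibble of
#'   per-epoch losses and validation F1), `stop_epoch`, `stop_reason`,
#'   `class_weights`.
#' @export
train_binary_cnn <- function(x_train, y_train, x_val, y_val, config = train_config(),
                             model = NULL) {
  if (!any(y_train == 2L) || !any(y_train == 1L)) {
    abort("training set must contain positive and negative examples")
  }
  with_seed(config$seed, {
    if (is.null(model)) {
      model <- build_model(architecture_spec(), init = config$init,
                           pretrained_path = config$pretrained_path)
    }
    weights <- config$class_weights %||% default_class_weights(y_train)
    opt <- adam_init(flatten_model_params(model))
    n <- dim(x_train)[4]
    hist <- list()
    best_loss <- Inf
    best_model <- model
    rises <- 0L
    stop_reason <- "max_epochs"
    stop_epoch <- config$max_epochs
    prev_val <- Inf
    for (epoch in seq_len(config$max_epochs)) {
      lr_of <- function(pname) {
        lr_at_epoch(config, epoch, if (grepl("^fc", pname)) "head" else "backbone")
      }
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        ix <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- x_train[, , , ix, drop = FALSE]
        if (config$augment) xb <- augment_batch(xb, config)
        fw <- cnn_forward(model, xb, training = TRUE, cache = TRUE)
        model <- fw$model
        ce <- weighted_cross_entropy(fw$logits, y_train[ix], weights, gradient = TRUE)
        grads <- cnn_backward(model, fw$cache, ce$dlogits)
        st <- adam_step(flatten_model_params(model), grads, opt, lr_of, config$l2)
        opt <- st$state
        model <- unflatten_model_params(model, st$params)
        ep_loss <- ep_loss + ce$loss; nb <- nb + 1L
      }
      val <- evaluate_loss_f1(model, x_val, y_val, weights, config$batch_size)
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss / nb,
        val_loss = val$loss, val_f1 = val$f1,
        lr_backbone = lr_at_epoch(config, epoch, "backbone")
      )
      if (val$loss < best_loss) {
        best_loss <- val$loss
        best_model <- model
      }
      rises <- if (val$loss > prev_val) rises + 1L else 0L
      prev_val <- val$loss
      if (rises >= config$patience) {
        stop_reason <- "early_stop"
        stop_epoch <- epoch
        break
      }
      stop_epoch <- epoch
    }
    structure(
      list(
        model = best_model, history = dplyr::bind_rows(hist),
        stop_epoch = stop_epoch, stop_reason = stop_reason,
        class_weights = weights, config = config
      ),
      class = "gleason_cnn_fit"
    )
  })
}

evaluate_loss_f1 <- function(model, x, y, weights, batch_size) {
  n <- dim(x)[4]
  scores <- numeric(n); loss_sum <- 0; w_sum <- 0
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    logits <- cnn_forward(model, x[, , , ix, drop = FALSE], training = FALSE)$logits
    p <- softmax_cols(logits)
    scores[ix] <- p[2L, ]
    wy <- weights[y[ix]]
    picked <- p[cbind(y[ix], seq_along(ix))]
    loss_sum <- loss_sum + sum(wy * -log(pmax(picked, 1e-300)))
    w_sum <- w_sum + sum(wy)
  }
  pred <- as.integer(scores > 0.5) + 1L
  list(loss = loss_sum / w_sum, f1 = binary_f1(pred == 2L, y == 2L), scores = scores)
}

binary_f1 <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

#' Early-stopping epoch for a validation-loss trace
#'
#' Pure arithmetic of the stopping rule: training stops after the first
#' epoch at which the validation loss has risen (strictly, versus the
#' immediately preceding epoch) for `patience` consecutive epochs. Returns
#' `NA` if the trace never triggers.
#'
#' @param val_losses Numeric per-epoch validation losses.
#' @param patience Required consecutive rises.
#' @return The 1-based stopping epoch, or `NA`.
#' @examples
#' early_stop_epoch(c(5, 1:10), patience = 8) # rises from epoch 3; stops at 10
#' @export
early_stop_epoch <- function(val_losses, patience = 8L) {
  rises <- 0L
  for (e in seq_along(val_losses)) {
    if (e > 1L && val_losses[e] > val_losses[e - 1L]) rises <- rises + 1L else rises <- 0L
    if (rises >= patience) return(e)
  }
  NA_integer_
}

#' Train one one-vs-all sub-classifier from a manifest
#'
#' Derives binary targets for `grade` under the labelling policy, drops
#' excluded (sub-threshold cancer) patches, loads and resizes the patch
#' images, and runs [train_binary_cnn()] with the train/validation fold
#' split.
#'
#' @param manifest Manifest tibble (relabel columns are computed if absent).
#' @param grade `"G3"`, `"G4"` or `"G5"`.
#' @param policy A [label_policy()].
#' @param config A [train_config()].
#' @param train_folds,val_folds Fold names used for training and validation.
#' @return A `gleason_cnn_fit` (see [train_binary_cnn()]).
#' @export
train_sub_classifier <- function(manifest, grade, policy = label_policy(),
                                 config = train_config(),
                                 train_folds = c("Val1", "Val2", "Val3"),
                                 val_folds = "Val4") {
  bt <- binary_targets(manifest, policy, grade) %>%
    dplyr::filter(.data$target != "excluded")
  tr <- bt %>% dplyr::filter(.data$fold %in% train_folds)
  va <- bt %>% dplyr::filter(.data$fold %in% val_folds)
  if (!nrow(tr) || !any(tr$target == "positive")) {
    abort(paste0("no positive training patches for ", grade))
  }
  if (!nrow(va)) abort("empty validation fold")
  x_tr <- load_patch_array(tr$patch_path, config$input_size)
  x_va <- load_patch_array(va$patch_path, config$input_size)
  y_tr <- as.integer(tr$target == "positive") + 1L
  y_va <- as.integer(va$target == "positive") + 1L
  fit <- train_binary_cnn(x_tr, y_tr, x_va, y_va, config)
  fit$grade <- grade
  fit
}

#' @rdname train_binary_cnn
#' @param x A `gleason_cnn_fit`.
#' @param ... Unused.
#' @export
tidy.gleason_cnn_fit <- function(x, ...) x$history

#' @rdname train_binary_cnn
#' @param object A `gleason_cnn_fit`.
#' @export
glance.gleason_cnn_fit <- function(object, ...) {
  tibble::tibble(
    epochs = object$stop_epoch, stop_reason = object$stop_reason,
    best_val_loss = min(object$history$val_loss),
    final_val_f1 = object$history$val_f1[which.min(object$history$val_loss)]
  )
}

#' @export
print.gleason_cnn_fit <- function(x, ...) {
  cat("<gleason_cnn_fit>", x$grade %||% "", "stopped after", x$stop_epoch,
      "epochs (", x$stop_reason, "), best val loss",
      format(min(x$history$val_loss), digits = 4), "\n")
  invisible(x)
}

#' @rdname train_binary_cnn
#' @export
autoplot.gleason_cnn_fit <- function(object, ...) {
  d <- object$history %>%
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "series", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Training curves", y = "weighted cross-entropy") +
    ggplot2::theme_minimal()
}
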