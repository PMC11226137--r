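#' Labelling policy for mask-to-label conversion
#'
#' The policy governs how a pixel mask becomes a multi-label: a grade enters
#' the label set when its pixel count reaches
#' `max(min_count, floor(tau * N))`, where `N` is the denominator — all
#' patch pixels by default (for 512 x 512 patches and `tau = 0.01` this is
#' 2621 pixels), or only tissue (non-background) pixels when
#' `denominator = "tissue_pixels"`. `min_count = 1` guarantees that
#' `tau = 0` never admits a grade with zero pixels.
#'
#' @param tau Pixel-fraction threshold in `[0, 1]`; default 0.01 (1%).
#' @param denominator `"all_pixels"` or `"tissue_pixels"`.
#' @param min_count Minimum absolute pixel count, integer >= 1.
#' @return A `label_policy` list.
#' @examples
#' label_policy() # the default 1% policy
#' @export
label_policy <- function(tau = 0.01, denominator = c("all_pixels", "tissue_pixels"),
                         min_count = 1L) {
  denominator <- match.arg(denominator)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1) {
    abort("tau must be a single number in [0, 1]")
  }
  if (!is.numeric(min_count) || min_count < 1) abort("min_count must be >= 1")
  structure(
    list(tau = tau, denominator = denominator, min_count = as.integer(min_count)),
    class = "label_policy"
  )
}

#' Training configuration for a one-vs-all sub-classifier
#'
#' Defaults are the recipe the grading network was tuned with: Adam at a base
#' learning rate of 1e-3 dropped by a factor 0.1 every 15 epochs, a 10x
#' faster final fully-connected head (transfer-learning practice: pre-trained
#' backbone moves slowly, the fresh head adapts fast), L2 penalty 1e-2 on
#' conv/FC weights, up to 50 epochs with early stopping after 8 consecutive
#' epochs of rising validation loss, inverse-frequency class weights in the
#' cross-entropy, and train-time augmentation (resize, rotation, translation,
#' flips).
#'
#' @param base_lr Backbone learning rate (> 0).
#' @param lr_drop_factor Multiplicative drop applied every `lr_drop_every` epochs.
#' @param lr_drop_every Epoch period of the learning-rate drop.
#' @param head_lr_multiplier Learning-rate multiplier for the FC head.
#' @param max_epochs Maximum training epochs.
#' @param patience Consecutive rising-validation-loss epochs before stopping.
#' @param l2 L2 regularization factor on conv/FC weights.
#' @param class_weights Optional length-2 positive weights `(negative, positive)`;
#'   `NULL` means inverse-frequency weights computed from the training targets.
#' @param batch_size Minibatch size.
#' @param input_size Side of the square network input in pixels (patches are
#'   resized to this; 224 reproduces the published activation sizes).
#' @param augment Apply train-time augmentation.
#' @param aug_rotate Max rotation in degrees (uniform in +/- this).
#' @param aug_translate Max translation as a fraction of the input side.
#' @param aug_flip Probability of each of horizontal/vertical flip.
#' @param init `"random"` or `"pretrained"` (requires a cached weight file).
#' @param pretrained_path Optional RDS file with pretrained backbone weights.
#' @param seed RNG seed making training runs reproducible.
#' @return A `train_config` list.
#' @export
train_config <- function(base_lr = 1e-3, lr_drop_factor = 0.1, lr_drop_every = 15L,
                         head_lr_multiplier = 10, max_epochs = 50L, patience = 8L,
                         l2 = 1e-2, class_weights = NULL, batch_size = 16L,
                         input_size = 224L, augment = TRUE, aug_rotate = 15,
                         aug_translate = 0.1, aug_flip = 0.5,
                         init = c("random", "pretrained"), pretrained_path = NULL,
                         seed = 1L) {
  init <- match.arg(init)
  if (base_lr <= 0) abort("base_lr must be positive")
  if (lr_drop_factor <= 0 || lr_drop_factor > 1) abort("lr_drop_factor must be in (0, 1]")
  if (head_lr_multiplier <= 0) abort("head_lr_multiplier must be positive")
  if (max_epochs < 1) abort("max_epochs must be >= 1")
  if (patience < 1) abort("patience must be >= 1")
  if (l2 < 0) abort("l2 must be >= 0")
  if (!is.null(class_weights) && (length(class_weights) != 2L || any(class_weights <= 0))) {
    abort("class_weights must be two positive numbers")
  }
  if (input_size < 8) abort("input_size must be >= 8")
  structure(
    list(
      base_lr = base_lr, lr_drop_factor = lr_drop_factor,
      lr_drop_every = as.integer(lr_drop_every),
      head_lr_multiplier = head_lr_multiplier,
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      l2 = l2, class_weights = class_weights,
      batch_size = as.integer(batch_size), input_size = as.integer(input_size),
      augment = isTRUE(augment), aug_rotate = aug_rotate,
      aug_translate = aug_translate, aug_flip = aug_flip,
      init = init, pretrained_path = pretrained_path, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Full run configuration
#'
#' Bundles the labelling policy, training recipe, ensemble thresholds and
#' bookkeeping fields; every field defaults to the published value where one
#' exists. `load_config()` reads a YAML or JSON document, fills unspecified
#' fields from the defaults, and validates ranges; `save_config()` writes a
#' round-trippable YAML document.
#'
#' @param label_policy A [label_policy()].
#' @param tau_test Optional evaluation-time threshold; `NULL` means the
#'   training `tau` is reused.
#' @param train A [train_config()].
#' @param thresholds Optional named per-grade score thresholds in `[0, 1]`.
#' @param paths Optional named list of data paths.
#' @param seed Top-level RNG seed.
#' @return A `run_config` list.
#' @export
run_config <- function(label_policy = mlgleason::label_policy(), tau_test = NULL,
                       train = train_config(), thresholds = NULL,
                       paths = list(), seed = 1L) {
  if (!is.null(thresholds)) {
    if (any(thresholds < 0 | thresholds > 1)) abort("thresholds must lie in [0, 1]")
  }
  if (!is.null(tau_test) && (tau_test < 0 || tau_test > 1)) abort("tau_test must be in [0, 1]")
  structure(
    list(
      label_policy = label_policy, tau_test = tau_test, train = train,
      thresholds = thresholds, paths = paths, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration file.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  lp_args <- raw$label_policy %||% list()
  tr_args <- raw$train %||% list()
  known_lp <- names(formals(label_policy))
  known_tr <- names(formals(train_config))
  unknown <- c(setdiff(names(lp_args), known_lp), setdiff(names(tr_args), known_tr))
  if (length(unknown)) abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  lp <- do.call(label_policy, lp_args)
  tr <- do.call(train_config, tr_args)
  thr <- raw$thresholds
  if (!is.null(thr)) thr <- unlist(thr)
  run_config(
    label_policy = lp, tau_test = raw$tau_test, train = tr, thresholds = thr,
    paths = raw$paths %||% list(), seed = raw$seed %||% 1L
  )
}

#' @rdname run_config
#' @param config A `run_config` to serialize.
#' @export
save_config <- function(config, path) {
  out <- list(
    label_policy = unclass(config$label_policy),
    tau_test = config$tau_test,
    train = unclass(config$train),
    thresholds = as.list(config$thresholds),
    paths = config$paths,
    seed = config$seed
  )
  out$train$class_weights <- config$train$class_weights
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run a block with a locally pinned RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
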