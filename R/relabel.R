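#' Pixel counts per grade code
#'
#' @param mask Integer matrix of grade codes.
#' @return Named integer vector of counts over `BG, NC, G3, G4, G5`;
#'   counts always sum to the number of pixels.
#' @export
grade_pixel_counts <- function(mask) {
  gc <- grade_codes()
  counts <- tabulate(as.integer(mask) + 1L, nbins = length(gc))
  setNames(as.integer(counts), names(gc))
}

policy_denominator <- function(counts, policy) {
  if (policy$denominator == "all_pixels") sum(counts) else sum(counts) - counts[["BG"]]
}

#' Majority-vote patch label
#'
#' The conventional single label: the Gleason grade occupying the most
#' pixels, `NC` when no grade pixels exist at all. Background pixels never
#' vote. Ties between grades break toward the higher (more aggressive)
#' grade — the clinically conservative choice.
#'
#' @param mask Integer matrix of grade codes.
#' @return A single grade code (`NC`, `G3`, `G4` or `G5`).
#' @examples
#' m <- matrix(c(3L, 3L, 3L, 2L, 2L, 1L), 2, 3)
#' grade_name(majority_label(m)) # "G4"
#' @export
majority_label <- function(mask) {
  counts <- grade_pixel_counts(mask)
  if (sum(counts) == counts[["BG"]]) abort("mask contains no tissue (all background)")
  g <- counts[gleason_grades()]
  if (all(g == 0L)) return(grade_code("NC"))
  # which.max on the reversed vector prefers the higher grade on ties
  win <- names(g)[length(g) + 1L - which.max(rev(g))]
  grade_code(win)
}

# effective pixel-count threshold for a policy and denominator size
policy_count_threshold <- function(policy, n) {
  max(policy$min_count, floor(policy$tau * n))
}

#' Threshold-based multi-label for a patch
#'
#' A grade is included whenever its pixel count reaches
#' `max(min_count, floor(tau * N))` (`N` from the policy denominator). The
#' `NC` flag is issued only if the patch contains zero pixels of G3, G4 and
#' G5. A patch with some grade pixels but none above threshold gets an empty
#' label set with `nc = FALSE`: it is ambiguous and flagged `excluded` by
#' [binary_targets()] and [relabel_manifest()].
#'
#' @param mask Integer matrix of grade codes.
#' @param policy A [label_policy()].
#' @return A `multilabel` object: list with `grades` (character subset of
#'   G3/G4/G5) and `nc` (logical).
#' @examples
#' m <- matrix(1L, 64, 64); m[1:40, 1:60] <- 3L
#' multilabel_from_mask(m, label_policy())
#' @export
multilabel_from_mask <- function(mask, policy = label_policy()) {
  counts <- grade_pixel_counts(mask)
  if (sum(counts) == counts[["BG"]]) abort("mask contains no tissue (all background)")
  n <- policy_denominator(counts, policy)
  thr <- policy_count_threshold(policy, n)
  g <- counts[gleason_grades()]
  grades <- names(g)[g >= thr]
  new_multilabel(grades, nc = all(g == 0L))
}

new_multilabel <- function(grades, nc) {
  stopifnot(!nc || length(grades) == 0L)
  structure(list(grades = grades, nc = nc), class = "multilabel")
}

#' @export
print.multilabel <- function(x, ...) {
  lab <- if (x$nc) "NC" else if (length(x$grades)) paste(x$grades, collapse = "+") else "(none; excluded)"
  cat("<multilabel>", lab, "\n")
  invisible(x)
}

#' @export
format.multilabel <- function(x, ...) {
  if (x$nc) "NC" else if (length(x$grades)) paste(x$grades, collapse = "+") else ""
}

#' Off-majority (misclassified) pixel fractions
#'
#' For a patch whose majority-vote label is `m`, every pixel of another
#' grade is a pixel the single-label convention misclassifies. This returns
#' the area fraction of each grade other than `m` (0 for absent grades),
#' with the fraction denominator taken from the policy.
#'
#' @inheritParams multilabel_from_mask
#' @return Named numeric vector over the grades other than the majority
#'   label (all three when the majority label is `NC`).
#' @export
misclassified_fractions <- function(mask, policy = label_policy()) {
  counts <- grade_pixel_counts(mask)
  if (sum(counts) == counts[["BG"]]) abort("mask contains no tissue (all background)")
  m <- grade_name(majority_label(mask))
  n <- policy_denominator(counts, policy)
  others <- setdiff(gleason_grades(), m)
  setNames(as.numeric(counts[others]) / n, others)
}

#' Relabel a whole manifest
#'
#' Reads every mask and appends the multi-label columns `g3`, `g4`, `g5`,
#' `nc` and `excluded` (0/1) plus the majority-vote label, turning a
#' majority-vote dataset into a multi-label one.
#'
#' @param manifest Manifest tibble (see [load_manifest()]).
#' @param policy A [label_policy()].
#' @return The manifest with label columns appended.
#' @export
relabel_manifest <- function(manifest, policy = label_policy()) {
  labs <- purrr::map(manifest$mask_path, function(p) {
    mask <- read_mask(p)
    ml <- multilabel_from_mask(mask, policy)
    tibble::tibble(
      g3 = as.integer("G3" %in% ml$grades),
      g4 = as.integer("G4" %in% ml$grades),
      g5 = as.integer("G5" %in% ml$grades),
      nc = as.integer(ml$nc),
      excluded = as.integer(!ml$nc && length(ml$grades) == 0L),
      majority = grade_name(majority_label(mask))
    )
  })
  dplyr::bind_cols(manifest, dplyr::bind_rows(labs))
}

#' Audit the label noise induced by majority voting
#'
#' Aggregates [misclassified_fractions()] over all patches, per fold and per
#' grade: the mean and maximum off-majority area fraction, the number of
#' contributing patches, and a histogram of the fractions (1-percentage-point
#' bins) for distribution plots. With `population = "present"` (default) the
#' mean/max are taken over patches where the grade occurs off-majority
#' (fraction > 0); `"all"` averages over every patch in the fold.
#'
#' @param manifest Manifest tibble.
#' @param policy A [label_policy()].
#' @param population `"present"` or `"all"`.
#' @return An `inconsistency_report`: list with `summary` (tibble
#'   fold x class: `mean_frac`, `max_frac`, `n`) and `histogram` (tibble
#'   fold x class x bin with counts).
#' @export
inconsistency_report <- function(manifest, policy = label_policy(),
                                 population = c("present", "all")) {
  population <- match.arg(population)
  if (nrow(manifest) == 0L) abort("empty manifest")
  fr <- purrr::map2_dfr(manifest$mask_path, manifest$fold, function(p, fold) {
    f <- misclassified_fractions(read_mask(p), policy)
    tibble::tibble(fold = fold, class = names(f), frac = unname(f))
  })
  # grades the majority label absorbs never appear as off-majority rows;
  # absent grades appear with frac = 0 and are dropped under "present"
  summary <- fr %>%
    dplyr::group_by(.data$fold, .data$class) %>%
    dplyr::summarise(
      mean_frac = if (population == "present") {
        if (any(.data$frac > 0)) mean(.data$frac[.data$frac > 0]) else 0
      } else {
        mean(.data$frac)
      },
      max_frac = max(.data$frac, 0),
      n = if (population == "present") sum(.data$frac > 0) else dplyr::n(),
      .groups = "drop"
    ) %>%
    tidyr::complete(
      fold = unique(manifest$fold), class = gleason_grades(),
      fill = list(mean_frac = 0, max_frac = 0, n = 0L)
    )
  hist <- fr %>%
    dplyr::filter(.data$frac > 0) %>%
    dplyr::mutate(bin = floor(.data$frac * 100) / 100) %>%
    dplyr::count(.data$fold, .data$class, .data$bin, name = "count")
  structure(
    list(summary = summary, histogram = hist, policy = policy, population = population),
    class = "inconsistency_report"
  )
}

#' @export
print.inconsistency_report <- function(x, ...) {
  cat("Majority-vote label inconsistency audit (", x$population, " population)\n", sep = "")
  s <- x$summary %>%
    dplyr::mutate(
      mean_pct = round(.data$mean_frac * 100, 1),
      max_pct = round(.data$max_frac * 100, 1)
    )
  print(as.data.frame(s[, c("fold", "class", "mean_pct", "max_pct", "n")]), row.names = FALSE)
  invisible(x)
}

#' @rdname inconsistency_report
#' @param x An `inconsistency_report`.
#' @param ... Unused.
#' @export
tidy.inconsistency_report <- function(x, ...) x$summary

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname inconsistency_report
#' @param object An `inconsistency_report`.
#' @export
autoplot.inconsistency_report <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(width = 0.008, fill = "steelblue") +
    ggplot2::facet_grid(class ~ fold, scales = "free_y") +
    ggplot2::labs(
      x = "off-majority pixel area fraction", y = "patches",
      title = "Misclassified-pixel distributions under majority voting"
    ) +
    ggplot2::theme_minimal()
}

#' One-vs-all binary targets for a grade
#'
#' Maps multi-labels to the training target of the `grade` sub-classifier:
#' `positive` when the grade is in the label set; `negative` when the patch
#' is NC or carries only other grades at/above threshold; `excluded` when
#' the label set is empty but the patch is not NC (sub-threshold cancer —
#' unlabelable under the joint NC/threshold rule, so it is kept out of
#' training rather than injected as noise).
#'
#' @param manifest Manifest tibble; if the relabel columns (`g3`,`g4`,`g5`,
#'   `nc`,`excluded`) are absent, masks are read and relabelled on the fly.
#' @param policy A [label_policy()].
#' @param grade `"G3"`, `"G4"` or `"G5"`.
#' @return The manifest with a `target` column
#'   (factor: positive/negative/excluded).
#' @export
binary_targets <- function(manifest, policy = label_policy(), grade) {
  if (!grade %in% gleason_grades()) abort("grade must be one of G3, G4, G5")
  if (!all(c("g3", "g4", "g5", "nc", "excluded") %in% names(manifest))) {
    manifest <- relabel_manifest(manifest, policy)
  }
  col <- tolower(grade)
  manifest %>%
    dplyr::mutate(
      target = factor(
        dplyr::case_when(
          .data[[col]] == 1L ~ "positive",
          .data$excluded == 1L ~ "excluded",
          TRUE ~ "negative"
        ),
        levels = c("negative", "positive", "excluded")
      )
    )
}
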