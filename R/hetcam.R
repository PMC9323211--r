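#' HET-CAM irritation score from onset times
#'
#' Computes the continuous irritation score of the hen's-egg
#' chorioallantoic-membrane (HET-CAM) assay from the onset times (seconds) of
#' the three endpoint reactions observed during the 300 s window:
#'
#' `IS = 5*(301 - h)/300 + 7*(301 - l)/300 + 9*(301 - c)/300`
#'
#' where `h`, `l`, `c` are the onset times of hemorrhage, lysis/hyperemia and
#' coagulation. A reaction not observed within the window is encoded as
#' `301 s`, which makes its contribution exactly zero; an immediate reaction
#' at 1 s yields the scale maximum of 21.
#'
#' @param hemorrhage_s,lysis_s,coagulation_s Onset times in seconds, each in
#'   `[1, 301]`. Vectorised and recycled to a common length.
#' @return Irritation score(s) in `[0, 21]`.
#' @examples
#' irritation_score(1, 1, 1)       # 21, strongest possible reaction
#' irritation_score(301, 301, 301) # 0, nothing observed
#' @seealso [classify_irritation()], [score_hetcam()]
#' @export
irritation_score <- function(hemorrhage_s, lysis_s, coagulation_s) {
  onsets <- vctrs_recycle(hemorrhage_s, lysis_s, coagulation_s)
  for (o in onsets) {
    if (!is.numeric(o) || any(!is.finite(o)) || any(o < 1) || any(o > 301)) {
      abort("Onset times must lie in [1, 301] seconds (301 = not observed).",
            class = "ocurel_domain_error")
    }
  }
  5 * (301 - onsets[[1]]) / 300 +
    7 * (301 - onsets[[2]]) / 300 +
    9 * (301 - onsets[[3]]) / 300
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, rep_len, length.out = n)
}

hetcam_categories <- c("non-irritant", "less irritant",
                       "moderate irritant", "severe irritant")

#' Irritation category from a HET-CAM score
#'
#' Maps a continuous irritation score to the standard HET-CAM category
#' scale. The printed ranges (0-0.9 non-irritant, 1.0-4.9 less irritant,
#' 5.0-8.9 moderate irritant, 9.0-21.0 severe irritant) leave small gaps
#' between categories; these are closed with half-open intervals
#' `[0,1) [1,5) [5,9) [9,21]` so every score in `[0, 21]` gets a category
#' and the printed lower bounds are preserved as left endpoints.
#'
#' @param score Numeric score(s) in `[0, 21]`.
#' @return A factor with levels `non-irritant < less irritant <
#'   moderate irritant < severe irritant`.
#' @examples
#' classify_irritation(c(0.07, 3, 5, 21))
#' @export
classify_irritation <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score)) ||
      any(score < 0) || any(score > 21)) {
    abort("`score` must lie in [0, 21].", class = "ocurel_domain_error")
  }
  cut(score, breaks = c(0, 1, 5, 9, 21), labels = hetcam_categories,
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Score a table of HET-CAM observations
#'
#' Appends the continuous irritation score and its category to a table of
#' onset times with columns `h_s`, `l_s`, `c_s` (hemorrhage, lysis/hyperemia,
#' coagulation onsets in seconds, 301 = not observed).
#'
#' @param observations A data frame with columns `h_s`, `l_s`, `c_s`; any
#'   other columns (e.g. `sample`) are carried through.
#' @return The input as a tibble with `score` and `category` columns added.
#' @examples
#' obs <- tibble::tibble(sample = c("neg", "pos"),
#'                       h_s = c(301, 5), l_s = c(301, 8), c_s = c(301, 12))
#' score_hetcam(obs)
#' @export
score_hetcam <- function(observations) {
  observations <- as_tibble(observations)
  needed <- c("h_s", "l_s", "c_s")
  if (!all(needed %in% names(observations))) {
    abort("`observations` needs columns h_s, l_s, c_s.",
          class = "ocurel_format_error")
  }
  dplyr::mutate(
    observations,
    score = irritation_score(.data$h_s, .data$l_s, .data$c_s),
    category = classify_irritation(.data$score)
  )
}

#' Discrete window score for a single HET-CAM effect
#'
#' The tabulated (discrete) variant of HET-CAM scoring assigns integer
#' points by which observation window the effect first appeared in:
#' within 0.5 min, within 2 min, or within 5 min. Lysis/hyperemia scores
#' 5/3/1, hemorrhage 7/5/3 and coagulation 9/7/5 over those windows; an
#' effect outside the 5 min window scores 0. The continuous
#' [irritation_score()] is the authoritative quantity for classification;
#' this discrete form is provided for comparison with scored tables.
#'
#' @param effect One of `"lysis"`, `"hemorrhage"`, `"coagulation"`
#'   (`"hyperemia"` is accepted as a synonym for `"lysis"`).
#' @param onset_s Onset time(s) in seconds, `>= 1`.
#' @return Integer score(s).
#' @examples
#' discrete_window_score("hemorrhage", 20) # 7
#' discrete_window_score("lysis", 120)     # 3
#' @export
discrete_window_score <- function(effect, onset_s) {
  effect <- match.arg(effect, c("lysis", "hyperemia", "hemorrhage",
                                "coagulation"))
  if (!is.numeric(onset_s) || any(!is.finite(onset_s)) || any(onset_s < 1)) {
    abort("`onset_s` must be >= 1 second.", class = "ocurel_domain_error")
  }
  pts <- switch(effect,
    lysis = ,
    hyperemia = c(5L, 3L, 1L),
    hemorrhage = c(7L, 5L, 3L),
    coagulation = c(9L, 7L, 5L)
  )
  dplyr::case_when(
    onset_s <= 30 ~ pts[[1]],
    onset_s <= 120 ~ pts[[2]],
    onset_s <= 300 ~ pts[[3]],
    TRUE ~ 0L
  )
}
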