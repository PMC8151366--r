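#' Intensity-of-pesticide-use index
#'
#' For each orchard the index sums, over all pesticides applied, the number of
#' applications weighted by the product's toxicity to bees on a 1 (low) to 3
#' (highly toxic) scale: \eqn{\sum_i T_i \times A_i}. An unsprayed orchard
#' (no entries) scores 0.
#'
#' @param toxicity Integer vector of toxicity levels, each in \{1, 2, 3\}.
#' @param applications Integer vector of application counts (>= 1), same
#'   length as `toxicity`.
#' @return The index (non-negative number).
#' @export
#' @examples
#' compute_intensity(c(3, 2, 1), c(10, 5, 9))  # 49
compute_intensity <- function(toxicity, applications) {
  if (length(toxicity) != length(applications))
    stop_input("'toxicity' and 'applications' must have equal length")
  if (length(toxicity) == 0L) return(0)
  if (!all(toxicity %in% c(1, 2, 3)))
    stop_input("toxicity levels must be 1, 2 or 3")
  if (any(applications < 1 | applications != round(applications)))
    stop_input("application counts must be positive integers")
  sum(toxicity * applications)
}

#' Classify pesticide-use intensity as low or high
#'
#' Orchards are split into a binary pesticide-use covariate at an index
#' threshold chosen to balance the two classes (default 48.5, so an index of
#' 48 is "low" and 49 is "high").
#'
#' @param index Numeric vector of non-negative intensity indices.
#' @param threshold Split point; indices `<= threshold` are "low".
#' @return Character vector, `"low"` or `"high"`.
#' @export
#' @examples
#' classify_intensity(c(48, 49))
classify_intensity <- function(index, threshold = 48.5) {
  if (any(!is.finite(index)) || any(index < 0))
    stop_input("'index' must be finite and non-negative")
  ifelse(index <= threshold, "low", "high")
}

#' Per-orchard pesticide index from a registry table
#'
#' @param registry Data frame with columns `orchard_id`, `toxicity`,
#'   `applications` (one row per pesticide applied; orchards absent from the
#'   table but listed in `orchards` score 0).
#' @param orchards Optional vector of orchard ids fixing the output order and
#'   including unsprayed orchards.
#' @param threshold Passed to [classify_intensity()].
#' @return Data frame with `orchard_id`, `index`, `class`.
#' @export
pesticide_index_table <- function(registry, orchards = unique(registry$orchard_id),
                                  threshold = 48.5) {
  for (col in c("orchard_id", "toxicity", "applications"))
    if (is.null(registry[[col]])) stop_input("registry lacks column '", col, "'")
  idx <- vapply(orchards, function(o) {
    rows <- registry$orchard_id == o
    compute_intensity(registry$toxicity[rows], registry$applications[rows])
  }, numeric(1))
  data.frame(orchard_id = orchards, index = idx,
             class = classify_intensity(idx, threshold),
             stringsAsFactors = FALSE)
}

#' Published orchard characteristics of the 12-orchard study design
#'
#' The per-orchard intensity-of-pesticide-use indices and landscape
#' enhancement status of the twelve southern-Quebec apple orchards the
#' analyses are designed around. Useful as a reference design for the
#' pesticide classifier and the synthetic generator.
#'
#' @return Data frame with `orchard`, `region`, `enhancement` (0/1) and
#'   `pesticide_index`.
#' @export
orchard_design <- function() {
  data.frame(
    orchard = 1:12,
    region = rep(c("Estrie", "Monteregie"), each = 6),
    enhancement = c(0, 1, 1, 1, 0, 0, 1, 1, 0, 0, 0, 1),
    pesticide_index = c(23, 13, 27, 51, 48, 49, 109, 32, 70, 54, 52, 48)
  )
}
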