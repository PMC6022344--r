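#' Binomial standard error of a grounding-accuracy proportion
#'
#' `sqrt((k/n) * (1 - k/n) / n)` — the standard error attached to each
#' per-category accuracy percentage, where `k` is the number of correctly
#' grounded samples in the category and `n` the number of samples in the
#' category.
#'
#' @param k number of correct samples, `0 <= k <= n`
#' @param n number of samples in the category, `n >= 1`
#' @return standard error as a fraction in `[0, 0.5/sqrt(n)]`
#' @export
#' @examples
#' round_half_up(100 * standard_error(37, 52), 1)  # 6.3
standard_error <- function(k, n) {
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("`k` must satisfy 0 <= k <= n", call. = FALSE)
  p <- k / n
  sqrt(p * (1 - p) / n)
}

#' Category accuracy table for a grounding evaluation
#'
#' Summarises a manually scored sample of named entities: for each entity
#' category (protein/gene, family/complex, small molecule, biological
#' process, microRNA, other/unknown) it reports the share of the overall
#' sample the category accounts for, the number and percentage of correctly
#' grounded entities, and the binomial standard error of that percentage.
#'
#' @param samples data.frame with columns `category` (character) and
#'   `correct` (logical), one row per scored entity
#' @return data.frame of class `famground_accuracy` with one row per
#'   category present (ordered by category count, descending): category,
#'   n_category, entity_pct, k_correct, correct_pct, se_pct.  Percentage
#'   columns are unrounded; the print method displays them rounded
#'   half-up to one decimal.
#' @export
#' @examples
#' s <- annotation_samples(c(family_complex = 52), c(family_complex = 37))
#' accuracy_table(s)
accuracy_table <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("category", "correct") %in% names(samples)),
            nrow(samples) > 0L, is.logical(samples$correct))
  total <- nrow(samples)
  cats <- names(sort(table(samples$category), decreasing = TRUE))
  rows <- lapply(cats, function(cat) {
    sub <- samples[samples$category == cat, , drop = FALSE]
    n <- nrow(sub)
    k <- sum(sub$correct)
    data.frame(
      category = cat,
      n_category = n,
      entity_pct = 100 * n / total,
      k_correct = k,
      correct_pct = 100 * k / n,
      se_pct = 100 * standard_error(k, n),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("famground_accuracy", class(out))
  out
}

#' @export
print.famground_accuracy <- function(x, ...) {
  disp <- data.frame(
    category = x$category,
    n = x$n_category,
    `entity%` = round_half_up(x$entity_pct, 1),
    correct = x$k_correct,
    `correct%` = sprintf("%.1f ± %.1f",
                         round_half_up(x$correct_pct, 1),
                         round_half_up(x$se_pct, 1)),
    check.names = FALSE
  )
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Build annotation samples from per-category counts
#'
#' Expands printed evaluation counts (category size and number correct) into
#' the per-sample form [accuracy_table()] consumes.
#'
#' @param n_by_category named integer vector: category -> sample count
#' @param k_by_category named integer vector: category -> correct count
#'   (categories absent default to 0)
#' @return data.frame with columns category, correct
#' @export
annotation_samples <- function(n_by_category, k_by_category = integer()) {
  stopifnot(!is.null(names(n_by_category)))
  rows <- lapply(names(n_by_category), function(cat) {
    n <- as.integer(n_by_category[[cat]])
    k <- as.integer(if (cat %in% names(k_by_category)) k_by_category[[cat]] else 0L)
    if (k > n) stop(sprintf("more correct than total for '%s'", cat), call. = FALSE)
    data.frame(category = rep(cat, n),
               correct = rep(c(TRUE, FALSE), c(k, n - k)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative occurrence curve of ungrounded strings
#'
#' Orders distinct strings by occurrence count (descending; ties broken
#' lexicographically) and accumulates their occurrence fractions, producing
#' the curve that shows how heavily missed groundings concentrate in a small
#' number of frequent strings.  A uniform count distribution puts the curve
#' on the diagonal.
#'
#' @param freqs named numeric vector: string -> occurrence count (>= 1)
#' @return data.frame with columns string, count, percentile (fraction of
#'   distinct strings up to and including this one) and cum_fraction
#'   (fraction of all occurrences covered); monotone, ending at 1
#' @export
cumulative_curve <- function(freqs) {
  if (length(freqs) == 0L) stop("`freqs` must be non-empty", call. = FALSE)
  if (is.null(names(freqs)) || any(!nzchar(names(freqs)))) {
    stop("`freqs` must be a named vector", call. = FALSE)
  }
  if (any(freqs < 1)) stop("occurrence counts must be >= 1", call. = FALSE)
  ord <- order(-freqs, names(freqs), method = "radix")
  counts <- as.numeric(freqs[ord])
  data.frame(
    string = names(freqs)[ord],
    count = counts,
    percentile = seq_along(counts) / length(counts),
    cum_fraction = cumsum(counts) / sum(counts),
    stringsAsFactors = FALSE
  )
}

#' Share of distinct strings covering a fraction of occurrences
#'
#' The smallest percentile of distinct strings (most frequent first) whose
#' cumulative occurrences reach `occurrence_fraction` of the total — e.g.
#' "half of all ungrounded occurrences involve the top X% of strings".
#'
#' @inheritParams cumulative_curve
#' @param occurrence_fraction target cumulative occurrence fraction in
#'   `(0, 1]`
#' @return the distinct-string percentile as a fraction in `(0, 1]`
#' @export
#' @examples
#' top_share(c(a = 10, b = 2, c = 2, d = 2, e = 2, f = 2), 0.5)  # 1/6
top_share <- function(freqs, occurrence_fraction) {
  stopifnot(is.numeric(occurrence_fraction), length(occurrence_fraction) == 1L,
            occurrence_fraction > 0, occurrence_fraction <= 1)
  curve <- cumulative_curve(freqs)
  curve$percentile[[which(curve$cum_fraction >= occurrence_fraction)[[1L]]]]
}

#' Event-level grounding coverage
#'
#' An extracted event is only useful downstream if its entities are
#' grounded.  Given one logical vector of per-entity grounded flags per
#' event, computes the proportions of events with at least one ungrounded
#' entity and with all entities ungrounded.
#'
#' @param events list of logical vectors; `TRUE` = entity grounded; each
#'   event must have at least one entity
#' @return list with n_events, n_any_ungrounded, n_all_ungrounded,
#'   prop_any_ungrounded, prop_all_ungrounded
#' @export
#' @examples
#' event_coverage(list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE)))
event_coverage <- function(events) {
  stopifnot(is.list(events), length(events) > 0L)
  if (any(lengths(events) == 0L)) {
    stop("every event must have at least one entity flag", call. = FALSE)
  }
  any_un <- vapply(events, function(e) any(!e), logical(1))
  all_un <- vapply(events, function(e) all(!e), logical(1))
  n <- length(events)
  list(
    n_events = n,
    n_any_ungrounded = sum(any_un),
    n_all_ungrounded = sum(all_un),
    prop_any_ungrounded = sum(any_un) / n,
    prop_all_ungrounded = sum(all_un) / n
  )
}

#' Distribution of grounding levels within a sub-hierarchy
#'
#' For a multi-level family/complex, classifies each observed grounding as
#' gene-level, intermediate-level or top-level relative to the named
#' top-level entry (see [grounding_level()]) and returns the fractions.
#'
#' @param groundings character vector of grounded node references (bare
#'   identifiers resolve in the resource namespace)
#' @param graph a [hierarchy_graph()]
#' @param top_entry the top-level entry anchoring the sub-hierarchy
#' @return named numeric vector `c(gene =, intermediate =, top =)` summing
#'   to 1
#' @export
level_distribution <- function(groundings, graph, top_entry) {
  stopifnot(length(groundings) > 0L)
  lev <- vapply(groundings, function(g) grounding_level(graph, g, top_entry),
                character(1))
  counts <- table(factor(lev, levels = c("gene", "intermediate", "top")))
  as.numeric(counts) / length(lev) -> frac
  stats::setNames(frac, names(counts))
}

#' Coverage percentage from evaluation counts
#'
#' Simple helper for recall-style coverage arithmetic on annotation subsets:
#' the percentage of scored annotations matched, after excluding a number of
#' out-of-scope annotations from the denominator.
#'
#' @param n_matched annotations matched
#' @param n_total annotations scored before exclusions
#' @param n_excluded annotations removed from the denominator (e.g.
#'   out-of-scope entity types)
#' @return percentage in `[0, 100]` (unrounded)
#' @export
#' @examples
#' coverage_pct(1908, 2439, 51)  # 79.9 (to one decimal)
coverage_pct <- function(n_matched, n_total, n_excluded = 0) {
  denom <- n_total - n_excluded
  if (denom <= 0) stop("denominator must be positive", call. = FALSE)
  if (n_matched > denom) stop("matched exceeds denominator", call. = FALSE)
  100 * n_matched / denom
}
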