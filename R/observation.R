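# Imperfect detection overlay.
#
# Surveys detect each individual present independently with probability p
# (species- and habitat-independent), so an observed abundance is a binomial
# thinning of the true abundance and the chance of detecting a species with
# n individuals at all is 1 - (1 - p)^n.

#' Binomial thinning of a true abundance
#'
#' @param n true count(s), nonnegative integers (vectorized).
#' @param p per-individual detection probability in \[0, 1\].
#' @return observed count(s), `Binomial(n, p)`.
#' @export
observe_abundance <- function(n, p) {
  stopifnot(all(n >= 0), p >= 0, p <= 1)
  rbinom(length(n), size = n, prob = p)
}

#' Probability of detecting a species at least once
#'
#' With `n` individuals present and per-individual detection probability `p`,
#' the species goes undetected only if every individual is missed, so the
#' species-level detection probability is `1 - (1 - p)^n`.
#'
#' @inheritParams observe_abundance
#' @return probability in \[0, 1\] (vectorized over `n`).
#' @examples
#' species_detection_prob(10, 0.1) # ~0.651
#' @export
species_detection_prob <- function(n, p) {
  stopifnot(all(n >= 0), all(p >= 0), all(p <= 1))
  1 - (1 - p)^n
}

#' Temporal occupancy of each species under imperfect detection
#'
#' Applies the detection overlay to the focal cell's true abundance series: a
#' species is detected in a year iff its binomially thinned abundance is at
#' least 1. Occupancy is the fraction of the `W`-year window with a
#' detection. Species never detected in the window yield no record — an
#' observer has no datum for them, just as an empirical survey cannot tabulate
#' species it never saw; this matters for error-rate denominators.
#'
#' Relative abundance is the species' landscape-wide abundance at the final
#' step as a percentage of the most abundant species'. A species observed in
#' the window but landscape-extinct by the final census gets `NA` (no
#' meaningful log-abundance); such records are rare and are dropped by the
#' abundance GLM.
#'
#' Detection is an overlay: several detection levels can be laid over one
#' simulation, mirroring repeated virtual surveys of the same truth. Draws at
#' different `p` are independent.
#'
#' @param record a `ct_simulation`.
#' @param p per-individual detection probability.
#' @return tibble with one row per detected species: `species_id`,
#'   `true_status` ("core"/"transient" by habitat match with the focal cell),
#'   `detected_years`, `occupancy`, `landscape_abundance`,
#'   `relative_abundance` (percent of the most abundant species).
#' @export
occupancy_from_record <- function(record, p) {
  stopifnot(inherits(record, "ct_simulation"), p >= 0, p <= 1)
  tr <- record$focal_abundance
  obs <- matrix(rbinom(length(tr), size = as.vector(tr), prob = p),
                nrow(tr), ncol(tr))
  detected_all <- colSums(obs >= 1L)
  seen <- which(detected_all > 0L)
  dy <- as.integer(detected_all[seen])
  land <- record$landscape_abundance
  rel <- ifelse(land > 0L, 100 * land / max(land), NA_real_)
  tibble::tibble(
    species_id = seen,
    true_status = true_status(seen, record$pool, record$focal_habitat),
    detected_years = dy,
    occupancy = dy / nrow(tr),
    landscape_abundance = land[seen],
    relative_abundance = rel[seen]
  )
}
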