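# Occupancy-threshold classification and the confusion table.
#
# True status is biological: a species whose preferred habitat matches the
# focal cell can sustain a population there (core, net reproductive rate
# >= 1); a mismatched species cannot (transient) and persists at the focus
# only through dispersal. Inferred status comes from temporal occupancy
# thresholds; the four-way cross of true by inferred status gives the
# confusion counts and the two error rates.

#' Infer core/transient status from detected years
#'
#' With a `W`-year window, species detected in at most `floor(W / 3)` years
#' are inferred transient and species detected in more than `floor(2 W / 3)`
#' years inferred core; the rest are intermediate and excluded from
#' error-rate tallies. For the standard 15-year window that is <= 5 years
#' transient, >= 11 years core, 6-10 intermediate: the thresholds follow the
#' year counts, of which the usual "33% / 66%" quoting is a rounding.
#'
#' @param detected_years number of years with a detection (vectorized),
#'   each in `0..W`.
#' @param W window length in years.
#' @param low_frac,high_frac occupancy fractions defining the thresholds
#'   (`low_frac < high_frac`); counts at or below `floor(low_frac * W)` are
#'   transient, counts above `floor(high_frac * W)` core.
#' @return character vector in `c("transient", "intermediate", "core")`.
#' @export
infer_status <- function(detected_years, W = 15L, low_frac = 1 / 3,
                         high_frac = 2 / 3) {
  stopifnot(low_frac < high_frac)
  if (any(detected_years < 0L | detected_years > W)) {
    stop("`detected_years` must lie in 0..W")
  }
  lo <- floor(low_frac * W)
  hi <- floor(high_frac * W)
  dplyr::case_when(
    detected_years <= lo ~ "transient",
    detected_years > hi ~ "core",
    .default = "intermediate"
  )
}

#' True (biological) status relative to a focal habitat
#'
#' @param species_id species id(s), present in `pool`.
#' @param pool species pool tibble.
#' @param focal_habitat `"A"` or `"B"`: the habitat of the focal cell.
#' @return `"core"` where the species' preferred habitat matches the focal
#'   habitat, else `"transient"`.
#' @export
true_status <- function(species_id, pool, focal_habitat) {
  if (any(!species_id %in% pool$species_id)) {
    stop("unknown species id(s): ",
         paste(setdiff(species_id, pool$species_id), collapse = ", "))
  }
  pref <- pool$preferred_habitat[match(species_id, pool$species_id)]
  ifelse(pref == focal_habitat, "core", "transient")
}

#' Confusion table and error rates for one run at one detection level
#'
#' Crosses true against inferred status over the occupancy records of one
#' (run, detection level) pair. Counts follow the usual 2 x 2 layout:
#' `A` true core inferred transient, `B` true transient inferred transient,
#' `C` true core inferred core, `D` true transient inferred core. The core
#' error rate is `A / (A + C)` (core species mistaken for transients) and
#' the transient error rate `D / (B + D)` (transients mistaken for core).
#' Intermediate-occupancy species are excluded from the counts and reported
#' in `n_intermediate`; an error rate whose denominator is zero is `NA`, not
#' zero — silently zero-filling would bias downstream regressions.
#'
#' @param occ occupancy tibble from [occupancy_from_record()].
#' @param W window length used for the thresholds.
#' @param low_frac,high_frac threshold fractions, as in [infer_status()].
#' @return one-row tibble: `n_obs_core`, `n_obs_transient` (distinct observed
#'   species by true status, intermediates included), `A`, `B`, `C`, `D`,
#'   `n_intermediate`, `core_error`, `transient_error`.
#' @export
tabulate_confusion <- function(occ, W = 15L, low_frac = 1 / 3,
                               high_frac = 2 / 3) {
  inferred <- infer_status(occ$detected_years, W, low_frac, high_frac)
  A <- sum(occ$true_status == "core" & inferred == "transient")
  B <- sum(occ$true_status == "transient" & inferred == "transient")
  C <- sum(occ$true_status == "core" & inferred == "core")
  D <- sum(occ$true_status == "transient" & inferred == "core")
  tibble::tibble(
    n_obs_core = sum(occ$true_status == "core"),
    n_obs_transient = sum(occ$true_status == "transient"),
    A = A, B = B, C = C, D = D,
    n_intermediate = sum(inferred == "intermediate"),
    core_error = if (A + C > 0) A / (A + C) else NA_real_,
    transient_error = if (B + D > 0) D / (B + D) else NA_real_
  )
}
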