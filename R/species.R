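# Species pool and the global species abundance distribution (GSAD).
#
# Each species is a strict habitat specialist: it reproduces only in its
# preferred habitat type. The GSAD is the regional relative-abundance vector
# governing which species immigrants from outside the landscape belong to;
# the landscape is also initialized by sampling it.

#' Build the species pool
#'
#' `n_species` habitat specialists, the first half preferring habitat A and
#' the second half habitat B. Assignment is deterministic by species index;
#' preference labels are exchangeable, so nothing is lost and reproducibility
#' is gained.
#'
#' @param n_species even number of species (default 40, i.e. 20 per habitat).
#' @return tibble with columns `species_id`, `preferred_habitat` ("A"/"B").
#' @examples
#' build_species_pool(4)
#' @export
build_species_pool <- function(n_species = 40L) {
  if (length(n_species) != 1L || n_species < 2L || n_species %% 2L != 0L) {
    stop("`n_species` must be an even integer >= 2, got ", n_species)
  }
  n_species <- as.integer(n_species)
  tibble::tibble(
    species_id = seq_len(n_species),
    preferred_habitat = rep(c("A", "B"), each = n_species %/% 2L)
  )
}

#' Draw a lognormal GSAD
#'
#' Relative regional abundances: `n_species` iid lognormal draws normalized
#' to sum to one. The lognormal shape gives the usual few-common /
#' many-rare structure, so relative abundances span several orders of
#' magnitude at the default `sdlog = 1`.
#'
#' @param n_species number of species.
#' @param meanlog,sdlog lognormal parameters on the log scale (`sdlog > 0`).
#' @return a `gsad`: numeric weight vector summing to 1, with attributes
#'   `meanlog` and `sdlog`.
#' @export
draw_gsad <- function(n_species = 40L, meanlog = 0, sdlog = 1) {
  if (sdlog <= 0) stop("`sdlog` must be > 0, got ", sdlog)
  w <- rlnorm(n_species, meanlog, sdlog)
  w <- w / sum(w)
  structure(w, meanlog = meanlog, sdlog = sdlog, class = "gsad")
}

#' @export
print.gsad <- function(x, ...) {
  cat("<gsad> ", length(x), " species, lognormal(meanlog = ",
      attr(x, "meanlog"), ", sdlog = ", attr(x, "sdlog"),
      "), max/min weight ratio = ", round(max(x) / min(x), 1), "\n", sep = "")
  invisible(x)
}

#' Sample species identities from a GSAD
#'
#' @param gsad a `gsad` weight vector.
#' @param k number of iid categorical draws (`k >= 0`).
#' @return integer vector of `k` species ids.
#' @export
sample_species <- function(gsad, k) {
  if (k < 0) stop("`k` must be >= 0")
  if (k == 0) return(integer(0))
  sample.int(length(gsad), size = k, replace = TRUE, prob = as.numeric(gsad))
}

#' Species table for export
#'
#' @param pool species pool tibble from [build_species_pool()].
#' @param gsad matching `gsad`.
#' @return tibble `species_id`, `preferred_habitat`, `gsad_weight`.
#' @export
species_table <- function(pool, gsad) {
  stopifnot(nrow(pool) == length(gsad))
  dplyr::mutate(pool, gsad_weight = as.numeric(gsad))
}
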