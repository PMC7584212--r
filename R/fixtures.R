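# Deterministic small-scale scenarios for fast testing and exploration.

#' Build a named small-scale fixture
#'
#' Millisecond-scale scenarios exercising every stage of the pipeline without
#' a full run. Available fixtures:
#' \describe{
#'   \item{`tiny`}{4 x 4 iid landscape (h_A = 0.5), 4 species, K = 5,
#'     narrow kernel (q99 = 1.5), 10-step runs with a 5-step window.}
#'   \item{`homogeneous`}{8 x 8 all habitat A.}
#'   \item{`checkerboard`}{8 x 8 alternating habitat; window similarities are
#'     hand-countable (25/49 for a 7 x 7 window).}
#'   \item{`two_block`}{8 x 8 split into a left A block and right B block,
#'     for source-sink scenarios.}
#' }
#' Regeneration from the same `(name, seed)` is bit-identical; fixtures are
#' always built in code, never stored.
#'
#' @param name one of `"tiny"`, `"homogeneous"`, `"checkerboard"`,
#'   `"two_block"`.
#' @param seed integer seed used for the GSAD (and the `tiny` landscape).
#' @return list with `name`, `grid`, `pool`, `gsad`, `config`, `seed`.
#' @export
make_fixture <- function(name, seed = 42L) {
  valid <- c("tiny", "homogeneous", "checkerboard", "two_block")
  if (!name %in% valid) {
    stop("unknown fixture `", name, "`; valid names: ",
         paste(valid, collapse = ", "))
  }
  set.seed(seed)
  as_grid <- function(m, h_A) {
    structure(m, h_A = h_A, class = c("habitat_grid", class(m)))
  }
  if (name == "tiny") {
    grid <- generate_landscape(4L, 4L, h_A = 0.5)
    config <- sim_config(width = 4L, height = 4L, h_A = 0.5, n_species = 4L,
                         K = 5L, q99 = 1.5, n_steps = 10L, W = 5L,
                         seed = seed)
  } else {
    m <- switch(name,
      homogeneous = matrix(1L, 8L, 8L),
      checkerboard = outer(0:7, 0:7, function(r, c) as.integer((r + c) %% 2L == 0L)),
      two_block = cbind(matrix(1L, 8L, 4L), matrix(0L, 8L, 4L))
    )
    grid <- as_grid(m, mean(m == 1L))
    config <- sim_config(width = 8L, height = 8L, h_A = attr(grid, "h_A"),
                         n_species = 4L, K = 10L, q99 = 2, n_steps = 20L,
                         W = 5L, seed = seed)
  }
  pool <- build_species_pool(config$n_species)
  gsad <- draw_gsad(config$n_species, config$meanlog, config$sdlog)
  list(name = name, grid = grid, pool = pool, gsad = gsad, config = config,
       seed = seed)
}
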