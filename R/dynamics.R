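# The demographic engine.
#
# State representation: a community state is an integer matrix with one row
# per grid cell (column-major cell index: row + (col - 1) * nrow) and one
# column per species, holding counts of established individuals. Individuals
# are exchangeable within a (cell, species) pair, so counts carry the full
# per-individual semantics; propagule pools use the same representation.
#
# A time step applies, in order: death -> birth -> adult dispersal out of
# non-preferred habitat -> dispersal of the pooled propagules -> establishment
# into empty slots. Consequences of that order are deliberate: individuals
# dying this step do not reproduce this step, and adult dispersers compete
# for slots exactly like newborn propagules and die if unplaced.

#' Half-normal dispersal kernel from its 99th percentile
#'
#' Dispersal distance is the absolute value of a zero-mean Gaussian. The
#' kernel is parameterized by the distance below which 99% of movements fall:
#' `sigma = q99 / qnorm(0.995)` and the mean distance is
#' `sigma * sqrt(2 / pi)`. The default `q99 = 4` grid cells gives a mean of
#' ~1.24 cells; `q99 = 2` and `q99 = 8` are the narrow and broad variants.
#'
#' @param q99 99th percentile of dispersal distance, in grid cells (> 0).
#' @return a `dispersal_kernel` list with `sigma`, `mean`, `q99`.
#' @examples
#' kernel_from_q99(4)$mean # ~1.24 grid cells
#' @export
kernel_from_q99 <- function(q99 = 4) {
  if (length(q99) != 1L || is.na(q99) || q99 <= 0) {
    stop("`q99` must be a single positive distance, got ", format(q99))
  }
  sigma <- q99 / qnorm(0.995)
  structure(list(sigma = sigma, mean = sigma * sqrt(2 / pi), q99 = q99),
            class = "dispersal_kernel")
}

#' @export
print.dispersal_kernel <- function(x, ...) {
  cat("<dispersal_kernel> half-normal, sigma = ", signif(x$sigma, 5),
      ", mean = ", signif(x$mean, 4), ", q99 = ", x$q99, " cells\n", sep = "")
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles every knob of one simulation run. Defaults are the standard study
#' conditions: a 32 x 32 lattice of communities capped at `K = 100`
#' individuals, 40 habitat specialists (20 per habitat), per-step mortality
#' 0.5, two offspring per matched adult, per-empty-slot immigration
#' probability 0.001 from a lognormal GSAD, half-normal dispersal with 99% of
#' movements within 4 cells, 200 steps of burn-in-plus-dynamics with the last
#' 15 steps forming the occupancy window.
#'
#' @param width,height grid dimensions.
#' @param h_A proportion of habitat A.
#' @param n_species even species-pool size.
#' @param K per-cell carrying capacity (hard cap).
#' @param d per-individual, per-step mortality probability.
#' @param f offspring per adult in its preferred habitat per step.
#' @param m per-empty-slot probability that an establishment event is an
#'   immigrant from the regional pool rather than a local propagule.
#' @param q99 dispersal kernel 99th percentile, grid cells.
#' @param n_steps total time steps `T`.
#' @param W occupancy window: the last `W` steps are recorded (`W <= T`).
#' @param meanlog,sdlog lognormal GSAD parameters.
#' @param seed integer seed making the run reproducible; `NULL` to use the
#'   ambient RNG state.
#' @return a `ct_config` list.
#' @export
sim_config <- function(width = 32L, height = 32L, h_A = 0.5, n_species = 40L,
                       K = 100L, d = 0.5, f = 2L, m = 0.001, q99 = 4,
                       n_steps = 200L, W = 15L, meanlog = 0, sdlog = 1,
                       seed = NULL) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              h_A = h_A, n_species = as.integer(n_species), K = as.integer(K),
              d = d, f = as.integer(f), m = m, q99 = q99,
              n_steps = as.integer(n_steps), W = as.integer(W),
              meanlog = meanlog, sdlog = sdlog, seed = seed)
  for (p in c("h_A", "d", "m")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop("`", p, "` must be in [0, 1]")
  }
  if (cfg$K < 1L || cfg$n_steps < 1L || cfg$W < 1L || cfg$f < 0L) {
    stop("K, n_steps, W must be positive and f nonnegative")
  }
  if (cfg$W > cfg$n_steps) stop("`W` must not exceed `n_steps`")
  structure(cfg, class = "ct_config")
}

# cells x species logical matrix: TRUE where the cell's habitat matches the
# species' preference
habitat_match <- function(grid, pool) {
  a_cell <- as.vector(grid == 1L)
  outer(a_cell, pool$preferred_habitat == "A", "==")
}

new_community_state <- function(counts, grid) {
  structure(counts, grid_dim = dim(grid), class = "community_state")
}

#' Fill the landscape to carrying capacity from the GSAD
#'
#' Every cell starts with exactly `K` individuals drawn iid from the GSAD,
#' irrespective of habitat match; sorting by habitat suitability is left to
#' the dynamics.
#'
#' @param grid a `habitat_grid`.
#' @param gsad a `gsad`.
#' @param K per-cell carrying capacity.
#' @return a `community_state`: cells x species count matrix.
#' @export
initialize_communities <- function(grid, gsad, K = 100L) {
  n_cells <- length(grid)
  S <- length(gsad)
  draws <- sample_species(gsad, n_cells * K)
  cell <- rep(seq_len(n_cells), each = K)
  counts <- matrix(tabulate(cell + (draws - 1L) * n_cells, nbins = n_cells * S),
                   n_cells, S)
  new_community_state(counts, grid)
}

#' @export
print.community_state <- function(x, ...) {
  gd <- attr(x, "grid_dim")
  cat("<community_state> ", gd[1], " x ", gd[2], " cells, ", ncol(x),
      " species, ", sum(x), " individuals\n", sep = "")
  invisible(x)
}

#' Apply one round of density-independent mortality
#'
#' Each established individual dies independently with probability `d`,
#' regardless of habitat.
#'
#' @param state a `community_state`.
#' @param d mortality probability in \[0, 1\].
#' @return the thinned `community_state`.
#' @export
apply_mortality <- function(state, d) {
  stopifnot(d >= 0, d <= 1)
  surv <- state
  surv[] <- rbinom(length(state), size = as.vector(state), prob = 1 - d)
  surv
}

#' Offspring production in preferred habitat
#'
#' Adults in their preferred habitat each produce `f` propagules at their
#' natal cell; adults in non-preferred habitat produce none.
#'
#' @param state a `community_state`.
#' @param pool species pool tibble.
#' @param grid the `habitat_grid` the state lives on.
#' @param f offspring per matched adult.
#' @return cells x species count matrix of propagules at natal cells.
#' @export
produce_propagules <- function(state, pool, grid, f = 2L) {
  stopifnot(f >= 0)
  unclass(state) * habitat_match(grid, pool) * f
}

#' Remove mismatched adults into the dispersal pool
#'
#' Established adults disperse only when stranded in non-preferred habitat:
#' all of them leave their cell and join the propagule pool for this step,
#' competing for establishment slots at their destination and dying if
#' unplaced.
#'
#' @inheritParams produce_propagules
#' @return list of `state` (matched adults only) and `dispersers`
#'   (cells x species counts at natal cells).
#' @export
collect_adult_dispersers <- function(state, pool, grid) {
  match <- habitat_match(grid, pool)
  dispersers <- unclass(state) * !match
  kept <- state
  kept[] <- unclass(state) * match
  list(state = kept, dispersers = dispersers)
}

#' Disperse a propagule pool across the grid
#'
#' Each propagule draws an angle uniform on \[0, 2*pi) and a distance from
#' the half-normal kernel; the continuous displacement is added to the natal
#' cell's centre and snapped to the nearest cell per axis
#' (round-half-away-from-zero). The boundary is absorbing: propagules landing
#' off-grid are lost (the outside world is represented explicitly by GSAD
#' immigration, so wrapping would double-count it).
#'
#' @param pool cells x species count matrix of propagules at natal cells
#'   (offspring and adult dispersers pooled).
#' @param kernel a `dispersal_kernel`.
#' @param grid the `habitat_grid` (for dimensions).
#' @return cells x species count matrix of arrivals.
#' @export
disperse <- function(pool, kernel, grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  n_cells <- nr * nc
  S <- ncol(pool)
  nz <- which(pool > 0)
  if (length(nz) == 0L) return(matrix(0L, n_cells, S))
  id <- rep.int(nz, pool[nz])
  cell <- (id - 1L) %% n_cells + 1L
  sp <- (id - 1L) %/% n_cells + 1L
  row <- (cell - 1L) %% nr + 1L
  col <- (cell - 1L) %/% nr + 1L
  n <- length(id)
  r <- abs(rnorm(n, 0, kernel$sigma))
  theta <- runif(n, 0, 2 * pi)
  drow <- row + round_away(r * sin(theta))
  dcol <- col + round_away(r * cos(theta))
  keep <- drow >= 1 & drow <= nr & dcol >= 1 & dcol <= nc
  idx <- drow[keep] + (dcol[keep] - 1) * nr + (sp[keep] - 1) * n_cells
  matrix(tabulate(idx, nbins = n_cells * S), n_cells, S)
}

#' Establishment into empty slots
#'
#' Each empty slot (capacity `K` minus current occupancy) in each cell is
#' processed independently: with probability `m` it is filled by an immigrant
#' sampled from the GSAD; otherwise by an individual drawn uniformly without
#' replacement from the cell's arrival pool, the slot staying empty once the
#' pool is exhausted. Arrivals left over are destroyed. The
#' without-replacement draw over a pool held as per-species counts is a
#' multivariate hypergeometric, realized species-by-species with vectorized
#' [stats::rhyper()] across cells.
#'
#' @param state a `community_state` at or below capacity.
#' @param arrivals cells x species count matrix of dispersal arrivals.
#' @param gsad a `gsad` (immigrant identities).
#' @param m per-slot immigration probability.
#' @param K carrying capacity.
#' @return the updated `community_state`.
#' @export
establish <- function(state, arrivals, gsad, m = 0.001, K = 100L) {
  n_cells <- nrow(state)
  S <- ncol(state)
  occ <- rowSums(state)
  if (any(occ > K)) {
    stop("internal consistency failure: occupancy above K before establishment")
  }
  vac <- K - occ
  counts <- unclass(state)

  n_imm <- rbinom(n_cells, size = vac, prob = m)
  tot_imm <- sum(n_imm)
  if (tot_imm > 0L) {
    sp <- sample_species(gsad, tot_imm)
    cell <- rep.int(seq_len(n_cells), n_imm)
    counts <- counts + matrix(
      tabulate(cell + (sp - 1L) * n_cells, nbins = n_cells * S), n_cells, S)
  }

  pool_tot <- rowSums(arrivals)
  rem <- pmin(vac - n_imm, pool_tot)   # slots to fill from the local pool
  rest <- pool_tot
  for (j in seq_len(S)) {
    mj <- arrivals[, j]
    rest <- rest - mj
    xj <- rhyper(n_cells, m = mj, n = rest, k = rem)
    counts[, j] <- counts[, j] + xj
    rem <- rem - xj
  }
  state[] <- counts
  state
}

#' Advance a community state by one time step
#'
#' Death, then birth, then dispersal (newborn propagules pooled with adults
#' leaving non-preferred habitat), then establishment. After every step each
#' cell is at or below `K` and no propagule survives.
#'
#' @param state a `community_state`.
#' @param grid,pool,gsad landscape, species pool, GSAD.
#' @param config a `ct_config`.
#' @param kernel optional precomputed `dispersal_kernel` (defaults to
#'   `kernel_from_q99(config$q99)`).
#' @param match optional precomputed habitat-match matrix.
#' @return the next `community_state`.
#' @export
step_community <- function(state, grid, pool, gsad, config,
                           kernel = kernel_from_q99(config$q99),
                           match = habitat_match(grid, pool)) {
  state <- apply_mortality(state, config$d)
  prop <- unclass(state) * match * config$f
  dispersers <- unclass(state) * !match
  state[] <- unclass(state) * match
  arrivals <- disperse(prop + dispersers, kernel, grid)
  establish(state, arrivals, gsad, m = config$m, K = config$K)
}

#' Run one full simulation
#'
#' Generates a landscape, species pool and GSAD from the config, fills the
#' landscape to capacity, advances `n_steps` time steps, and records the
#' focal cell's per-species abundance over the last `W` steps plus
#' landscape-wide abundances at the final step.
#'
#' @param config a `ct_config`; `config$seed`, when non-`NULL`, makes the run
#'   fully reproducible.
#' @return a `ct_simulation` list: `focal_abundance` (W x species integer
#'   matrix, row sums <= K), `landscape_abundance` (per-species totals at the
#'   final step), `grid`, `pool`, `gsad`, `focal` (row, col), `focal_habitat`,
#'   `similarity`, `config`.
#' @examples
#' \donttest{
#' rec <- run_simulation(sim_config(h_A = 0.9, n_steps = 40, seed = 1))
#' rec$similarity
#' }
#' @export
run_simulation <- function(config = sim_config()) {
  stopifnot(inherits(config, "ct_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  grid <- generate_landscape(config$width, config$height, config$h_A)
  pool <- build_species_pool(config$n_species)
  gsad <- draw_gsad(config$n_species, config$meanlog, config$sdlog)
  focus <- focal_cell(grid)
  sim <- local({
    kernel <- kernel_from_q99(config$q99)
    match <- habitat_match(grid, pool)
    state <- initialize_communities(grid, gsad, config$K)
    focal_idx <- focus[1] + (focus[2] - 1L) * nrow(grid)
    rec <- matrix(0L, config$W, config$n_species)
    first_rec <- config$n_steps - config$W + 1L
    for (t in seq_len(config$n_steps)) {
      state <- step_community(state, grid, pool, gsad, config, kernel, match)
      if (t >= first_rec) rec[t - first_rec + 1L, ] <- state[focal_idx, ]
    }
    list(rec = rec, final = colSums(state))
  })
  structure(list(
    focal_abundance = sim$rec,
    landscape_abundance = as.integer(sim$final),
    grid = grid, pool = pool, gsad = gsad,
    focal = focus,
    focal_habitat = habitat_at(grid, matrix(focus, ncol = 2L)),
    similarity = local_similarity(grid, focus),
    config = config
  ), class = "ct_simulation")
}

#' @export
print.ct_simulation <- function(x, ...) {
  cat("<ct_simulation> h_A = ", x$config$h_A,
      ", focal habitat ", x$focal_habitat,
      ", similarity = ", round(x$similarity, 3),
      ", ", x$config$W, "-step window, ",
      sum(colSums(x$focal_abundance) > 0), "/", x$config$n_species,
      " species ever present at focus\n", sep = "")
  invisible(x)
}

#' @method tidy ct_simulation
#' @export
tidy.ct_simulation <- function(x, ...) {
  W <- nrow(x$focal_abundance)
  tibble::tibble(
    year = rep(seq_len(W), times = ncol(x$focal_abundance)),
    species_id = rep(seq_len(ncol(x$focal_abundance)), each = W),
    true_abundance = as.integer(x$focal_abundance)
  )
}

#' @method glance ct_simulation
#' @export
glance.ct_simulation <- function(x, ...) {
  tibble::tibble(
    h_A = x$config$h_A, q99 = x$config$q99,
    focal_habitat = x$focal_habitat, similarity = x$similarity,
    n_steps = x$config$n_steps, W = x$config$W,
    n_species_present = sum(colSums(x$focal_abundance) > 0),
    mean_focal_occupancy_n = mean(rowSums(x$focal_abundance))
  )
}

#' Serialize a simulation record to plain-text files
#'
#' Writes `focal_occupancy.csv` (year, species_id, true_abundance),
#' `landscape_abundance.csv` (species_id, preferred_habitat,
#' landscape_abundance) and `run_metadata.json` (config, focal cell in the
#' 1-based (row, col) convention, habitat, similarity) under `dir`.
#'
#' @param record a `ct_simulation`.
#' @param dir output directory (created if needed).
#' @export
write_simulation_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(tidy(record), file.path(dir, "focal_occupancy.csv"))
  readr::write_csv(
    dplyr::mutate(record$pool,
                  landscape_abundance = record$landscape_abundance),
    file.path(dir, "landscape_abundance.csv"))
  jsonlite::write_json(
    list(config = unclass(record$config),
         coordinate_convention = "1-based (row, col), row 1 at top",
         focal = record$focal, focal_habitat = record$focal_habitat,
         similarity = record$similarity),
    file.path(dir, "run_metadata.json"), auto_unbox = TRUE, null = "null",
    digits = NA)
  invisible(dir)
}
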