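# Literal per-individual reference implementation of one time step.
# Deliberately naive (explicit loops over individuals, propagules and slots)
# and independent of the package's vectorized engine: it is the oracle the
# engine is checked against distributionally on small instances.

ref_round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

ref_step <- function(state, grid, pool, gsad, config) {
  nr <- nrow(grid); nc <- ncol(grid)
  n_cells <- nr * nc
  S <- nrow(pool)
  sigma <- config$q99 / qnorm(0.995)
  cell_habitat <- ifelse(as.vector(grid) == 1L, "A", "B")

  # flatten to individuals
  ind_cell <- integer(0); ind_sp <- integer(0)
  for (cell in seq_len(n_cells)) {
    for (sp in seq_len(S)) {
      k <- state[cell, sp]
      if (k > 0) {
        ind_cell <- c(ind_cell, rep(cell, k))
        ind_sp <- c(ind_sp, rep(sp, k))
      }
    }
  }

  # death
  keep <- logical(length(ind_cell))
  for (i in seq_along(ind_cell)) keep[i] <- runif(1) >= config$d
  ind_cell <- ind_cell[keep]; ind_sp <- ind_sp[keep]

  matched <- cell_habitat[ind_cell] == pool$preferred_habitat[ind_sp]

  # birth: f propagules per matched adult, at the natal cell
  prop_cell <- integer(0); prop_sp <- integer(0)
  for (i in seq_along(ind_cell)) {
    if (matched[i]) {
      prop_cell <- c(prop_cell, rep(ind_cell[i], config$f))
      prop_sp <- c(prop_sp, rep(ind_sp[i], config$f))
    }
  }

  # mismatched adults leave and join the dispersal pool
  prop_cell <- c(prop_cell, ind_cell[!matched])
  prop_sp <- c(prop_sp, ind_sp[!matched])
  ind_cell <- ind_cell[matched]; ind_sp <- ind_sp[matched]

  # dispersal, one propagule at a time; absorbing boundary
  arr_cell <- integer(0); arr_sp <- integer(0)
  for (i in seq_along(prop_cell)) {
    r <- abs(rnorm(1, 0, sigma))
    th <- runif(1, 0, 2 * pi)
    row <- (prop_cell[i] - 1L) %% nr + 1L + ref_round_away(r * sin(th))
    col <- (prop_cell[i] - 1L) %/% nr + 1L + ref_round_away(r * cos(th))
    if (row >= 1 && row <= nr && col >= 1 && col <= nc) {
      arr_cell <- c(arr_cell, row + (col - 1L) * nr)
      arr_sp <- c(arr_sp, prop_sp[i])
    }
  }

  # establishment, one empty slot at a time
  counts <- matrix(0L, n_cells, S)
  for (i in seq_along(ind_cell)) {
    counts[ind_cell[i], ind_sp[i]] <- counts[ind_cell[i], ind_sp[i]] + 1L
  }
  for (cell in seq_len(n_cells)) {
    pool_here <- which(arr_cell == cell)
    taken <- rep(FALSE, length(pool_here))
    for (slot in seq_len(config$K - sum(counts[cell, ]))) {
      if (runif(1) < config$m) {
        sp <- sample.int(S, 1L, prob = as.numeric(gsad))
        counts[cell, sp] <- counts[cell, sp] + 1L
      } else if (any(!taken)) {
        j <- if (sum(!taken) == 1L) which(!taken) else sample(which(!taken), 1L)
        taken[j] <- TRUE
        sp <- arr_sp[pool_here[j]]
        counts[cell, sp] <- counts[cell, sp] + 1L
      }
    }
  }
  counts
}

# minimal hand-built simulation record for observation/classification tests
fake_record <- function(focal_abundance, landscape_abundance, pool,
                        focal_habitat = "A") {
  structure(list(
    focal_abundance = focal_abundance,
    landscape_abundance = landscape_abundance,
    pool = pool, gsad = NULL, grid = NULL,
    focal = c(1L, 1L), focal_habitat = focal_habitat, similarity = NA_real_,
    config = sim_config(W = nrow(focal_abundance),
                        n_steps = nrow(focal_abundance),
                        n_species = nrow(pool))
  ), class = "ct_simulation")
}
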