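# Landscape generation and the local-similarity metric.
#
# A landscape is a binary raster of two habitat types, A and B. All
# demographic rules key off the match between a species' preferred habitat
# and the habitat of the cell it occupies. Internally habitat A is stored as
# 1L and habitat B as 0L in an integer matrix indexed (row, col), 1-based.

#' Generate a two-habitat landscape
#'
#' Each cell is labelled habitat A independently with probability `h_A`,
#' otherwise habitat B. How habitat is arranged spatially is a modelling
#' choice: independent Bernoulli draws are the default because the downstream
#' analyses use realized landscape similarity around the focal cell as a
#' continuous predictor, which iid generation varies naturally across
#' replicates at fixed `h_A`. A different arrangement can be supplied through
#' `generator`.
#'
#' @param width,height grid dimensions in cells (default 32 x 32).
#' @param h_A proportion of the landscape expected to be habitat A, in
#'   \[0, 1\].
#' @param generator either `"iid"` or a function `(width, height, h_A)`
#'   returning an integer matrix of 0/1 labels (1 = habitat A) with `height`
#'   rows and `width` columns, for plugging in e.g. spatially autocorrelated
#'   generators without touching downstream code.
#' @return a `habitat_grid`: an integer matrix (1 = habitat A, 0 = habitat B)
#'   with attribute `h_A`.
#' @examples
#' set.seed(1)
#' g <- generate_landscape(32, 32, h_A = 0.9)
#' mean(g == 1L) # realized proportion of habitat A
#' @export
generate_landscape <- function(width = 32L, height = 32L, h_A,
                               generator = "iid") {
  if (length(h_A) != 1L || is.na(h_A) || h_A < 0 || h_A > 1) {
    stop("`h_A` must be a single proportion in [0, 1], got ", format(h_A))
  }
  if (width < 1L || height < 1L) {
    stop("grid dimensions must be positive (got ", width, " x ", height, ")")
  }
  if (is.function(generator)) {
    hab <- generator(width, height, h_A)
    stopifnot(is.matrix(hab), nrow(hab) == height, ncol(hab) == width,
              all(hab %in% c(0L, 1L)))
    hab <- matrix(as.integer(hab), height, width)
  } else {
    hab <- matrix(as.integer(runif(width * height) < h_A), height, width)
  }
  structure(hab, h_A = h_A, class = c("habitat_grid", class(hab)))
}

#' @export
print.habitat_grid <- function(x, ...) {
  cat("<habitat_grid> ", nrow(x), " x ", ncol(x),
      ", target h_A = ", attr(x, "h_A"),
      ", realized = ", round(mean(x == 1L), 3), "\n", sep = "")
  invisible(x)
}

#' Habitat label of one or more cells
#'
#' @param grid a `habitat_grid`.
#' @param cell matrix or vector of (row, col) 1-based coordinates.
#' @return character vector of `"A"` / `"B"`.
#' @export
habitat_at <- function(grid, cell) {
  cell <- matrix(as.integer(cell), ncol = 2L)
  ifelse(grid[cell] == 1L, "A", "B")
}

#' Central focal cell of a grid
#'
#' The focal cell is the deterministic centre of the grid: index
#' `floor((n - 1) / 2)` per axis in 0-based terms, i.e. on an even-sized axis
#' the upper-left of the two central candidates. On a 32 x 32 grid this is
#' (16, 16) in the package's 1-based convention. The grid must be at least
#' `window` x `window` so the similarity window fits around the focal cell.
#'
#' @param grid a `habitat_grid`.
#' @param window width of the similarity window the focal cell must admit
#'   (odd, default 7).
#' @return integer vector `c(row, col)`, 1-based.
#' @export
focal_cell <- function(grid, window = 7L) {
  if (nrow(grid) < window || ncol(grid) < window) {
    stop("grid (", nrow(grid), " x ", ncol(grid), ") is too small for a ",
         window, " x ", window, " regional window")
  }
  focus <- c(floor((nrow(grid) - 1L) / 2), floor((ncol(grid) - 1L) / 2)) + 1L
  half <- (window - 1L) %/% 2L
  if (focus[1] - half < 1L || focus[1] + half > nrow(grid) ||
      focus[2] - half < 1L || focus[2] + half > ncol(grid)) {
    stop("similarity window does not fit around the central cell")
  }
  as.integer(focus)
}

#' Local landscape similarity around a focal cell
#'
#' The proportion of the `window` x `window` block centred on `focus` that
#' shares the focal cell's habitat type, the focal cell itself included (so
#' the minimum is `1 / window^2` and a homogeneous window scores 1).
#'
#' @param grid a `habitat_grid`.
#' @param focus `c(row, col)` 1-based; defaults to [focal_cell()].
#' @param window odd window width in cells (default 7).
#' @return similarity in \[0, 1\].
#' @export
local_similarity <- function(grid, focus = focal_cell(grid, window),
                             window = 7L) {
  if (window %% 2L != 1L || window < 1L) stop("`window` must be odd and positive")
  half <- (window - 1L) %/% 2L
  rows <- (focus[1] - half):(focus[1] + half)
  cols <- (focus[2] - half):(focus[2] + half)
  if (min(rows) < 1L || max(rows) > nrow(grid) ||
      min(cols) < 1L || max(cols) > ncol(grid)) {
    stop("similarity window extends past the grid edge")
  }
  block <- grid[rows, cols]
  mean(block == grid[focus[1], focus[2]])
}

#' Write / read a landscape as plain CSV
#'
#' One row per grid row, cells 0/1 with 1 = habitat A; headerless.
#'
#' @param grid a `habitat_grid`.
#' @param path file path.
#' @export
write_landscape <- function(grid, path) {
  utils::write.table(unclass(grid), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @param h_A target proportion to record on the restored grid (the realized
#'   proportion is used when omitted).
#' @export
read_landscape <- function(path, h_A = NULL) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  stopifnot(all(m %in% c(0L, 1L)))
  structure(m, h_A = if (is.null(h_A)) mean(m == 1L) else h_A,
            class = c("habitat_grid", class(m)))
}
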