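# ggplot2 views of the main result types.

#' Heatmap of a sweep response over detection and landscape similarity
#'
#' Mean of the chosen response within cells of the detection-by-similarity
#' plane (similarity binned to the 1/49 resolution of the 7 x 7 window,
#' coarsened to `bins`).
#'
#' @param object a `ct_sweep`.
#' @param response column to display (default `"core_error"`).
#' @param bins number of similarity bins.
#' @param ... unused.
#' @method autoplot ct_sweep
#' @export
autoplot.ct_sweep <- function(object, response = "core_error", bins = 10L,
                              ...) {
  dat <- dplyr::mutate(object,
                       sim_bin = cut(.data$similarity,
                                     breaks = seq(0, 1, length.out = bins + 1L),
                                     include.lowest = TRUE))
  dat <- dplyr::summarise(dat,
                          value = mean(.data[[response]], na.rm = TRUE),
                          .by = c("p", "sim_bin"))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$p), y = .data$sim_bin,
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = response) +
    ggplot2::labs(x = "detection probability",
                  y = "landscape similarity (binned)",
                  title = paste("Mean", response,
                                "by detection and landscape similarity")) +
    ggplot2::theme_minimal()
}

#' Fitted abundance-classification curve
#'
#' The logistic fit of correct core classification against log relative
#' abundance, with the observed outcomes as jittered points and the
#' inflection abundance as a dashed line.
#'
#' @param object a `ct_abundance_glm`.
#' @param ... unused.
#' @method autoplot ct_abundance_glm
#' @export
autoplot.ct_abundance_glm <- function(object, ...) {
  dat <- object$fit$model
  grid <- tibble::tibble(log_rel = seq(min(dat$log_rel), max(dat$log_rel),
                                       length.out = 200L))
  grid$p_correct <- predict(object, exp(grid$log_rel))$p_correct
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log_rel)) +
    ggplot2::geom_jitter(ggplot2::aes(y = as.numeric(.data$correct)),
                         height = 0.03, width = 0, alpha = 0.15, size = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p_correct),
                       linewidth = 1) +
    ggplot2::geom_vline(xintercept = log(object$inflection),
                        linetype = "dashed") +
    ggplot2::labs(x = "log relative abundance (% of most abundant species)",
                  y = "P(correctly classified core)") +
    ggplot2::theme_minimal()
}

#' Temporal-occupancy histogram of a focal community
#'
#' Distribution of detected-years over the occupancy window, coloured by
#' true status. In homogeneous landscapes this is strongly bimodal: core
#' species pile up at full occupancy while a churn of transients occupies
#' the lowest bin.
#'
#' @param occ occupancy tibble from [occupancy_from_record()].
#' @param W window length in years.
#' @export
plot_occupancy_hist <- function(occ, W = 15L) {
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$detected_years,
                                    fill = .data$true_status)) +
    ggplot2::geom_histogram(breaks = seq(0.5, W + 0.5, by = 1)) +
    ggplot2::labs(x = paste0("years detected (of ", W, ")"),
                  y = "species", fill = "true status") +
    ggplot2::theme_minimal()
}

#' Map of a habitat grid
#'
#' @param object a `habitat_grid`.
#' @param focus optional focal cell to mark.
#' @param ... unused.
#' @method autoplot habitat_grid
#' @export
autoplot.habitat_grid <- function(object, focus = NULL, ...) {
  dat <- tibble::tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    habitat = ifelse(as.vector(object) == 1L, "A", "B")
  )
  pl <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$habitat)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (!is.null(focus)) {
    pl <- pl + ggplot2::annotate("point", x = focus[2], y = focus[1],
                                 shape = 4, size = 3, stroke = 1.5)
  }
  pl
}
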