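# The factorial sweep and the statistical analyses run on it.

#' Run a replicate sweep over habitat proportions and detection levels
#'
#' Runs `reps` independent simulations per `h_A` value (child seeds derived
#' deterministically from `root_seed`), overlays every detection probability
#' in `p` on each run, and tabulates one confusion-table row per
#' (run, detection level). The standard full-scale design is 50 replicates
#' x 5 habitat proportions x 10 detection levels = 2,500 rows; `reps = 10`
#' is the reduced scale used for routine checking.
#'
#' Reproducibility: the root seed fixes the per-run child seeds; each run's
#' simulation and its subsequent detection overlays consume one RNG stream in
#' a fixed order, so rerunning with the same `root_seed` reproduces the table
#' bit for bit. Detection draws at different `p` are independent.
#'
#' @param h_A habitat-A proportions to sweep (default `seq(0.5, 0.9, 0.1)`).
#' @param p detection probabilities to overlay (default `seq(0.1, 1, 0.1)`).
#' @param reps replicate simulations per `h_A`.
#' @param q99 dispersal-kernel 99th percentile, grid cells.
#' @param root_seed integer seed for the whole sweep.
#' @param occupancy_at detection probabilities (subset of `p`) whose
#'   per-species occupancy records should be kept, pooled, and attached as
#'   `attr(, "occupancy")` — used by [fit_abundance_glm()].
#' @param ... further [sim_config()] overrides applied to every run (e.g.
#'   `n_steps`, `K`).
#' @param progress print one line per completed run.
#' @return a `ct_sweep` tibble: `run_id`, `h_A`, `q99`, `seed`,
#'   `focal_habitat`, `similarity`, `p`, plus the [tabulate_confusion()]
#'   columns.
#' @export
run_sweep <- function(h_A = seq(0.5, 0.9, by = 0.1),
                      p = seq(0.1, 1, by = 0.1),
                      reps = 10L, q99 = 4, root_seed = 1L,
                      occupancy_at = NULL, ..., progress = FALSE) {
  stopifnot(reps >= 1L, all(p >= 0 & p <= 1))
  design <- tidyr::expand_grid(h_A = h_A, rep = seq_len(reps))
  set.seed(root_seed)
  design$seed <- sample.int(.Machine$integer.max - 1L, nrow(design))
  design$run_id <- seq_len(nrow(design))

  W <- sim_config(...)$W
  occ_kept <- vector("list", nrow(design))
  rows <- purrr::pmap(design, function(h_A, rep, seed, run_id) {
    cfg <- sim_config(h_A = h_A, q99 = q99, seed = seed, ...)
    record <- tryCatch(run_simulation(cfg), error = function(e) {
      stop("run ", run_id, " (h_A = ", h_A, ", seed = ", seed,
           ") failed: ", conditionMessage(e))
    })
    per_p <- purrr::map(p, function(pp) {
      occ <- occupancy_from_record(record, pp)
      if (pp %in% occupancy_at) {
        occ_kept[[run_id]] <<- dplyr::bind_rows(
          occ_kept[[run_id]],
          dplyr::mutate(occ, run_id = run_id, h_A = h_A, p = pp,
                        .before = 1))
      }
      dplyr::mutate(tabulate_confusion(occ, W = W), p = pp, .before = 1)
    })
    if (progress) {
      message("run ", run_id, "/", nrow(design), " h_A=", h_A,
              " seed=", seed, " similarity=", round(record$similarity, 3))
    }
    dplyr::bind_cols(
      tibble::tibble(run_id = run_id, h_A = h_A, q99 = q99, seed = seed,
                     focal_habitat = record$focal_habitat,
                     similarity = record$similarity),
      dplyr::bind_rows(per_p))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ct_sweep", class(out))
  attr(out, "W") <- W
  if (!is.null(occupancy_at)) {
    attr(out, "occupancy") <- dplyr::bind_rows(occ_kept)
  }
  out
}

#' Simple linear regression of one sweep column on one predictor
#'
#' Ordinary least squares of a single response on a single predictor, rows
#' with missing response (e.g. undefined error rates) dropped. Each
#' (response, predictor) pair is fit separately so the variance explained by
#' each predictor alone is reported, which is the quantity of interest when
#' comparing how much detection versus landscape similarity drives counts
#' and error rates.
#'
#' @param rows a `ct_sweep` (or any data frame with the named columns).
#' @param response,predictor column names, e.g. `"core_error"` and `"p"`.
#' @return a `ct_fit`; see [tidy.ct_fit()] and [glance.ct_fit()].
#' @export
fit_univariate_ols <- function(rows, response, predictor) {
  dat <- dplyr::filter(rows, !is.na(.data[[response]]),
                       !is.na(.data[[predictor]]))
  if (nrow(dat) < 3L) {
    stop("need at least 3 non-missing rows to fit ", response, " ~ ",
         predictor, " (have ", nrow(dat), ")")
  }
  fit <- lm(stats::reformulate(predictor, response), data = dat)
  structure(list(fit = fit, response = response, predictor = predictor,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(dat)),
            class = "ct_fit")
}

#' @export
print.ct_fit <- function(x, ...) {
  cat("<ct_fit> ", x$response, " ~ ", x$predictor,
      ": slope = ", signif(x$slope, 4),
      ", R^2 = ", round(100 * x$r_squared, 1), "%, n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Tidy / summarize a univariate sweep regression
#'
#' `tidy()` returns per-term coefficients; `glance()` the one-row fit
#' summary (response, predictor, slope, intercept, R-squared, n).
#'
#' @param x a `ct_fit`.
#' @param ... unused.
#' @method tidy ct_fit
#' @export
tidy.ct_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                 std.error = unname(s[, 2]), statistic = unname(s[, 3]),
                 p.value = unname(s[, 4]))
}

#' @rdname tidy.ct_fit
#' @method glance ct_fit
#' @export
glance.ct_fit <- function(x, ...) {
  tibble::tibble(response = x$response, predictor = x$predictor,
                 slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n = x$n)
}

#' Fit the standard battery of univariate models to a sweep
#'
#' Regresses each of the four responses (observed true-core count, observed
#' true-transient count, core error rate, transient error rate) on each of
#' the two predictors (detection probability `p`, landscape `similarity`),
#' eight simple regressions in all. A joint two-predictor fit per response is
#' included for completeness under `predictor = "p + similarity"`.
#'
#' @param sweep a `ct_sweep`.
#' @param joint also fit the two-predictor models (default TRUE).
#' @return tibble of [glance.ct_fit()] rows.
#' @export
fit_error_models <- function(sweep, joint = TRUE) {
  responses <- c("n_obs_core", "n_obs_transient", "core_error",
                 "transient_error")
  single <- tidyr::expand_grid(response = responses,
                               predictor = c("p", "similarity"))
  out <- purrr::pmap(single, function(response, predictor) {
    # a response can be entirely missing (e.g. no transients ever observed
    # in a tiny sweep); report an NA row rather than aborting the battery
    tryCatch(glance(fit_univariate_ols(sweep, response, predictor)),
             error = function(e) tibble::tibble(
               response = response, predictor = predictor,
               slope = NA_real_, intercept = NA_real_,
               r_squared = NA_real_,
               n = sum(!is.na(sweep[[response]]))))
  })
  out <- dplyr::bind_rows(out)
  if (joint) {
    jnt <- purrr::map(responses, function(resp) {
      dat <- dplyr::filter(sweep, !is.na(.data[[resp]]))
      fit <- lm(stats::reformulate(c("p", "similarity"), resp), data = dat)
      tibble::tibble(response = resp, predictor = "p + similarity",
                     slope = NA_real_, intercept = unname(coef(fit)[1L]),
                     r_squared = summary(fit)$r.squared, n = nrow(dat))
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(jnt))
  }
  out
}

#' Logistic model of core-species classification against abundance
#'
#' Pools occupancy records of biologically core species (one detection level,
#' conventionally p = 0.5) across runs, drops intermediates, and fits a
#' binomial GLM with logit link of correct classification (inferred core) on
#' the natural log of relative landscape-wide abundance (percent of the most
#' abundant species). The inflection point is the relative abundance at which
#' the fitted probability of correct classification is 0.5.
#'
#' @param occ pooled occupancy tibble (e.g. `attr(sweep, "occupancy")`,
#'   filtered to one `p`), with columns `true_status`, `detected_years`,
#'   `relative_abundance`.
#' @param W occupancy-window length for the status thresholds.
#' @return a `ct_abundance_glm`: the `glm` fit plus `inflection` (% relative
#'   abundance), `n`, `n_dropped_zero_abundance`, and a `separation` flag set
#'   when the outcomes are perfectly separated (coefficients then diverge and
#'   should not be interpreted).
#' @seealso [predict.ct_abundance_glm()]
#' @export
fit_abundance_glm <- function(occ, W = 15L) {
  dat <- dplyr::filter(occ, .data$true_status == "core")
  dat$inferred <- infer_status(dat$detected_years, W)
  dat <- dplyr::filter(dat, .data$inferred != "intermediate")
  n_zero <- sum(is.na(dat$relative_abundance))
  dat <- dplyr::filter(dat, !is.na(.data$relative_abundance))
  dat$correct <- dat$inferred == "core"
  dat$log_rel <- log(dat$relative_abundance)
  if (length(unique(dat$correct)) < 2L) {
    stop("cannot fit the classification GLM: only ",
         if (all(dat$correct)) "correct" else "incorrect",
         " outcomes present in ", nrow(dat), " records")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(correct ~ log_rel, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # glm can also converge on separated data without warning, leaving fitted
  # probabilities numerically at 0/1 and divergent coefficients
  if (any(fitted(fit) < 1e-10) || any(fitted(fit) > 1 - 1e-10)) {
    separation <- TRUE
  }
  b <- coef(fit)
  structure(list(fit = fit,
                 inflection = unname(exp(-b[1L] / b[2L])),
                 n = nrow(dat), n_dropped_zero_abundance = n_zero,
                 separation = separation),
            class = "ct_abundance_glm")
}

#' @export
print.ct_abundance_glm <- function(x, ...) {
  b <- coef(x$fit)
  cat("<ct_abundance_glm> P(correct core classification) ~ log relative",
      "abundance\n  logit intercept = ", signif(b[1L], 4),
      ", slope = ", signif(b[2L], 4),
      ", inflection at ", signif(x$inflection, 3), "% relative abundance, n = ",
      x$n, if (x$separation) " [complete separation]", "\n", sep = "")
  invisible(x)
}

#' Predicted classification probabilities at given relative abundances
#'
#' @param object a `ct_abundance_glm`.
#' @param relative_abundance relative abundances (percent of the most
#'   abundant species) at which to evaluate the fitted curve.
#' @param ... unused.
#' @return tibble: `relative_abundance`, `p_correct`, `p_misclassified`.
#' @export
predict.ct_abundance_glm <- function(object, relative_abundance, ...) {
  b <- coef(object$fit)
  pc <- plogis(b[1L] + b[2L] * log(relative_abundance))
  tibble::tibble(relative_abundance = relative_abundance,
                 p_correct = unname(pc), p_misclassified = unname(1 - pc))
}

#' @method tidy ct_abundance_glm
#' @export
tidy.ct_abundance_glm <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @method glance ct_abundance_glm
#' @export
glance.ct_abundance_glm <- function(x, ...) {
  b <- coef(x$fit)
  tibble::tibble(intercept = unname(b[1L]), slope = unname(b[2L]),
                 inflection = x$inflection, n = x$n,
                 n_dropped_zero_abundance = x$n_dropped_zero_abundance,
                 separation = x$separation)
}

#' Rerun the sweep and fits under alternative dispersal kernels
#'
#' Repeats [run_sweep()] and [fit_error_models()] for each kernel width,
#' for checking that the qualitative pattern (slope signs, variance-explained
#' ordering) is robust to dispersal scale.
#'
#' @inheritParams run_sweep
#' @param q99 kernel 99th percentiles to compare (default narrow/standard/
#'   broad = 2, 4, 8 cells).
#' @return list with `sweeps` (named list of `ct_sweep`) and `fits` (tibble
#'   of fit summaries with a `q99` column).
#' @export
kernel_variants_report <- function(h_A = seq(0.5, 0.9, by = 0.1),
                                   p = seq(0.1, 1, by = 0.1),
                                   reps = 10L, q99 = c(2, 4, 8),
                                   root_seed = 1L, ...) {
  sweeps <- purrr::map(seq_along(q99), function(i) {
    run_sweep(h_A = h_A, p = p, reps = reps, q99 = q99[i],
              root_seed = root_seed + i - 1L, ...)
  })
  names(sweeps) <- paste0("q99_", q99)
  fits <- purrr::imap(sweeps, function(sw, nm) {
    dplyr::mutate(fit_error_models(sw, joint = FALSE),
                  q99 = sw$q99[1L], .before = 1)
  })
  list(sweeps = sweeps, fits = dplyr::bind_rows(fits))
}

#' Write sweep outputs to a directory
#'
#' `sweep.csv` (one row per run x detection level), `fits.csv` (univariate
#' and joint fit summaries) and, when occupancy records are attached,
#' `occupancy.csv`.
#'
#' @param sweep a `ct_sweep`.
#' @param dir output directory.
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(sweep, file.path(dir, "sweep.csv"))
  readr::write_csv(fit_error_models(sweep), file.path(dir, "fits.csv"))
  occ <- attr(sweep, "occupancy")
  if (!is.null(occ)) readr::write_csv(occ, file.path(dir, "occupancy.csv"))
  invisible(dir)
}
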