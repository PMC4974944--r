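#' Percentage error of a density estimate
#'
#' @param estimate Estimated density (vectorised).
#' @param truth True density; must be positive.
#' @return `100 * (estimate - truth) / truth`.
#' @examples
#' percent_error(71.4, 70)
#' @export
percent_error <- function(estimate, truth) {
  if (any(truth <= 0)) stop("`truth` must be positive", call. = FALSE)
  100 * (estimate - truth) / truth
}

#' Coefficient of variation
#'
#' The precision metric used throughout the simulation experiments:
#' sample standard deviation over mean, as a percentage. Not invariant
#' under constant shifts, so only meaningful for ratio-scale quantities
#' such as densities.
#'
#' @param values At least two numeric values with non-zero mean.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(c(2, 4))  # 47.14
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) {
    stop("need at least two values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("mean is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Experiment grids and representative cells
#'
#' `experiment_grid()` builds the full factorial of sensor and signal
#' widths used in the validation study: seven sensor widths
#' `2*pi*c(1,2,3,4,5,7,9)/9` by eleven signal widths `pi*(1:11)/11`.
#' `corner_cells()` returns the four corners of that grid (small/large
#' sensor width crossed with small/large signal width), used as
#' representative submodels for the capture-number and movement-model
#' experiments. `spanning_cells()` adds two interior cells for a compact
#' six-cell sweep.
#'
#' @param theta_values,alpha_values Angle grids in radians.
#' @return A tibble with columns `theta` and `alpha`.
#' @export
experiment_grid <- function(theta_values = 2 * pi * c(1, 2, 3, 4, 5, 7, 9) / 9,
                            alpha_values = pi * (1:11) / 11) {
  stopifnot(all(theta_values > 0), all(theta_values <= 2 * pi),
            all(alpha_values > 0), all(alpha_values <= 2 * pi))
  tidyr::expand_grid(theta = theta_values, alpha = alpha_values)
}

#' @rdname experiment_grid
#' @export
corner_cells <- function() {
  tidyr::expand_grid(theta = c(2 * pi / 9, 2 * pi), alpha = c(pi / 11, pi))
}

#' @rdname experiment_grid
#' @export
spanning_cells <- function() {
  dplyr::bind_rows(
    corner_cells(),
    tibble::tibble(theta = c(8 * pi / 9, 10 * pi / 9),
                   alpha = c(5 * pi / 11, 8 * pi / 11))
  )
}

# deterministic distinct sub-seeds below 2^31
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + idx) %% 2147483647)
}

run_cell_survey <- function(theta, alpha, seed, arena, replicate_idx, ...) {
  cfg <- sim_config(theta = theta, alpha = alpha, arena = arena,
                    seed = derive_seed(seed, replicate_idx), ...)
  run_survey(cfg)
}

new_experiment <- function(results, summary, truth, class) {
  structure(list(results = results, summary = summary, truth = truth),
            class = c(class, "grem_experiment"))
}

#' @export
print.grem_experiment <- function(x, ...) {
  cat(sprintf("<%s> true density %.4g animals/km^2\n", class(x)[1], x$truth))
  print(x$summary, n = 20)
  invisible(x)
}

#' @rdname submodel_accuracy_experiment
#' @param x An experiment object.
#' @param ... Unused.
#' @method tidy grem_experiment
#' @export
tidy.grem_experiment <- function(x, ...) x$results

#' @rdname submodel_accuracy_experiment
#' @method glance grem_experiment
#' @export
glance.grem_experiment <- function(x, ...) x$summary

#' Accuracy and precision of the submodels
#'
#' For every `(theta, alpha)` cell, simulates replicate surveys, applies
#' the density estimator with the matching closed-form mean profile, and
#' summarises the percentage error between estimated and true density.
#' The default is a desk-scale sweep (1.5 km arena, 30 replicates over
#' the six [spanning_cells()]); `full_scale = TRUE` reproduces the
#' 7.5 km, 100-replicate sweep over all 77 grid cells. Expected captures
#' are independent of arena size at fixed density, duration and
#' geometry, so the reduced arena only reduces computing cost.
#'
#' @param cells Tibble of `theta`, `alpha` cells (default
#'   [spanning_cells()]).
#' @param replicates Replicate surveys per cell (at least 2).
#' @param arena Arena side in km.
#' @param seed Integer seed; every replicate derives its own sub-seed.
#' @param full_scale If `TRUE`, run the full-size experiment
#'   (77 cells, 100 replicates, 7.5 km arena); overrides the other
#'   arguments.
#' @param ... Further arguments passed to [sim_config()] (e.g.
#'   `density`, `n_steps`, `speed`).
#' @return A `grem_accuracy` object: `results` has one row per replicate
#'   (`theta`, `alpha`, `region`, `replicate`, `z`, `D_hat`,
#'   `pct_error`), `summary` one row per cell with the median, IQR and
#'   standard deviation of the percentage error and the mean capture
#'   count.
#' @examples
#' \donttest{
#' acc <- submodel_accuracy_experiment(
#'   cells = tibble::tibble(theta = 2 * pi, alpha = pi),
#'   replicates = 3, seed = 1
#' )
#' acc$summary
#' }
#' @export
submodel_accuracy_experiment <- function(cells = spanning_cells(),
                                         replicates = 30, arena = 1.5,
                                         seed = 1, full_scale = FALSE, ...) {
  if (full_scale) {
    cells <- experiment_grid()
    replicates <- 100
    arena <- 7.5
  }
  stopifnot(replicates >= 2)
  cells <- tibble::as_tibble(cells)
  results <- purrr::pmap_dfr(
    tidyr::expand_grid(cell = seq_len(nrow(cells)), replicate = seq_len(replicates)),
    function(cell, replicate) {
      th <- cells$theta[cell]; al <- cells$alpha[cell]
      idx <- (cell - 1L) * replicates + replicate
      sv <- run_cell_survey(th, al, seed, arena, idx, ...)
      est <- estimate_density(tibble::tibble(
        z = sv$z, t = sv$t_total, v = sv$config$speed,
        theta = th, alpha = al, r = sv$config$r
      ))
      tibble::tibble(
        theta = th, alpha = al, region = est$region, replicate = replicate,
        z = sv$z, D_hat = est$D_hat,
        pct_error = percent_error(est$D_hat, sv$config$density),
        truth = sv$config$density
      )
    })
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$theta, .data$alpha, .data$region),
    median_pct_error = stats::median(.data$pct_error),
    iqr_pct_error = stats::IQR(.data$pct_error),
    sd_pct_error = stats::sd(.data$pct_error),
    mean_captures = mean(.data$z),
    replicates = dplyr::n(),
    .groups = "drop"
  )
  new_experiment(results, summary, results$truth[1], "grem_accuracy")
}

#' Precision as a function of the number of captures
#'
#' For each representative cell, runs replicate surveys until the largest
#' capture target is reached and estimates density at each intermediate
#' target `n` using the elapsed time of the `n`-th capture. Precision is
#' summarised by the coefficient of variation across replicates and
#' accuracy by the median percentage error (reported both signed and in
#' absolute value).
#'
#' @inheritParams submodel_accuracy_experiment
#' @param cells Tibble of representative `theta`, `alpha` cells (default
#'   [corner_cells()]).
#' @param targets Capture-count targets (increasing, within 10-100 in
#'   the validation study).
#' @param max_steps Per-replicate step guard for [run_until_captures()].
#' @return A `grem_captures` object; `summary` has one row per cell and
#'   target with `cv`, `median_pct_error` and `median_abs_pct_error`.
#' @export
capture_count_experiment <- function(cells = corner_cells(),
                                     targets = c(10, 25, 50, 100),
                                     replicates = 100, arena = 1.5,
                                     seed = 1, max_steps = 5e6, ...) {
  stopifnot(replicates >= 2, all(targets >= 1), !is.unsorted(targets))
  cells <- tibble::as_tibble(cells)
  n_max <- max(targets)
  results <- purrr::pmap_dfr(
    tidyr::expand_grid(cell = seq_len(nrow(cells)), replicate = seq_len(replicates)),
    function(cell, replicate) {
      th <- cells$theta[cell]; al <- cells$alpha[cell]
      idx <- (cell - 1L) * replicates + replicate
      cfg <- sim_config(theta = th, alpha = al, arena = arena,
                        seed = derive_seed(seed, idx), ...)
      sv <- run_until_captures(cfg, n_target = n_max, max_steps = max_steps)
      t_at <- sv$encounters$time[targets]
      est <- estimate_density(tibble::tibble(
        z = targets, t = t_at, v = cfg$speed, theta = th, alpha = al,
        r = cfg$r
      ))
      tibble::tibble(
        theta = th, alpha = al, region = est$region, replicate = replicate,
        n_captures = targets, t_elapsed = t_at, D_hat = est$D_hat,
        pct_error = percent_error(est$D_hat, cfg$density),
        truth = cfg$density
      )
    })
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$theta, .data$alpha, .data$region,
                    .data$n_captures),
    cv = coefficient_of_variation(.data$D_hat),
    median_pct_error = stats::median(.data$pct_error),
    median_abs_pct_error = stats::median(abs(.data$pct_error)),
    replicates = dplyr::n(),
    .groups = "drop"
  )
  new_experiment(results, summary, results$truth[1], "grem_captures")
}

#' Default movement-model settings
#'
#' The stop-start settings `S` in `{0, 0.25, 0.5, 0.75}` (with `A = 0`)
#' and correlated-random-walk settings `A` in `{0, pi/3, 2*pi/3, pi}`
#' (with `S = 0`) used by [movement_model_experiment()]; the simple
#' model (`S = A = 0`) appears once.
#'
#' @return A tibble with columns `stationary_prob` and `max_turn`.
#' @export
default_movement_settings <- function() {
  dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(stationary_prob = c(0, 0.25, 0.5, 0.75), max_turn = 0),
    tibble::tibble(stationary_prob = 0, max_turn = c(0, pi / 3, 2 * pi / 3, pi))
  ))
}

#' Robustness to movement model
#'
#' Repeats the accuracy experiment under stop-start movement (stationary
#' probability `S`) and correlated random walks (maximum turn `A`). The
#' estimator assumes continuous straight-line motion, so for stop-start
#' movement the speed supplied to the estimator is the realised average
#' speed `v * (1 - S)`; only movement during the survey contributes to
#' encounters.
#'
#' @inheritParams capture_count_experiment
#' @param movement Tibble with columns `stationary_prob` and `max_turn`;
#'   defaults to `S` in `{0, 0.25, 0.5, 0.75}` (with `A = 0`) and `A` in
#'   `{0, pi/3, 2*pi/3, pi}` (with `S = 0`).
#' @return A `grem_movement` object; `summary` is per cell and movement
#'   setting.
#' @export
movement_model_experiment <- function(cells = corner_cells(),
                                      movement = default_movement_settings(),
                                      replicates = 30, arena = 1.5,
                                      seed = 1, ...) {
  stopifnot(replicates >= 2)
  cells <- tibble::as_tibble(cells)
  movement <- tibble::as_tibble(movement)
  grid <- tidyr::expand_grid(
    setting = seq_len(nrow(movement)),
    cell = seq_len(nrow(cells)),
    replicate = seq_len(replicates)
  )
  results <- purrr::pmap_dfr(grid, function(setting, cell, replicate) {
    th <- cells$theta[cell]; al <- cells$alpha[cell]
    S <- movement$stationary_prob[setting]
    A <- movement$max_turn[setting]
    idx <- (setting - 1L) * nrow(cells) * replicates +
      (cell - 1L) * replicates + replicate
    cfg <- sim_config(theta = th, alpha = al, arena = arena,
                      stationary_prob = S, max_turn = A,
                      seed = derive_seed(seed, idx), ...)
    sv <- run_survey(cfg)
    v_eff <- cfg$speed * (1 - S)           # realised average speed
    est <- estimate_density(tibble::tibble(
      z = sv$z, t = sv$t_total, v = v_eff, theta = th, alpha = al,
      r = cfg$r
    ))
    tibble::tibble(
      theta = th, alpha = al, region = est$region,
      stationary_prob = S, max_turn = A, replicate = replicate,
      z = sv$z, D_hat = est$D_hat,
      pct_error = percent_error(est$D_hat, cfg$density),
      truth = cfg$density
    )
  })
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$theta, .data$alpha, .data$region,
                    .data$stationary_prob, .data$max_turn),
    median_pct_error = stats::median(.data$pct_error),
    iqr_pct_error = stats::IQR(.data$pct_error),
    sd_pct_error = stats::sd(.data$pct_error),
    replicates = dplyr::n(),
    .groups = "drop"
  )
  new_experiment(results, summary, results$truth[1], "grem_movement")
}

#' Stochastic parameter-error experiment
#'
#' Simulates surveys under the true parameters and re-estimates density
#' with single parameters (`alpha`, `theta`, `r`, `v`) perturbed by the
#' given relative errors, combining sampling noise with parameter bias.
#' The deterministic expected-count analogue is
#' [parameter_sensitivity()].
#'
#' @inheritParams submodel_accuracy_experiment
#' @param errors Signed relative parameter errors (0 reproduces the
#'   plain accuracy experiment).
#' @return A `grem_parameter_error` object; `summary` is per cell,
#'   parameter and error.
#' @export
parameter_error_experiment <- function(cells = spanning_cells(),
                                       errors = c(-0.10, -0.05, 0, 0.05, 0.10),
                                       replicates = 10, arena = 1.5,
                                       seed = 1, ...) {
  stopifnot(replicates >= 2, all(errors > -1))
  cells <- tibble::as_tibble(cells)
  surveys <- purrr::pmap_dfr(
    tidyr::expand_grid(cell = seq_len(nrow(cells)), replicate = seq_len(replicates)),
    function(cell, replicate) {
      th <- cells$theta[cell]; al <- cells$alpha[cell]
      idx <- (cell - 1L) * replicates + replicate
      sv <- run_cell_survey(th, al, seed, arena, idx, ...)
      tibble::tibble(theta = th, alpha = al, replicate = replicate,
                     z = sv$z, t = sv$t_total, v = sv$config$speed,
                     r = sv$config$r, truth = sv$config$density)
    })
  pgrid <- tidyr::expand_grid(parameter = c("alpha", "theta", "r", "v"),
                              rel_error = errors)
  results <- purrr::pmap_dfr(pgrid, function(parameter, rel_error) {
    pert <- surveys
    clipped <- FALSE
    fac <- 1 + rel_error
    if (parameter == "alpha") {
      raw <- pert$alpha * fac
      clipped <- any(raw > 2 * pi)
      pert$alpha <- pmin(raw, 2 * pi)
    } else if (parameter == "theta") {
      raw <- pert$theta * fac
      clipped <- any(raw > 2 * pi)
      pert$theta <- pmin(raw, 2 * pi)
    } else if (parameter == "r") {
      pert$r <- pert$r * fac
    } else {
      pert$v <- pert$v * fac
    }
    est <- estimate_density(pert)
    tibble::tibble(
      theta = surveys$theta, alpha = surveys$alpha,
      replicate = surveys$replicate, parameter = parameter,
      rel_error = rel_error, D_hat = est$D_hat,
      pct_error = percent_error(est$D_hat, surveys$truth),
      clipped = clipped, truth = surveys$truth
    )
  })
  if (any(results$clipped)) {
    warning("some angular perturbations were clipped to 2*pi", call. = FALSE)
  }
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$theta, .data$alpha, .data$parameter,
                    .data$rel_error),
    median_pct_error = stats::median(.data$pct_error),
    sd_pct_error = stats::sd(.data$pct_error),
    clipped = any(.data$clipped),
    .groups = "drop"
  )
  new_experiment(results, summary, results$truth[1], "grem_parameter_error")
}
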