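#' Simulation configuration
#'
#' Describes the spatially explicit validation world: animals at density
#' `density` move on a square torus of side `arena` past a single
#' stationary sector sensor at the arena centre. Movement alternates
#' discrete steps of duration `step_duration`: with probability
#' `stationary_prob` an animal stays put for the step; otherwise it turns
#' by a uniform draw from `[-max_turn, max_turn]` and moves a distance
#' drawn from `Normal(v*T, v*T/10)` (truncated at zero) along its new
#' heading. Defaults are a realistic upper-bound scenario: the density of
#' a very small (about 1 g) mammal and the day range of the fastest
#' terrestrial movers.
#'
#' @param theta Sensor detection width (radians).
#' @param alpha Animal signal width (radians).
#' @param arena Arena side length in km.
#' @param density Animal density in animals per square km.
#' @param n_steps Number of movement steps per survey.
#' @param step_duration Step duration in days (default 15 minutes).
#' @param speed Movement speed `v` in km/day.
#' @param stationary_prob Probability `S` of remaining stationary for a
#'   whole step, in `[0, 1)`.
#' @param max_turn Maximum absolute heading change per step `A`
#'   (radians), in `[0, pi]`.
#' @param r Sensor detection distance in km (default 10 m).
#' @param seed Optional integer seed; if supplied, [run_survey()] and
#'   [run_until_captures()] seed the generator so the encounter log is
#'   reproducible bit for bit.
#' @return An object of class `grem_sim_config`.
#' @examples
#' sim_config(theta = 2 * pi, alpha = 2 * pi, arena = 1.5, seed = 1)
#' @export
sim_config <- function(theta, alpha, arena = 7.5, density = 70,
                       n_steps = 14400, step_duration = 15 / 1440,
                       speed = 40, stationary_prob = 0, max_turn = 0,
                       r = 0.01, seed = NULL) {
  sensor <- sensor_spec(theta, r)
  signal <- signal_spec(alpha)
  stopifnot(arena > 0, density >= 0, n_steps >= 1, step_duration > 0,
            speed > 0, stationary_prob >= 0, stationary_prob < 1,
            max_turn >= 0, max_turn <= pi)
  mu <- speed * step_duration
  if (arena / 2 <= mu * 1.6 + r) {
    stop("arena too small relative to the step length: torus images of a ",
         "step segment could reach the central sensor", call. = FALSE)
  }
  structure(
    list(theta = theta, alpha = alpha, arena = arena, density = density,
         n_steps = n_steps, step_duration = step_duration, speed = speed,
         stationary_prob = stationary_prob, max_turn = max_turn, r = r,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "grem_sim_config"
  )
}

#' @export
print.grem_sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<grem_sim_config> %.4g x %.4g km torus, %.4g animals/km^2, ",
           "%d steps x %.4g days, v = %.4g km/day, S = %.3g, A = %.4g,\n",
           "  sensor theta = %.4g rad, r = %.4g km, signal alpha = %.4g rad\n"),
    x$arena, x$arena, x$density, x$n_steps, x$step_duration, x$speed,
    x$stationary_prob, x$max_turn, x$theta, x$r, x$alpha))
  invisible(x)
}

#' Initialise the simulated population
#'
#' Places `floor(arena^2 * density)` animals uniformly on the torus with
#' uniform headings. At the full-scale study defaults (7.5 km arena, 70
#' animals per square km) this creates 3937 individuals.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `x`, `y`, `heading`.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "grem_sim_config"))
  n <- floor(config$arena^2 * config$density)
  tibble::tibble(
    x = stats::runif(n, 0, config$arena),
    y = stats::runif(n, 0, config$arena),
    heading = stats::runif(n, 0, 2 * pi)
  )
}

#' Advance the population by one movement step
#'
#' Each animal independently remains stationary for the step with
#' probability `stationary_prob`; otherwise it turns by a uniform draw
#' from `[-max_turn, max_turn]` and moves a `Normal(v*T, v*T/10)`
#' distance (truncated at zero) along its heading, wrapping on the torus.
#' Headings persist through stationary steps.
#'
#' @param states A tibble as produced by [init_population()].
#' @inheritParams init_population
#' @return The updated states tibble.
#' @export
advance_step <- function(states, config) {
  stopifnot(inherits(config, "grem_sim_config"))
  n <- nrow(states)
  mu <- config$speed * config$step_duration
  stay <- if (config$stationary_prob > 0) {
    stats::runif(n) < config$stationary_prob
  } else rep(FALSE, n)
  turn <- if (config$max_turn > 0) {
    stats::runif(n, -config$max_turn, config$max_turn)
  } else numeric(n)
  d <- pmax(stats::rnorm(n, mu, mu / 10), 0)
  turn[stay] <- 0
  d[stay] <- 0
  heading <- states$heading + turn
  tibble::tibble(
    x = (states$x + d * cos(heading)) %% config$arena,
    y = (states$y + d * sin(heading)) %% config$arena,
    heading = heading
  )
}

#' Detection events along one movement segment
#'
#' Tests a straight movement segment against the detection predicate by
#' exact interval intersection: the detection radius cuts one
#' sub-interval of the segment (a quadratic in the position along it),
#' and each angular condition (sensor sector, signal cone) cuts a simple
#' set bounded by the crossings with its wedge's boundary rays. An
#' encounter is emitted at the first point of the intersection if the
#' animal is armed; detection disarms the animal, and it re-arms only
#' once its distance from the sensor exceeds `r` (one encounter per
#' pass). Stationary animals produce no new encounter events.
#'
#' @param start,end Numeric length-2 positions relative to the sensor.
#' @param heading Heading along the segment (radians).
#' @inheritParams is_detected
#' @param armed Logical: is the animal currently able to trigger a new
#'   encounter?
#' @return A list with `s` (fraction along the segment of the encounter,
#'   or `NA` if none) and `armed` (state after the segment).
#' @export
detect_on_segment <- function(start, end, heading, sensor, signal,
                              armed = TRUE) {
  sensor <- as_sensor(sensor)
  signal <- as_signal(signal)
  r <- sensor$r
  dx <- end[1] - start[1]; dy <- end[2] - start[2]
  dd <- dx^2 + dy^2
  out <- function(p) sqrt(p[1]^2 + p[2]^2) > r
  if (dd == 0) {                              # stationary: no entry occurs
    return(list(s = NA_real_, armed = armed))
  }
  # sub-interval of the segment inside the detection disk
  b2 <- 2 * (start[1] * dx + start[2] * dy)
  c2 <- start[1]^2 + start[2]^2 - r^2
  disc <- b2^2 - 4 * dd * c2
  if (disc <= 0) {                            # never inside the disk
    return(list(s = NA_real_, armed = armed || out(end)))
  }
  s_lo <- max(0, (-b2 - sqrt(disc)) / (2 * dd))
  s_hi <- min(1, (-b2 + sqrt(disc)) / (2 * dd))
  if (s_lo > s_hi) {
    return(list(s = NA_real_, armed = armed || out(end)))
  }
  if (!armed && c2 > 0) armed <- TRUE         # entered from beyond r
  w1 <- wedge_line_set(start[1], start[2], dx, dy, 0, sensor$theta / 2)
  w2 <- wedge_line_set(start[1], start[2], dx, dy, heading + pi,
                       signal$alpha / 2)
  s_enc <- first_in_sets(s_lo, s_hi,
                         w1$type, w1$lo, w1$hi, w2$type, w2$lo, w2$hi)
  if (armed && !is.na(s_enc)) {
    armed <- FALSE
  } else {
    s_enc <- NA_real_
  }
  if (!armed && out(end)) armed <- TRUE
  list(s = s_enc, armed = armed)
}

# --- exact line/wedge intersection ------------------------------------------

# s-interval of {q(s) = (rx, ry) + s (dx, dy)} inside the CONVEX wedge of
# half-angle w <= pi/2 centred at angle cc (apex at the origin), computed
# from the crossings with the two boundary rays.  Vectorised; an empty
# intersection is returned as lo > hi.
convex_wedge_interval <- function(rx, ry, dx, dy, cc, w) {
  a1 <- cc - w; a2 <- cc + w
  # inside iff cross(dir(a1), q) >= 0 and cross(q, dir(a2)) >= 0
  g0 <- cos(a1) * ry - sin(a1) * rx
  g1 <- cos(a1) * dy - sin(a1) * dx
  f0 <- sin(a2) * rx - cos(a2) * ry
  f1 <- sin(a2) * dx - cos(a2) * dy
  n <- length(rx)
  lo <- rep(-Inf, n); hi <- rep(Inf, n)
  i <- g1 > 0; lo[i] <- pmax(lo[i], -g0[i] / g1[i])
  i <- g1 < 0; hi[i] <- pmin(hi[i], -g0[i] / g1[i])
  i <- f1 > 0; lo[i] <- pmax(lo[i], -f0[i] / f1[i])
  i <- f1 < 0; hi[i] <- pmin(hi[i], -f0[i] / f1[i])
  bad <- (g1 == 0 & g0 < 0) | (f1 == 0 & f0 < 0)
  lo[bad] <- Inf; hi[bad] <- -Inf
  list(lo = lo, hi = hi)
}

# s-set of the (not necessarily convex) wedge of half-angle w centred at cc:
# type 0 = the whole line (w >= pi), 1 = the interval [lo, hi], 2 = the
# complement of the open interval (lo, hi).  A wedge wider than a half-plane
# is the complement of the convex wedge of half-angle pi - w at cc + pi.
wedge_line_set <- function(rx, ry, dx, dy, cc, w) {
  n <- length(rx)
  if (w >= pi) {
    return(list(type = rep(0L, n), lo = rep(-Inf, n), hi = rep(Inf, n)))
  }
  if (w <= 0) {                                # zero-width wedge: measure zero
    return(list(type = rep(1L, n), lo = rep(Inf, n), hi = rep(-Inf, n)))
  }
  if (w <= pi / 2) {
    iv <- convex_wedge_interval(rx, ry, dx, dy, cc, w)
    return(list(type = rep(1L, n), lo = iv$lo, hi = iv$hi))
  }
  iv <- convex_wedge_interval(rx, ry, dx, dy, cc + pi, pi - w)
  type <- rep(2L, n)
  type[iv$lo > iv$hi] <- 0L                   # empty inner wedge: whole line
  list(type = type, lo = iv$lo, hi = iv$hi)
}

# first s in [s0, s1] belonging to both wedge sets (scalar); NA if none
first_in_sets <- function(s0, s1, t1, lo1, hi1, t2, lo2, hi2) {
  s <- s0
  for (iter in 1:8) {
    s_prev <- s
    if (t1 == 1L) {
      if (lo1 > hi1 || s > hi1) return(NA_real_)
      if (s < lo1) s <- lo1
    } else if (t1 == 2L) {
      if (s > lo1 && s < hi1) s <- hi1
    }
    if (t2 == 1L) {
      if (lo2 > hi2 || s > hi2) return(NA_real_)
      if (s < lo2) s <- lo2
    } else if (t2 == 2L) {
      if (s > lo2 && s < hi2) s <- hi2
    }
    if (s > s1) return(NA_real_)
    if (s == s_prev) return(s)
  }
  NA_real_
}

# --- vectorised engine ------------------------------------------------------
# --- vectorised engine ------------------------------------------------------

# Simulates `n` steps for the whole population at once.  state is a list
# with numeric x, y, heading and logical armed.  Returns the new state and
# the encounter log for the chunk.  Random draws occur in a fixed order
# (stationary mask if S > 0, turns if A > 0, then step lengths), so a run
# is reproducible bit for bit from its seed.
sim_chunk <- function(state, config, n, step_offset) {
  nA <- length(state$x)
  L <- config$arena
  r <- config$r
  cx <- L / 2
  mu <- config$speed * config$step_duration
  empty <- tibble::tibble(step = integer(), time = numeric(),
                          animal_id = integer(), x = numeric(),
                          y = numeric(), heading = numeric())
  if (nA == 0L) return(list(state = state, encounters = empty))

  stay <- if (config$stationary_prob > 0) {
    matrix(stats::runif(n * nA) < config$stationary_prob, n, nA)
  } else NULL
  turn <- if (config$max_turn > 0) {
    tn <- matrix(stats::runif(n * nA, -config$max_turn, config$max_turn), n, nA)
    if (!is.null(stay)) tn[stay] <- 0
    tn
  } else NULL
  dlen <- matrix(pmax(stats::rnorm(n * nA, mu, mu / 10), 0), n, nA)
  if (!is.null(stay)) dlen[stay] <- 0

  cum2 <- function(M) {
    if (n == 1L) M else apply(M, 2, cumsum)
  }
  if (is.null(turn)) {
    # headings constant over the chunk: avoid per-step trig matrices
    h_end <- state$heading
    DX <- dlen * rep(cos(state$heading), each = n)
    DY <- dlen * rep(sin(state$heading), each = n)
  } else {
    H <- cum2(turn) + matrix(state$heading, n, nA, byrow = TRUE)
    h_end <- H[n, ]
    DX <- dlen * cos(H)
    DY <- dlen * sin(H)
  }
  X <- cum2(DX) + matrix(state$x, n, nA, byrow = TRUE)
  Y <- cum2(DY) + matrix(state$y, n, nA, byrow = TRUE)

  # wrapped start-of-step positions relative to the central sensor; each
  # step segment is treated unwrapped (the config guarantees a wrapped
  # image cannot reach the sensor)
  Rx <- (X - DX) %% L - cx
  Ry <- (Y - DY) %% L - cx

  new_state <- list(
    x = X[n, ] %% L, y = Y[n, ] %% L, heading = h_end, armed = state$armed
  )
  moved_fun <- function() {
    if (is.null(stay)) rep(TRUE, nA)
    else if (n == 1L) dlen[1, ] > 0 else colSums(dlen) > 0
  }

  # cheap prefilter: a segment can only reach the disk if its start lies
  # within r plus the longest step drawn in this chunk
  near <- which(Rx^2 + Ry^2 <= (r + max(dlen))^2)
  if (length(near) == 0L) {
    new_state$armed <- state$armed | moved_fun()
    return(list(state = new_state, encounters = empty))
  }
  rx_n <- Rx[near]; ry_n <- Ry[near]
  dx_n <- DX[near]; dy_n <- DY[near]
  dd_n <- dx_n^2 + dy_n^2
  tt <- pmin(1, pmax(0, -(rx_n * dx_n + ry_n * dy_n) /
                          pmax(dd_n, .Machine$double.xmin)))
  d2 <- (rx_n + tt * dx_n)^2 + (ry_n + tt * dy_n)^2
  keep <- d2 <= r^2 & dd_n > 0
  cand <- near[keep]

  if (length(cand) == 0L) {
    new_state$armed <- state$armed | moved_fun()
    return(list(state = new_state, encounters = empty))
  }

  kstep <- (cand - 1L) %% n + 1L
  anim <- (cand - 1L) %/% n + 1L
  h_cand <- if (is.null(turn)) state$heading[anim] else H[cand]
  rx <- rx_n[keep]; ry <- ry_n[keep]
  ddx <- dx_n[keep]; ddy <- dy_n[keep]; dd_c <- dd_n[keep]
  b2 <- 2 * (rx * ddx + ry * ddy)
  c2 <- rx^2 + ry^2 - r^2
  disc <- pmax(b2^2 - 4 * dd_c * c2, 0)
  s_lo <- pmax(0, (-b2 - sqrt(disc)) / (2 * dd_c))
  s_hi <- pmin(1, (-b2 + sqrt(disc)) / (2 * dd_c))
  s_hi <- pmax(s_hi, s_lo)
  start_out <- c2 > 0
  end_out <- (rx + ddx)^2 + (ry + ddy)^2 > r^2

  # exact first detected point on each candidate segment
  w1 <- wedge_line_set(rx, ry, ddx, ddy, 0, config$theta / 2)
  w2 <- wedge_line_set(rx, ry, ddx, ddy, h_cand + pi, config$alpha / 2)
  s_det <- rep(NA_real_, length(cand))
  for (i in seq_along(cand)) {
    s_det[i] <- first_in_sets(s_lo[i], s_hi[i],
                              w1$type[i], w1$lo[i], w1$hi[i],
                              w2$type[i], w2$lo[i], w2$hi[i])
  }

  # sequential arming per animal, candidates in step order
  ord <- order(anim, kstep)
  armed <- state$armed
  hit <- logical(length(cand))
  for (i in ord) {
    aj <- anim[i]
    ok <- armed[aj]
    if (!ok && start_out[i]) ok <- TRUE
    if (ok && !is.na(s_det[i])) {
      hit[i] <- TRUE
      ok <- FALSE
    }
    if (!ok && end_out[i]) ok <- TRUE
    armed[aj] <- ok
  }
  # disarmed animals whose last candidate ended inside the disk cannot have
  # moved since (a later moving step would itself be a candidate); any other
  # animal with a moving step is beyond r by construction
  moved <- moved_fun()
  no_cand <- !(seq_len(nA) %in% anim)
  armed[no_cand] <- state$armed[no_cand] | moved[no_cand]
  new_state$armed <- armed

  enc <- which(hit)
  enc <- enc[order(kstep[enc] - 1 + s_det[enc], anim[enc])]
  encounters <- tibble::tibble(
    step = step_offset + kstep[enc],
    time = (step_offset + kstep[enc] - 1 + s_det[enc]) * config$step_duration,
    animal_id = anim[enc],
    x = (rx[enc] + s_det[enc] * ddx[enc]) + cx,
    y = (ry[enc] + s_det[enc] * ddy[enc]) + cx,
    heading = h_cand[enc]
  )
  list(state = new_state, encounters = encounters)
}

start_state <- function(config) {
  pop <- init_population(config)
  L <- config$arena
  det0 <- if (nrow(pop)) {
    is_detected(pop$x - L / 2, pop$y - L / 2, pop$heading,
                sensor_spec(config$theta, config$r),
                signal_spec(config$alpha))
  } else logical(0)
  enc0 <- tibble::tibble(
    step = rep(0L, sum(det0)), time = rep(0, sum(det0)),
    animal_id = which(det0), x = pop$x[det0], y = pop$y[det0],
    heading = pop$heading[det0]
  )
  list(state = list(x = pop$x, y = pop$y, heading = pop$heading,
                    armed = !det0),
       encounters = enc0)
}

chunk_rows <- function(nA) max(64L, as.integer(floor(2e5 / max(nA, 1L))))

#' Run a fixed-duration simulated survey
#'
#' Simulates `n_steps` movement steps of the whole population and records
#' every encounter: the first detected position of each pass of an animal
#' through the capture set (position-and-heading combinations satisfying
#' [is_detected()]). Animals already in the capture set at the start are
#' counted once at time zero. Encounter times are interpolated within a
#' step from the distance travelled.
#'
#' @inheritParams init_population
#' @return An object of class `grem_survey`: a list with `encounters`
#'   (tibble: `step`, `time`, `animal_id`, `x`, `y`, `heading`), `z`
#'   (encounter count), `t_total` (survey duration in days), `n_animals`
#'   and `config`. Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' cfg <- sim_config(2 * pi, 2 * pi, arena = 1, n_steps = 50, seed = 1)
#' run_survey(cfg)
#' @export
run_survey <- function(config) {
  stopifnot(inherits(config, "grem_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  init <- start_state(config)
  state <- init$state
  logs <- list(init$encounters)
  nA <- length(state$x)
  per <- chunk_rows(nA)
  done <- 0L
  while (done < config$n_steps) {
    n <- min(per, config$n_steps - done)
    res <- sim_chunk(state, config, n, done)
    state <- res$state
    logs[[length(logs) + 1L]] <- res$encounters
    done <- done + n
  }
  encounters <- dplyr::bind_rows(logs)
  structure(
    list(encounters = encounters, z = nrow(encounters),
         t_total = config$n_steps * config$step_duration,
         n_animals = nA, config = config),
    class = "grem_survey"
  )
}

#' Run a simulated survey until a target number of captures
#'
#' Simulates movement until the `n_target`-th encounter is recorded and
#' reports the elapsed time at that encounter (interpolated within the
#' step). Used to study how estimator precision scales with the number
#' of captures.
#'
#' @inheritParams init_population
#' @param n_target Number of captures to accumulate (at least 1).
#' @param max_steps Guard on the total number of steps simulated; the
#'   function fails with a timeout error if the target has not been
#'   reached by then.
#' @return An object of class `grem_survey` with `z = n_target`,
#'   `t_total` equal to the elapsed time of the final capture, and the
#'   encounter log up to (and including) that capture.
#' @export
run_until_captures <- function(config, n_target, max_steps = 5e6) {
  stopifnot(inherits(config, "grem_sim_config"), n_target >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  init <- start_state(config)
  state <- init$state
  logs <- list(init$encounters)
  total <- nrow(init$encounters)
  nA <- length(state$x)
  if (nA == 0L) stop("capture rate is zero: empty population", call. = FALSE)
  p_bar <- pbar_closed_num(config$theta, config$alpha, config$r)
  if (p_bar <= 0) stop("capture rate is zero: undetectable configuration",
                       call. = FALSE)
  rate <- p_bar * config$speed * config$density *
    (1 - config$stationary_prob)                       # encounters per day
  guess <- ceiling(1.3 * n_target / (rate * config$step_duration))
  per <- min(chunk_rows(nA), max(500L, guess))
  done <- 0L
  while (total < n_target) {
    if (done >= max_steps) {
      stop(sprintf("timeout: %d captures not reached within %d steps",
                   n_target, as.integer(max_steps)), call. = FALSE)
    }
    n <- min(per, max_steps - done)
    res <- sim_chunk(state, config, n, done)
    state <- res$state
    logs[[length(logs) + 1L]] <- res$encounters
    total <- total + nrow(res$encounters)
    done <- done + n
  }
  n_target <- as.integer(n_target)
  encounters <- dplyr::arrange(dplyr::bind_rows(logs), .data$time)[seq_len(n_target), ]
  structure(
    list(encounters = encounters, z = n_target,
         t_total = encounters$time[n_target],
         n_animals = nA, config = config),
    class = "grem_survey"
  )
}

#' @export
print.grem_survey <- function(x, ...) {
  cat(sprintf(
    "<grem_survey> %d encounters over %.4g days (%d animals, theta = %.4g, alpha = %.4g)\n",
    x$z, x$t_total, x$n_animals, x$config$theta, x$config$alpha))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname run_survey
#' @param x A `grem_survey` object.
#' @param ... Unused.
#' @method tidy grem_survey
#' @export
tidy.grem_survey <- function(x, ...) x$encounters

#' @rdname run_survey
#' @method glance grem_survey
#' @export
glance.grem_survey <- function(x, ...) {
  tibble::tibble(
    z = x$z, t_total = x$t_total, n_animals = x$n_animals,
    theta = x$config$theta, alpha = x$config$alpha, r = x$config$r,
    speed = x$config$speed, arena = x$config$arena,
    density = x$config$density,
    seed = if (is.null(x$config$seed)) NA_integer_ else x$config$seed
  )
}
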