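# The supervised-MD protocol as an explicit state machine over trajectory
# windows.  It is engine-agnostic: any callable with the segment contract
# (function(system, state, duration, config) -> list(segment, state), where
# the segment stamps frame times from state$time) can drive it, which is how
# the tests exercise the protocol with scripted stub engines.

#' Supervision-protocol configuration
#'
#' Defaults are the desk-scale settings; the classic atomistic protocol uses
#' a 600 ps window and a 25 ns production run, with the same structure:
#' windows are accepted when the ligand-site centroid-distance slope is
#' negative, 30 consecutive failures terminate the run, binding is declared
#' below 5 A, 30 unsupervised check windows follow, and an unsupervised
#' production run closes the protocol.
#'
#' @param window_length supervised window length (ps).
#' @param n_distance_samples centroid-distance samples per window, evenly
#'   spaced, used for the slope fit.
#' @param max_consecutive_failures consecutive rejected windows after which
#'   the run stops as `unbound_terminated`.
#' @param bind_threshold centroid distance (A) below which binding is
#'   declared and supervision is switched off.
#' @param n_unsupervised_checks number of post-binding unsupervised check
#'   windows; any check ending above `bind_threshold` resumes supervision.
#' @param unsupervised_window_length length of each check window (ps).
#' @param production_length unsupervised production run appended after the
#'   checks (ps); 0 skips it.
#' @param seed integer seed for the supervisor's RNG stream (velocity
#'   redraws on retries).
#' @param bind_check `"end"` evaluates the binding threshold on the
#'   end-of-window distance (default), `"any"` on any sampled frame.
#' @param centroid `"mass"` for mass-weighted centroids (default) or
#'   `"geometric"`.
#' @param time_budget optional cap on total simulated time (ps, including
#'   retried windows); exceeded runs stop with status `budget_exhausted`.
#' @return A validated list of class `supervision_config`.
#' @export
supervision_config <- function(window_length = 10, n_distance_samples = 100,
                               max_consecutive_failures = 30,
                               bind_threshold = 5,
                               n_unsupervised_checks = 30,
                               unsupervised_window_length = window_length,
                               production_length = 100 * window_length,
                               seed = 1, bind_check = c("end", "any"),
                               centroid = c("mass", "geometric"),
                               time_budget = Inf) {
  cfg <- list(window_length = window_length,
              n_distance_samples = as.integer(n_distance_samples),
              max_consecutive_failures = as.integer(max_consecutive_failures),
              bind_threshold = bind_threshold,
              n_unsupervised_checks = as.integer(n_unsupervised_checks),
              unsupervised_window_length = unsupervised_window_length,
              production_length = production_length,
              seed = as.integer(seed),
              bind_check = match.arg(bind_check),
              centroid = match.arg(centroid),
              time_budget = time_budget)
  if (cfg$window_length <= 0) stop("window_length must be > 0")
  if (cfg$n_distance_samples < 1) stop("n_distance_samples must be >= 1")
  if (cfg$max_consecutive_failures < 1)
    stop("max_consecutive_failures must be >= 1")
  if (cfg$bind_threshold <= 0) stop("bind_threshold must be > 0")
  if (cfg$n_unsupervised_checks < 1)
    stop("n_unsupervised_checks must be >= 1")
  if (cfg$unsupervised_window_length <= 0)
    stop("unsupervised_window_length must be > 0")
  if (cfg$production_length < 0) stop("production_length must be >= 0")
  class(cfg) <- "supervision_config"
  cfg
}

#' Mass-weighted centroid of a bead selection
#'
#' @param coords N x 3 coordinates (A).
#' @param selection integer bead indices; must be non-empty.
#' @param masses per-bead masses (length N); equal masses give the geometric
#'   centroid.
#' @return Length-3 centroid (A).
#' @export
mass_weighted_centroid <- function(coords, selection, masses) {
  if (length(selection) == 0) stop("empty selection")
  w <- masses[selection]
  colSums(coords[selection, , drop = FALSE] * w) / sum(w)
}

#' Ordinary least-squares slope of distance versus time
#'
#' Computed as `cov(t, d) / var(t)`, which is exactly zero for an exactly
#' constant distance series (a zero slope must count as a rejected window,
#' so it must not pick up rounding noise).
#'
#' @param times sample times (ps); at least two distinct values.
#' @param distances distances (A), same length.
#' @return Slope (A/ps).
#' @export
ols_slope <- function(times, distances) {
  if (length(times) < 2 || length(distances) != length(times))
    stop("need >= 2 paired points")
  if (all(times == times[1])) stop("times have zero variance")
  stats::cov(times, distances) / stats::var(times)
}

# minimum-image distance between two points
.mi_dist <- function(a, b, box) {
  d <- a - b
  if (!is.null(box) && box > 0) d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

#' Ligand-to-site centroid distance of one configuration
#'
#' @param coords N x 3 coordinates (A).
#' @param system a `cg_system` with site and ligand selections.
#' @param centroid `"mass"` or `"geometric"`.
#' @return Distance (A), minimum-image when the system has a box.
#' @export
centroid_distance <- function(coords, system, centroid = "mass") {
  m <- if (centroid == "mass") system$beads$mass else
    rep(1, n_beads(system))
  cs <- mass_weighted_centroid(coords, site_beads(system), m)
  cl <- mass_weighted_centroid(coords, ligand_beads(system), m)
  .mi_dist(cl, cs, system$box)
}

# centroid-distance series over all frames of a trajectory, vectorised
.distance_series <- function(traj, system, centroid = "mass") {
  nf <- n_frames(traj)
  m <- if (centroid == "mass") system$beads$mass else
    rep(1, dim(traj$frames)[2])
  cen <- function(idx) {
    w <- m[idx] / sum(m[idx])
    out <- matrix(0, nf, 3)
    for (d in 1:3)
      out[, d] <- matrix(traj$frames[, idx, d, drop = FALSE], nrow = nf) %*% w
    out
  }
  d <- cen(ligand_beads(system)) - cen(site_beads(system))
  if (!is.null(system$box)) d <- d - system$box * round(d / system$box)
  sqrt(rowSums(d^2))
}

#' The default engine: coarse-grained Langevin dynamics
#'
#' Thin wrapper around [langevin_segment()] satisfying the supervisor's
#' engine contract.
#'
#' @param system,state,duration,config as in [langevin_segment()].
#' @return `list(segment, state)`.
#' @export
langevin_engine <- function(system, state, duration, config) {
  langevin_segment(system, state, duration, config)
}

#' Run one supervised window
#'
#' Propagates one window of `sup_config$window_length` ps, samples the
#' ligand-site centroid distance at `n_distance_samples` evenly spaced
#' times, and fits an ordinary least-squares line.  A strictly negative
#' slope accepts the window (the end-of-window state is returned); anything
#' else rejects it, returning the start-of-window coordinates and clock with
#' freshly drawn Maxwell-Boltzmann velocities for the mobile beads.
#'
#' @param system a `cg_system`.
#' @param state a [sim_state()].
#' @param engine_config an [engine_config()]; its `save_interval` is
#'   overridden to `window_length / n_distance_samples`.
#' @param sup_config a [supervision_config()].
#' @param engine an engine callable; defaults to [langevin_engine()].
#' @param retry_seed integer seed for the velocity redraw on rejection;
#'   defaults to a value drawn from `sup_config$seed`.
#' @return List with `record` (index-free window record: `slope`,
#'   `decision`, `end_distance`, `distance_series` data.frame), `state`, and
#'   `segment` (the propagated `cg_trajectory`).
#' @export
supervised_window <- function(system, state, engine_config, sup_config,
                              engine = langevin_engine, retry_seed = NULL) {
  cfg <- engine_config
  cfg$save_interval <- sup_config$window_length / sup_config$n_distance_samples
  res <- tryCatch(
    engine(system, state, sup_config$window_length, cfg),
    error = function(e) stop("engine failure in supervised window at t = ",
                             signif(state$time, 8), " ps: ",
                             conditionMessage(e), call. = FALSE))
  distances <- .distance_series(res$segment, system, sup_config$centroid)
  times <- res$segment$times
  slope <- ols_slope(times, distances)
  accepted <- slope < 0
  record <- list(slope = slope,
                 decision = if (accepted) "accepted" else "retried",
                 end_distance = distances[length(distances)],
                 distance_series = data.frame(time_ps = times,
                                              distance_A = distances))
  if (accepted) {
    return(list(record = record, state = res$state, segment = res$segment))
  }
  if (is.null(retry_seed)) retry_seed <- sup_config$seed
  frozen <- engine_config$frozen
  redraw <- rng_eval(retry_seed, function() {
    v <- maxwell_velocities(system$beads$mass, engine_config$temperature)
    if (length(frozen) > 0) v[frozen, ] <- 0
    v
  })
  new_state <- structure(list(coords = state$coords,
                              velocities = redraw$value,
                              time = state$time, rng_state = redraw$rng),
                         class = "sim_state")
  list(record = record, state = new_state, segment = res$segment)
}

#' Run the full supervised-binding protocol
#'
#' Phase 1 (supervised): windows are repeated under the slope criterion,
#' a consecutive-failure counter increments on each rejection and resets on
#' acceptance; reaching `max_consecutive_failures` terminates the run as
#' `unbound_terminated`.  When an accepted window ends below
#' `bind_threshold`, Phase 2 runs `n_unsupervised_checks` unsupervised check
#' windows; a check ending above the threshold resumes Phase 1 (counter
#' reset).  Phase 3 appends one unsupervised production run and the protocol
#' ends with status `bound`.  Every window (including retries) is logged and
#' counted in `total_simulated_time`; only accepted/check/production frames
#' enter the returned trajectory, so a retried window never advances the
#' accepted clock.
#'
#' @param system a `cg_system`.
#' @param initial_state a [sim_state()]; the ligand must start outside
#'   `bind_threshold`.
#' @param engine_config an [engine_config()].
#' @param sup_config a [supervision_config()].
#' @param engine an engine callable; defaults to [langevin_engine()].
#' @return Object of class `sumd_result`: `status` (`bound`,
#'   `unbound_terminated`, or `budget_exhausted` when a `time_budget` is
#'   set), `windows` (one row per attempted window), `total_simulated_time`
#'   (ps), `first_binding_time` (accepted-trajectory clock, ps, or NA),
#'   `first_binding_sim_time` (cumulative simulated time at first crossing),
#'   `final_state`, and `trajectory` (concatenated accepted frames).
#' @export
run_sumd <- function(system, initial_state, engine_config, sup_config,
                     engine = langevin_engine) {
  d0 <- centroid_distance(initial_state$coords, system, sup_config$centroid)
  if (d0 < sup_config$bind_threshold)
    stop("ligand already within bind_threshold (", signif(d0, 4), " A)")

  sup_rng <- rng_eval(sup_config$seed, function() runif(1))$rng
  draw_seed <- function() {
    r <- rng_eval(sup_rng, function() sample.int(2147483646L, 1))
    sup_rng <<- r$rng
    r$value
  }

  state <- initial_state
  phase <- "supervised"
  fails <- 0L
  idx <- 0L
  checks_done <- 0L
  total <- 0
  records <- list()
  segments <- list()
  first_bind <- NA_real_
  first_bind_sim <- NA_real_
  status <- NA_character_

  note_crossing <- function(seg_distances, seg_times, total_before,
                            window_start) {
    hit <- which(seg_distances < sup_config$bind_threshold)
    if (length(hit) > 0 && is.na(first_bind)) {
      first_bind <<- seg_times[hit[1]]
      first_bind_sim <<- total_before + (seg_times[hit[1]] - window_start)
    }
  }

  add_record <- function(rec) records[[length(records) + 1L]] <<- rec

  repeat {
    next_len <- switch(phase,
                       supervised = sup_config$window_length,
                       check = sup_config$unsupervised_window_length,
                       production = sup_config$production_length)
    if (total + next_len > sup_config$time_budget) {
      status <- "budget_exhausted"
      break
    }
    if (phase == "supervised") {
      idx <- idx + 1L
      sw <- supervised_window(system, state, engine_config, sup_config,
                              engine, retry_seed = draw_seed())
      total <- total + sup_config$window_length
      accepted <- sw$record$decision == "accepted"
      if (accepted) {
        fails <- 0L
        ds <- sw$record$distance_series
        note_crossing(ds$distance_A, ds$time_ps,
                      total - sup_config$window_length, state$time)
        segments[[length(segments) + 1L]] <- sw$segment
      } else {
        fails <- fails + 1L
      }
      add_record(data.frame(index = idx, phase = "supervised",
                            start_time = state$time, slope = sw$record$slope,
                            decision = sw$record$decision,
                            end_distance = sw$record$end_distance,
                            consecutive_failures_after = fails,
                            sim_time_after = total))
      state <- sw$state
      if (!accepted && fails >= sup_config$max_consecutive_failures) {
        status <- "unbound_terminated"
        break
      }
      if (accepted) {
        bound_now <- if (sup_config$bind_check == "end")
          sw$record$end_distance < sup_config$bind_threshold
        else any(sw$record$distance_series$distance_A <
                   sup_config$bind_threshold)
        if (bound_now) {
          phase <- "check"
          checks_done <- 0L
        }
      }
    } else if (phase == "check") {
      idx <- idx + 1L
      cfg <- engine_config
      cfg$save_interval <- sup_config$window_length /
        sup_config$n_distance_samples
      res <- engine(system, state, sup_config$unsupervised_window_length, cfg)
      total <- total + sup_config$unsupervised_window_length
      distances <- .distance_series(res$segment, system, sup_config$centroid)
      note_crossing(distances, res$segment$times,
                    total - sup_config$unsupervised_window_length,
                    state$time)
      segments[[length(segments) + 1L]] <- res$segment
      endd <- distances[length(distances)]
      checks_done <- checks_done + 1L
      add_record(data.frame(index = idx, phase = "unsupervised_check",
                            start_time = state$time, slope = NA_real_,
                            decision = "accepted", end_distance = endd,
                            consecutive_failures_after = 0L,
                            sim_time_after = total))
      state <- res$state
      if (endd > sup_config$bind_threshold) {
        phase <- "supervised"
        fails <- 0L
      } else if (checks_done >= sup_config$n_unsupervised_checks) {
        phase <- "production"
      }
    } else { # production
      if (sup_config$production_length > 0) {
        idx <- idx + 1L
        cfg <- engine_config
        cfg$save_interval <- sup_config$window_length /
          sup_config$n_distance_samples
        res <- engine(system, state, sup_config$production_length, cfg)
        total <- total + sup_config$production_length
        distances <- .distance_series(res$segment, system,
                                      sup_config$centroid)
        note_crossing(distances, res$segment$times,
                      total - sup_config$production_length, state$time)
        segments[[length(segments) + 1L]] <- res$segment
        add_record(data.frame(index = idx, phase = "production",
                              start_time = state$time, slope = NA_real_,
                              decision = "accepted",
                              end_distance = distances[length(distances)],
                              consecutive_failures_after = 0L,
                              sim_time_after = total))
        state <- res$state
      }
      status <- "bound"
      break
    }
  }

  windows <- if (length(records) > 0) do.call(rbind, records) else
    data.frame(index = integer(0), phase = character(0),
               start_time = numeric(0), slope = numeric(0),
               decision = character(0), end_distance = numeric(0),
               consecutive_failures_after = integer(0),
               sim_time_after = numeric(0))
  trajectory <- if (length(segments) > 0) concat_trajectories(segments) else
    NULL
  structure(list(status = status, windows = windows,
                 total_simulated_time = total,
                 first_binding_time = first_bind,
                 first_binding_sim_time = first_bind_sim,
                 final_state = state, trajectory = trajectory,
                 sup_config = sup_config),
            class = "sumd_result")
}

#' @export
print.sumd_result <- function(x, ...) {
  acc <- sum(x$windows$decision == "accepted" &
               x$windows$phase == "supervised")
  ret <- sum(x$windows$decision == "retried")
  cat("<sumd_result> status = ", x$status, "\n",
      "  supervised windows: ", acc, " accepted, ", ret, " retried\n",
      "  total simulated time: ", signif(x$total_simulated_time, 6), " ps\n",
      "  first binding at: ",
      if (is.na(x$first_binding_time)) "never" else
        paste0(signif(x$first_binding_time, 6), " ps (",
               signif(x$first_binding_sim_time, 6), " ps simulated)"),
      "\n", sep = "")
  invisible(x)
}
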