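# Synthetic hand-motion simulator: a parameterized virtual patient
# performs the test, so every engine path (grab, carry, divider
# collision, drop, score) is exercisable with no camera. The simulated
# hand runs closed-loop: it reads only the published arena observation
# (current block position and state) handed to every provider, reaches
# the block, pinches, carries it along an arc over the divider, opens in
# the target compartment, and repeats.
#
# Impairment model: tremor is white Gaussian landmark noise; an
# unreliable pinch fails a grasp *attempt* (the close command does not
# register, or the noisy fingertips missed the block), after which the
# subject re-opens and retries only after a corrective-movement penalty.
# The grip, once the engine has registered the grab, is held stably, so
# mean scores are monotone in both impairment axes.

#' Kinematic model of a simulated subject
#'
#' @param reach_speed Hand speed, pixels/second. The default emulates the
#'   slowed reaching of a hemiparetic hand: with the default 720p layout
#'   it yields roughly a dozen transfers per 60-second trial, the range
#'   reported for stroke patients on AR dexterity tests.
#' @param tremor_sd Gaussian positional noise added to each landmark per
#'   frame, pixels (white noise, no autocorrelation).
#' @param pinch_close_reliability Probability that a commanded grasp
#'   attempt registers a closed pinch; a failed attempt costs
#'   `grasp_retry_penalty` seconds of corrective movement before the
#'   next attempt.
#' @param grasp_retry_penalty Seconds lost after a fumbled grasp attempt.
#' @param aperture_open,aperture_closed Fingertip distance, pixels, when
#'   the hand is commanded open / closed. Must satisfy
#'   `aperture_closed < grab_threshold <= aperture_open` for the engine's
#'   default pinch thresholds.
#' @param reaction_lag Dwell, seconds, between arriving over a block and
#'   commanding the pinch.
#' @param carry_height_fraction Height at which blocks are carried, as a
#'   fraction of box height from the bottom. Values below the divider's
#'   `divider_top_fraction` produce divider collisions by construction.
#' @param start_position Initial hand position (pixels); `NULL` = the
#'   drop point in the target compartment.
#' @return A `subject_model` object.
#' @export
subject_model <- function(reach_speed = 300, tremor_sd = 3,
                          pinch_close_reliability = 0.97,
                          grasp_retry_penalty = 0.8,
                          aperture_open = 120, aperture_closed = 20,
                          reaction_lag = 0.1, carry_height_fraction = 0.85,
                          start_position = NULL) {
  stopifnot(reach_speed > 0, tremor_sd >= 0,
            pinch_close_reliability >= 0, pinch_close_reliability <= 1,
            grasp_retry_penalty >= 0,
            aperture_closed < aperture_open, reaction_lag >= 0,
            carry_height_fraction > 0, carry_height_fraction < 1)
  structure(list(reach_speed = reach_speed, tremor_sd = tremor_sd,
                 pinch_close_reliability = pinch_close_reliability,
                 grasp_retry_penalty = grasp_retry_penalty,
                 aperture_open = aperture_open,
                 aperture_closed = aperture_closed,
                 reaction_lag = reaction_lag,
                 carry_height_fraction = carry_height_fraction,
                 start_position = start_position),
            class = "subject_model")
}

# carry/drop geometry for a layout
sim_geometry <- function(subject, layout) {
  b <- layout$box
  h <- b["y1"] - b["y0"]
  tgt <- layout$target_compartment
  list(y_carry = unname(b["y1"] - subject$carry_height_fraction * h),
       drop = c(unname((tgt["x0"] + tgt["x1"]) / 2),
                unname(b["y1"] - 0.25 * h)))
}

# fixed 21-landmark template: pixel offsets of the non-tip landmarks
# around the carry point (x to the right, y downward); thumb tip (row 5)
# and index tip (row 9) are overridden by the commanded aperture.
hand_template <- function() {
  t(matrix(c(
       0,  90,   # 0 wrist
     -45,  60,   # 1 thumb cmc
     -60,  30,   # 2 thumb mcp
     -55,  10,   # 3 thumb ip
     -50,   0,   # 4 thumb tip (overridden)
     -15,  35,   # 5 index mcp
     -10,  15,   # 6 index pip
      -5,   5,   # 7 index dip
       0,   0,   # 8 index tip (overridden)
      10,  40,   # 9 middle mcp
      12,  20,   # 10 middle pip
      14,  10,   # 11 middle dip
      16,   5,   # 12 middle tip
      30,  45,   # 13 ring mcp
      33,  28,   # 14 ring pip
      36,  18,   # 15 ring dip
      39,  12,   # 16 ring tip
      48,  55,   # 17 pinky mcp
      52,  42,   # 18 pinky pip
      55,  34,   # 19 pinky dip
      58,  28),  # 20 pinky tip
    nrow = 2))
}

# build a landmark_frame for hand center `pos`, aperture `ap`, with
# per-landmark tremor noise (draws happen on the provider's RNG stream)
synth_frame <- function(t, pos, ap, tremor_sd, stream, handedness) {
  pts <- hand_template() + matrix(pos, nrow = 21, ncol = 2, byrow = TRUE)
  pts[5, ] <- pos + c(-ap / 2, 0)
  pts[9, ] <- pos + c(ap / 2, 0)
  # drawn unconditionally (sd 0 gives zeros) so the noise stream advances
  # identically at every tremor level: grid contrasts stay paired
  pts <- pts + matrix(stats::rnorm(42, 0, tremor_sd), ncol = 2)
  norm <- cbind(pmin(pmax(pts[, 1] / stream$frame_width, 0), 1),
                pmin(pmax(pts[, 2] / stream$frame_height, 0), 1),
                seq(-0.02, 0.02, length.out = 21))
  landmark_frame(t, norm, handedness = handedness)
}

#' Closed-loop provider simulating a subject performing the test
#'
#' Satisfies the provider contract of [run_trial()]: each call receives
#' the published arena observation and returns the next landmark frame.
#' The virtual hand reaches the current block, dwells for the reaction
#' lag, closes the pinch, carries the block up to the carry height,
#' across the divider and down to a drop point in the target compartment,
#' opens, and repeats. Deterministic per seed.
#'
#' @param subject A [subject_model()].
#' @param cfg A [session_config()].
#' @param seed Integer seed for tremor and pinch-reliability noise.
#' @return A provider function.
#' @export
simulated_subject_provider <- function(subject, cfg, seed = 1) {
  stream <- cfg$stream
  layout <- cfg$layout
  geom <- sim_geometry(subject, layout)
  fps <- stream$fps_nominal
  step_len <- subject$reach_speed / fps
  lag_frames_total <- round(subject$reaction_lag * fps)
  handedness <- cfg$arena$assessed_side
  rng_tremor <- rng_stream(derive_seed(seed, 1))
  rng_rel <- rng_stream(derive_seed(seed, 2))

  retry_frames <- round(subject$grasp_retry_penalty * fps)

  e <- new.env(parent = emptyenv())
  e$k <- 0L
  e$phase <- "REACH"
  e$pos <- if (is.null(subject$start_position)) geom$drop
           else as.numeric(subject$start_position)
  e$waypoints <- NULL
  e$lag_left <- lag_frames_total
  e$cooldown <- 0L
  e$attempted <- FALSE

  function(obs = NULL) {
    t <- e$k / fps
    e$k <- e$k + 1L
    blk <- obs$block

    # phase transitions driven by the previous frame's arena response
    if (e$phase == "GRASP" && !is.null(blk) && blk$state == "GRABBED") {
      e$phase <- "CARRY"
      e$attempted <- FALSE
      e$waypoints <- list(c(e$pos[1], geom$y_carry),
                          c(geom$drop[1], geom$y_carry),
                          geom$drop)
    } else if (e$phase %in% c("CARRY", "RELEASE") &&
               (is.null(blk) || blk$state != "GRABBED")) {
      e$phase <- "REACH"
      e$lag_left <- lag_frames_total
    } else if (e$phase == "GRASP" && e$attempted) {
      # previous attempt did not register a grab: fumbled grasp
      e$cooldown <- retry_frames
      e$attempted <- FALSE
    }
    if (e$phase == "REACH" && !is.null(blk) &&
        isTRUE(all(abs(e$pos - blk$center) < 1e-9))) {
      if (e$lag_left > 0) e$lag_left <- e$lag_left - 1L
      else { e$phase <- "GRASP"; e$cooldown <- 0L; e$attempted <- FALSE }
    }
    if (e$phase == "CARRY" && length(e$waypoints) == 0) e$phase <- "RELEASE"

    # action: move and command the aperture
    target <- switch(e$phase,
                     REACH = if (is.null(blk)) NULL else blk$center,
                     CARRY = if (length(e$waypoints)) e$waypoints[[1]] else NULL,
                     NULL)
    if (!is.null(target)) {
      d <- euclidean_distance(e$pos, target)
      if (d <= step_len) {
        e$pos <- as.numeric(target)
        if (e$phase == "CARRY") e$waypoints <- e$waypoints[-1]
      } else {
        e$pos <- e$pos + step_len * (as.numeric(target) - e$pos) / d
      }
    }
    closed <- if (e$phase == "CARRY") TRUE
    else if (e$phase == "GRASP") {
      if (e$cooldown > 0) { e$cooldown <- e$cooldown - 1L; FALSE }
      else {
        e$attempted <- TRUE
        with_rng_stream(rng_rel,
          subject$pinch_close_reliability >= 1 ||
            stats::runif(1) < subject$pinch_close_reliability)
      }
    } else FALSE
    ap <- if (closed) subject$aperture_closed else subject$aperture_open
    with_rng_stream(rng_tremor,
      synth_frame(t, e$pos, ap, subject$tremor_sd, stream, handedness))
  }
}

#' Simulate a full trial and record its landmark stream
#'
#' Runs the closed-loop simulated subject through [run_trial()] and
#' returns both the recorded landmark stream (replayable through the
#' engine for bit-identical results) and the trial result.
#'
#' @inheritParams simulated_subject_provider
#' @return List with `frames` (the landmark stream, including the final
#'   past-cutoff frame that closes the trial) and `result` (the
#'   `trial_result`).
#' @export
simulate_trial_stream <- function(subject, cfg, seed = 1) {
  provider <- simulated_subject_provider(subject, cfg, seed)
  rec <- new.env(parent = emptyenv())
  rec$frames <- list()
  recording <- function(obs = NULL) {
    f <- provider(obs)
    if (!is.null(f)) rec$frames[[length(rec$frames) + 1L]] <- f
    f
  }
  result <- run_trial(recording, cfg)
  list(frames = rec$frames, result = result)
}

#' Mean trial score across a grid of impairment parameters
#'
#' Simulates `replicates` trials at every combination of tremor and
#' pinch-reliability values and reports the mean and SD of the score,
#' with simple monotonicity diagnostics along each axis. Useful for
#' studying why scores on the AR version of the test sit well below
#' scores on the physical test.
#'
#' @param tremor_sd_grid,reliability_grid Numeric vectors of parameter
#'   values.
#' @param cfg A [session_config()].
#' @param subject Base [subject_model()] whose tremor/reliability fields
#'   are overridden at each grid point.
#' @param replicates Trials per grid point (distinct derived seeds).
#' @param seed Master seed.
#' @return Data.frame with columns `tremor_sd`, `pinch_close_reliability`,
#'   `mean_score`, `sd_score`, `replicates`; attribute `monotone`
#'   reports whether mean score is non-increasing in tremor and
#'   non-decreasing in reliability across the grid.
#' @export
score_vs_impairment_curve <- function(tremor_sd_grid, reliability_grid,
                                      cfg = session_config(),
                                      subject = subject_model(),
                                      replicates = 5, seed = 1) {
  grid <- expand.grid(tremor_sd = tremor_sd_grid,
                      pinch_close_reliability = reliability_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    subj <- subject
    subj$tremor_sd <- grid$tremor_sd[i]
    subj$pinch_close_reliability <- grid$pinch_close_reliability[i]
    # common random numbers across grid points: replicate r shares its
    # arena and noise seeds at every (tremor, reliability) combination,
    # so grid contrasts are paired
    scores <- vapply(seq_len(replicates), function(r) {
      cfg_r <- cfg
      cfg_r$arena$seed <- derive_seed(seed, r)
      run_trial(simulated_subject_provider(subj, cfg_r,
                                           seed = derive_seed(seed, 100000 + r)),
                cfg_r)$score
    }, numeric(1))
    c(mean_score = mean(scores), sd_score = stats::sd(scores))
  })
  out <- cbind(grid, do.call(rbind, res), replicates = replicates)
  mono_tremor <- all(vapply(reliability_grid, function(p) {
    m <- out$mean_score[out$pinch_close_reliability == p][order(tremor_sd_grid)]
    all(diff(m) <= 1e-9)
  }, logical(1)))
  mono_rel <- all(vapply(tremor_sd_grid, function(s) {
    m <- out$mean_score[out$tremor_sd == s][order(reliability_grid)]
    all(diff(m) >= -1e-9)
  }, logical(1)))
  attr(out, "monotone") <- c(tremor = mono_tremor, reliability = mono_rel)
  out
}
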