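# Timed trials and the clinical protocol: per-frame stepping, the
# 60-second clock, familiarization repetitions, HUD state, kinematics
# extraction and trial reports. The clock is driven by frame timestamps,
# not frame counts, so processing jitter in a recorded stream cannot
# distort the 60-second window.

#' Session configuration
#'
#' @param trial_duration Trial length, seconds (60 as in the standard
#'   test).
#' @param familiarization_trials Practice trials preceding the assessment
#'   trial (the protocol uses five).
#' @param session_name Free-text label shown on the HUD.
#' @param stream A [stream_config()].
#' @param arena An [arena_config()].
#' @param pinch A [pinch_config()]; default scales with the stream width.
#' @param layout A [box_layout()]; default from [default_box_layout()].
#' @return A `session_config` object.
#' @export
session_config <- function(trial_duration = 60, familiarization_trials = 5,
                           session_name = "AR-BBT", stream = stream_config(),
                           arena = arena_config(),
                           pinch = default_pinch_config(stream),
                           layout = default_box_layout(stream, arena)) {
  stopifnot(trial_duration > 0, familiarization_trials >= 0)
  structure(list(trial_duration = trial_duration,
                 familiarization_trials = as.integer(familiarization_trials),
                 session_name = session_name, stream = stream,
                 arena = arena, pinch = pinch, layout = layout),
            class = "session_config")
}

#' Initialise a trial
#'
#' @param cfg A [session_config()].
#' @return A fresh trial state (clock at 0, first block spawned, pinch
#'   open).
#' @export
trial_init <- function(cfg) {
  list(elapsed = 0, last_t = -Inf, finished = FALSE,
       pinch_closed = FALSE, tracked_label = NULL,
       arena = arena_init(cfg$arena, cfg$layout, time = 0),
       samples = list(),
       counts = c(grabs = 0L, drops = 0L, divider_collisions = 0L,
                  clamps = 0L, unfinished_at_cutoff = 0L))
}

#' HUD state for a trial
#'
#' The heads-up display is pure state — session name, clock, score and
#' divider visibility — rendered (with a transparency filter over the
#' camera image) only by an optional display layer outside this package.
#'
#' @param state Trial state.
#' @param cfg A [session_config()].
#' @return List with `session_name`, `clock`, `score`, `divider_visible`.
#' @export
hud_state <- function(state, cfg) {
  list(session_name = cfg$session_name,
       clock = sprintf("%05.1f", max(cfg$trial_duration - state$elapsed, 0)),
       score = state$arena$score, divider_visible = TRUE)
}

#' Advance a trial by one frame
#'
#' A pure transition: update the hysteretic pinch state, apply the arena
#' rules (grab, carry + divider collision, release, respawn), then advance
#' the clock to the frame timestamp. Hand-absent frames advance the clock
#' only. A frame stamped at or beyond the trial duration marks the trial
#' finished and is not applied.
#'
#' @param state Trial state from [trial_init()].
#' @param frame A [landmark_frame()], a [hand_absent()] marker, or a list
#'   of simultaneous candidate frames (the first-detected hand is tracked,
#'   stickily, when several are present).
#' @param cfg A [session_config()].
#' @return Updated trial state.
#' @export
trial_step <- function(state, frame, cfg) {
  if (is.list(frame) && !inherits(frame, c("landmark_frame", "hand_absent"))) {
    ts <- unique(vapply(frame, frame_time, numeric(1)))
    if (length(ts) != 1) stop("candidate frames must share one timestamp")
    chosen <- select_primary_hand(frame, state$tracked_label)
    frame <- if (is.null(chosen)) hand_absent(ts) else chosen
  }
  t <- frame_time(frame)
  if (t <= state$last_t)
    stop(sprintf("out-of-order frame: t=%.6f after t=%.6f", t, state$last_t))
  state$last_t <- t
  if (t >= cfg$trial_duration) {
    state$finished <- TRUE
    state$elapsed <- cfg$trial_duration
    return(state)
  }
  state$elapsed <- t
  if (is_hand_absent(frame)) {
    state$tracked_label <- NULL
    return(state)
  }
  state$tracked_label <- frame$handedness

  closed <- pinch_closed(frame, cfg$stream, cfg$pinch, state$pinch_closed)
  state$pinch_closed <- closed
  tips <- fingertips(frame, cfg$stream)

  n_ev <- length(state$arena$events)
  state$arena <- arena_step(state$arena, tips, closed, t)
  new_ev <- state$arena$events[seq_len(length(state$arena$events) - n_ev) + n_ev]
  for (e in new_ev) {
    key <- switch(e$kind, GRAB = "grabs", DROP = "drops",
                  DIVIDER_COLLISION = "divider_collisions",
                  CLAMP = "clamps", NULL)
    if (!is.null(key)) state$counts[key] <- state$counts[key] + 1L
  }

  # carry-point samples feed the per-transfer kinematics
  active <- state$arena$active_id
  grabbed_now <- !is.na(active) &&
    state$arena$blocks[[active]]$state == "GRABBED"
  released_now <- any(vapply(new_ev, function(e)
    e$kind %in% c("SCORE", "DROP", "DIVIDER_COLLISION"), logical(1)))
  if (grabbed_now || released_now) {
    mid <- (tips$thumb + tips$index) / 2
    bid <- if (grabbed_now) active else new_ev[[1]]$block_id
    state$samples[[length(state$samples) + 1L]] <-
      list(t = t, x = unname(mid[1]), y = unname(mid[2]),
           aperture = euclidean_distance(tips$thumb, tips$index),
           block_id = as.integer(bid))
  }
  state
}

samples_df <- function(samples) {
  if (length(samples) == 0)
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      aperture = numeric(0), block_id = integer(0)))
  data.frame(t = vapply(samples, `[[`, numeric(1), "t"),
             x = vapply(samples, `[[`, numeric(1), "x"),
             y = vapply(samples, `[[`, numeric(1), "y"),
             aperture = vapply(samples, `[[`, numeric(1), "aperture"),
             block_id = vapply(samples, `[[`, integer(1), "block_id"))
}

#' Run one timed trial
#'
#' Folds [trial_step()] over the provider's frames until the trial clock
#' reaches the configured duration or the stream ends. A block still held
#' at cutoff is recorded in the counts but never scored.
#'
#' @param provider A provider function (see [stream_provider()]) or a
#'   plain list of frames. Closed-loop providers receive an observation
#'   list (`elapsed`, `score`, `pinch_closed`, `block`) each call.
#' @param cfg A [session_config()].
#' @return A `trial_result`: score, duration, per-transfer kinematics,
#'   event counts, event log, config echo and seed.
#' @export
run_trial <- function(provider, cfg) {
  if (!is.function(provider)) provider <- stream_provider(provider)
  state <- trial_init(cfg)
  n_frames <- 0L
  repeat {
    frame <- provider(trial_observation(state))
    if (is.null(frame)) break
    n_frames <- n_frames + 1L
    state <- trial_step(state, frame, cfg)
    if (state$finished) break
  }
  empty <- n_frames == 0L
  if (empty) warning("empty landmark stream: zero-score trial")
  active <- state$arena$active_id
  if (!is.na(active) && state$arena$blocks[[active]]$state == "GRABBED")
    state$counts["unfinished_at_cutoff"] <- 1L
  events <- arena_events(state$arena)
  samples <- samples_df(state$samples)
  transfers <- extract_kinematics(events, samples)
  structure(list(score = state$arena$score,
                 duration = cfg$trial_duration,
                 transfers = transfers,
                 counts = as.list(state$counts),
                 events = events,
                 samples = samples,
                 seed = cfg$arena$seed,
                 empty_stream = empty,
                 config = list(trial_duration = cfg$trial_duration,
                               blocks_total = cfg$arena$blocks_total,
                               assessed_side = cfg$arena$assessed_side,
                               grab_threshold = cfg$pinch$grab_threshold,
                               release_threshold = cfg$pinch$release_threshold,
                               frame_width = cfg$stream$frame_width,
                               frame_height = cfg$stream$frame_height)),
            class = "trial_result")
}

# what a closed-loop provider may observe: published arena state only
trial_observation <- function(state) {
  active <- state$arena$active_id
  block <- if (is.na(active)) NULL else {
    b <- state$arena$blocks[[active]]
    list(center = b$center, half_size = b$half_size, state = b$state, id = b$id)
  }
  list(elapsed = state$elapsed, score = state$arena$score,
       pinch_closed = state$pinch_closed, block = block)
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("AR-BBT trial: %d blocks in %g s\n", x$score, x$duration))
  cat(sprintf("  grabs %d, drops %d, divider collisions %d, held at cutoff %d\n",
              x$counts$grabs, x$counts$drops, x$counts$divider_collisions,
              x$counts$unfinished_at_cutoff))
  if (nrow(x$transfers) > 0)
    cat(sprintf("  mean transfer %.2f s, mean path %.0f px, peak speed %.0f px/s\n",
                mean(x$transfers$transfer_duration),
                mean(x$transfers$path_length), max(x$transfers$peak_speed)))
  invisible(x)
}

#' Per-transfer kinematics from an event log and carry samples
#'
#' For each scored transfer (the span from the last GRAB of a block to
#' its SCORE), computes the transfer duration, the fingertip-midpoint
#' path length (sum of successive displacements), the peak speed
#' (maximum displacement over inter-sample time) and the mean pinch
#' aperture over the carried span. Spans unmatched at trial cutoff are
#' excluded (they appear in the trial counts instead).
#'
#' @param events Event data.frame from [arena_events()].
#' @param samples Data.frame of carry samples with columns `t`, `x`, `y`,
#'   `aperture`, `block_id`.
#' @return Data.frame, one row per scored transfer: `block_id`,
#'   `start_time`, `end_time`, `transfer_duration`, `path_length`,
#'   `peak_speed`, `mean_pinch_aperture`.
#' @export
extract_kinematics <- function(events, samples) {
  out <- data.frame(block_id = integer(0), start_time = numeric(0),
                    end_time = numeric(0), transfer_duration = numeric(0),
                    path_length = numeric(0), peak_speed = numeric(0),
                    mean_pinch_aperture = numeric(0))
  scores <- events[events$kind == "SCORE", , drop = FALSE]
  if (nrow(scores) == 0) return(out)
  for (i in seq_len(nrow(scores))) {
    id <- scores$block_id[i]; t_end <- scores$time[i]
    grabs <- events[events$kind == "GRAB" & events$block_id == id &
                      events$time <= t_end, , drop = FALSE]
    if (nrow(grabs) == 0) next
    t_start <- max(grabs$time)
    sp <- samples[samples$block_id == id & samples$t >= t_start &
                    samples$t <= t_end, , drop = FALSE]
    if (nrow(sp) < 2) {
      path <- 0; peak <- 0
    } else {
      dx <- diff(sp$x); dy <- diff(sp$y); dt <- diff(sp$t)
      seg <- sqrt(dx^2 + dy^2)
      path <- sum(seg)
      peak <- max(seg / dt)
    }
    out[nrow(out) + 1L, ] <-
      list(as.integer(id), t_start, t_end, t_end - t_start, path, peak,
           if (nrow(sp) > 0) mean(sp$aperture) else NA_real_)
  }
  out
}

trial_seed <- function(cfg, trial_index) {
  derive_seed(cfg$arena$seed, 1000000 + trial_index)
}

#' Run the clinical protocol: familiarization trials plus one assessment
#'
#' Executes `familiarization_trials` practice trials followed by a single
#' assessment trial; only the assessment score is the reported AR-BBT
#' score, but every trial is returned. Each trial uses a distinct seed
#' derived from the session seed and the trial index, so spawn sequences
#' differ across trials yet reproduce exactly across runs.
#'
#' @param provider_factory Function `(trial_index, trial_seed)` returning
#'   a fresh provider for that trial (e.g. wrapping
#'   [simulated_subject_provider()]).
#' @param cfg A [session_config()].
#' @return List with `familiarization` (list of `trial_result`s) and
#'   `assessment` (one `trial_result`).
#' @export
run_protocol <- function(provider_factory, cfg) {
  run_one <- function(i) {
    s <- trial_seed(cfg, i)
    cfg_i <- cfg
    cfg_i$arena$seed <- s
    run_trial(provider_factory(i, s), cfg_i)
  }
  fam <- lapply(seq_len(cfg$familiarization_trials), run_one)
  assessment <- run_one(cfg$familiarization_trials + 1L)
  list(familiarization = fam, assessment = assessment)
}

# ---- trial-result serialization --------------------------------------

#' Write a trial result as JSON
#' @param result A `trial_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_result <- function(result, path) {
  doc <- unclass(result)
  doc$events <- lapply(seq_len(nrow(result$events)),
                       function(i) as.list(result$events[i, ]))
  doc$samples <- lapply(seq_len(nrow(result$samples)),
                        function(i) as.list(result$samples[i, ]))
  doc$transfers <- lapply(seq_len(nrow(result$transfers)),
                          function(i) as.list(result$transfers[i, ]))
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             path)
  invisible(path)
}

#' Read a trial result written by [write_trial_result()]
#' @param path JSON path.
#' @return A `trial_result`.
#' @export
read_trial_result <- function(path) {
  doc <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyDataFrame = TRUE)
  rebuild <- function(x, template) {
    if (is.data.frame(x) && nrow(x) > 0) x
    else template
  }
  empty_events <- arena_events(list(events = list()))
  doc$events <- rebuild(doc$events, empty_events)
  doc$samples <- rebuild(doc$samples, samples_df(list()))
  doc$transfers <- rebuild(doc$transfers, extract_kinematics(empty_events,
                                                             samples_df(list())))
  doc$score <- as.integer(doc$score)
  doc$events$block_id <- as.integer(doc$events$block_id)
  doc$samples$block_id <- as.integer(doc$samples$block_id)
  structure(doc, class = "trial_result")
}

#' Export per-transfer kinematics as CSV
#' @param result A `trial_result`.
#' @param path Output CSV path (one row per scored transfer).
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(result, path) {
  utils::write.csv(result$transfers, path, row.names = FALSE)
  invisible(path)
}
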