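# Shared fixtures: scripted landmark frames with exact fingertip control,
# and a compact session configuration whose source compartment is square
# so a maximal spawn margin collapses spawning to a single known point.

# frame with thumb/index tips at given pixel coordinates; the 19 other
# landmarks sit at a fixed valid position
tip_frame <- function(t, thumb, index, cfg = stream_config(),
                      handedness = "right") {
  lm <- matrix(rep(c(0.5, 0.9, 0), each = 21), ncol = 3)
  lm[5, 1:2] <- c(thumb[1] / cfg$frame_width, thumb[2] / cfg$frame_height)
  lm[9, 1:2] <- c(index[1] / cfg$frame_width, index[2] / cfg$frame_height)
  landmark_frame(t, lm, handedness = handedness)
}

# frames from a data.frame with columns t, tx, ty, ix, iy
scripted_stream <- function(df, cfg = stream_config()) {
  lapply(seq_len(nrow(df)), function(i)
    tip_frame(df$t[i], c(df$tx[i], df$ty[i]), c(df$ix[i], df$iy[i]), cfg))
}

# layout with a 600 x 600 px source compartment; spawn_margin = 300
# degenerates the spawn distribution to the compartment center, making
# every transfer cycle geometrically identical
point_spawn_config <- function(trial_duration = 60, fps = 60, seed = 5,
                               assessed_side = "right") {
  acfg <- arena_config(spawn_margin = 300, seed = seed,
                       assessed_side = assessed_side)
  lay <- box_layout(rect(40, 90, 1264, 690), acfg)
  session_config(trial_duration = trial_duration,
                 stream = stream_config(fps_nominal = fps),
                 arena = acfg, layout = lay)
}

# independent frame-count oracle for an ideal subject in the point-spawn
# layout: per-segment frames are ceil(distance / per-frame step), plus
# one frame to close the pinch and one to open it
ideal_cycle_frames <- function(cfg, subject) {
  s <- cfg$layout$source_compartment
  spawn <- c((s["x0"] + s["x1"]) / 2, (s["y0"] + s["y1"]) / 2)
  b <- cfg$layout$box
  h <- b["y1"] - b["y0"]
  y_carry <- b["y1"] - subject$carry_height_fraction * h
  tgt <- cfg$layout$target_compartment
  drop <- c((tgt["x0"] + tgt["x1"]) / 2, b["y1"] - 0.25 * h)
  step <- subject$reach_speed / cfg$stream$fps_nominal
  d <- c(sqrt(sum((drop - spawn)^2)),      # reach back to the spawn point
         abs(spawn[2] - y_carry),          # lift
         abs(spawn[1] - drop[1]),          # cross
         abs(y_carry - drop[2]))           # lower
  sum(ceiling(d / step)) + 2L
}

ideal_subject <- function(reach_speed = 420) {
  subject_model(reach_speed = reach_speed, tremor_sd = 0,
                pinch_close_reliability = 1, reaction_lag = 0)
}
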