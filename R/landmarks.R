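# Landmark data model, frame preprocessing, hand selection and pinch
# geometry. Coordinate convention (used throughout the package): origin at
# the top-left of the image, x rightward, y downward; pixel rectangles are
# half-open [x0, x1) x [y0, y1). The engine consumes already-mirrored
# ("selfie-view") streams; mirroring utilities are diagnostics only.

N_LANDMARKS <- 21L
THUMB_TIP <- 5L  # landmark index 4, 1-based row 5
INDEX_TIP <- 9L  # landmark index 8, 1-based row 9

#' Construct a single hand-landmark observation
#'
#' One timestamped observation of a tracked hand: 21 landmarks following
#' the standard hand topology (wrist = 0, thumb tip = 4, index-finger
#' tip = 8), each with normalized image coordinates `x, y` in `[0, 1]`
#' and a relative depth `z` (dimensionless, smaller = closer to camera).
#'
#' @param t Time in seconds from stream start (non-negative).
#' @param landmarks Numeric 21 x 3 matrix (columns x, y, z) or 21 x 2
#'   (z assumed 0).
#' @param handedness `"left"` or `"right"`.
#' @param confidence Detection confidence in `[0, 1]`.
#' @return A `landmark_frame` object.
#' @export
landmark_frame <- function(t, landmarks, handedness = "right", confidence = 1) {
  stopifnot(is.numeric(t), length(t) == 1, t >= 0, is.matrix(landmarks))
  if (ncol(landmarks) == 2) landmarks <- cbind(landmarks, 0)
  if (nrow(landmarks) != N_LANDMARKS || ncol(landmarks) != 3)
    stop("landmarks must be a 21 x 3 matrix (x, y, z)")
  xy <- landmarks[, 1:2]
  if (any(!is.finite(xy)) || any(xy < 0) || any(xy > 1))
    stop("landmark x,y must be finite and within [0, 1]")
  handedness <- match.arg(handedness, c("left", "right"))
  stopifnot(confidence >= 0, confidence <= 1)
  structure(
    list(t = as.numeric(t), handedness = handedness,
         confidence = as.numeric(confidence),
         landmarks = unname(landmarks)),
    class = "landmark_frame")
}

#' Mark a timestamp at which no hand was detected
#'
#' Hand-absent frames freeze the arena state while the trial clock keeps
#' running, matching a timed test in which the hand leaves the camera view.
#'
#' @param t Time in seconds from stream start.
#' @return A `hand_absent` marker usable anywhere a frame is.
#' @export
hand_absent <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1, t >= 0)
  structure(list(t = as.numeric(t)), class = "hand_absent")
}

is_hand_absent <- function(frame) inherits(frame, "hand_absent")

frame_time <- function(frame) frame$t

#' Stream configuration
#'
#' @param frame_width,frame_height Image size in pixels; defaults to 720p
#'   (1280 x 720). A 480p fallback (854 x 480) is equally supported.
#' @param fps_nominal Nominal frame rate in frames/second.
#' @param mirror Whether the stream is selfie-view mirrored (informational;
#'   the engine assumes streams arrive already mirrored).
#' @return A `stream_config` object.
#' @export
stream_config <- function(frame_width = 1280, frame_height = 720,
                          fps_nominal = 60, mirror = TRUE) {
  stopifnot(frame_width > 0, frame_height > 0, fps_nominal > 0)
  structure(list(frame_width = frame_width, frame_height = frame_height,
                 fps_nominal = fps_nominal, mirror = isTRUE(mirror)),
            class = "stream_config")
}

#' Pinch-gesture thresholds
#'
#' A pinch closes when the thumb-tip/index-tip distance drops strictly
#' below `grab_threshold` and reopens only when it reaches
#' `release_threshold` (hysteresis, so a fingertip distance jittering
#' between the two never toggles the state). Defaults are proportional to
#' frame width — 0.05 x width (64 px at 1280) — which approximates a
#' fingertip pinch with the hand about 50 cm from a typical webcam.
#'
#' @param grab_threshold Pixels; pinch closes below this.
#' @param release_threshold Pixels; pinch opens at or above this. Must be
#'   `>= grab_threshold`.
#' @return A `pinch_config` object.
#' @export
pinch_config <- function(grab_threshold = 64, release_threshold = 1.25 * grab_threshold) {
  stopifnot(grab_threshold > 0, release_threshold >= grab_threshold)
  structure(list(grab_threshold = grab_threshold,
                 release_threshold = release_threshold),
            class = "pinch_config")
}

#' Default pinch thresholds for a stream resolution
#'
#' @param cfg A [stream_config()].
#' @return A [pinch_config()] scaled to the frame width.
#' @export
default_pinch_config <- function(cfg = stream_config()) {
  g <- 0.05 * cfg$frame_width
  pinch_config(grab_threshold = g, release_threshold = 1.25 * g)
}

#' Convert normalized landmarks to pixel coordinates
#'
#' @param frame A [landmark_frame()].
#' @param cfg A [stream_config()].
#' @return A 21 x 2 matrix of pixel points `(x * width, y * height)`.
#' @export
to_pixels <- function(frame, cfg) {
  stopifnot(inherits(frame, "landmark_frame"), inherits(cfg, "stream_config"))
  cbind(frame$landmarks[, 1] * cfg$frame_width,
        frame$landmarks[, 2] * cfg$frame_height)
}

#' Euclidean distance between two pixel points
#'
#' @param p,q Numeric length-2 vectors.
#' @return Non-negative distance in pixels.
#' @export
euclidean_distance <- function(p, q) {
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

# thumb/index fingertip pixel positions for a frame
fingertips <- function(frame, cfg) {
  px <- to_pixels(frame, cfg)
  list(thumb = px[THUMB_TIP, ], index = px[INDEX_TIP, ])
}

#' Pinch aperture of a frame, in pixels
#'
#' @inheritParams to_pixels
#' @return Thumb-tip to index-tip Euclidean distance in pixels.
#' @export
pinch_aperture <- function(frame, cfg) {
  tips <- fingertips(frame, cfg)
  euclidean_distance(tips$thumb, tips$index)
}

#' Hysteretic pinch state update
#'
#' When the pinch is open it closes iff the fingertip distance is strictly
#' less than `grab_threshold`; when closed it opens only once the distance
#' reaches `release_threshold`.
#'
#' @inheritParams to_pixels
#' @param pinch A [pinch_config()].
#' @param currently_closed Logical, the pinch state before this frame.
#' @return Logical: is the pinch closed after seeing this frame?
#' @export
pinch_closed <- function(frame, cfg, pinch, currently_closed = FALSE) {
  d <- pinch_aperture(frame, cfg)
  if (currently_closed) d < pinch$release_threshold else d < pinch$grab_threshold
}

#' Select the primary hand among simultaneous detections
#'
#' Only one hand is tracked. The first-detected hand is kept ("sticky")
#' for as long as a candidate with its handedness label is present; once
#' lost, tracking re-latches onto the first hand of the next detection.
#'
#' @param candidates List of [landmark_frame()]s sharing a timestamp
#'   (possibly empty).
#' @param current_label Handedness label currently tracked, or `NULL` if
#'   no hand is being tracked.
#' @return The selected `landmark_frame`, or `NULL` for "no hand".
#' @export
select_primary_hand <- function(candidates, current_label = NULL) {
  if (length(candidates) == 0) return(NULL)
  if (!is.null(current_label)) {
    labels <- vapply(candidates, function(f) f$handedness, character(1))
    hit <- which(labels == current_label)
    if (length(hit) > 0) return(candidates[[hit[1]]])
  }
  candidates[[1]]
}

#' Flip an image horizontally
#'
#' Column `j` maps to column `width - 1 - j`; applying the flip twice
#' restores the input. Used to turn a raw camera view into the mirrored
#' selfie view the test is played in.
#'
#' @param image Numeric matrix (rows = image rows, columns = image columns).
#' @return The horizontally mirrored matrix.
#' @export
flip_horizontal <- function(image) {
  stopifnot(is.matrix(image))
  image[, rev(seq_len(ncol(image))), drop = FALSE]
}

#' Mirror-consistency diagnostic score
#'
#' Measures how well `flipped` matches a horizontal mirror of `original`:
#' the minimum over integer horizontal shifts `s` in `[-max_shift,
#' max_shift]` of the mean absolute pixel difference between `original`
#' and the shifted `flipped`, compared over the overlapping columns. A
#' perfectly mirrored pair scores 0.
#'
#' @param original,flipped Equal-dimension numeric matrices.
#' @param max_shift Maximum horizontal shift searched, in pixels.
#' @return Non-negative score (0 = perfect mirror at some shift).
#' @export
mirror_consistency <- function(original, flipped, max_shift = 0) {
  stopifnot(is.matrix(original), is.matrix(flipped))
  if (!all(dim(original) == dim(flipped)))
    stop("original and flipped must have identical dimensions")
  w <- ncol(original)
  ref <- flip_horizontal(flipped)  # undo the flip; compare against original
  best <- Inf
  for (s in seq.int(-max_shift, max_shift)) {
    if (abs(s) >= w) next
    if (s >= 0) { a <- original[, (1 + s):w, drop = FALSE]
                  b <- ref[, 1:(w - s), drop = FALSE] }
    else        { a <- original[, 1:(w + s), drop = FALSE]
                  b <- ref[, (1 - s):w, drop = FALSE] }
    best <- min(best, mean(abs(a - b)))
  }
  best
}
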