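# Landmark-stream files: JSON Lines, one frame per line with keys
# t (seconds), hand ("left"/"right"), conf, pts (21 [x, y, z] triples in
# normalized coordinates). A line with "pts": null records a timestamp at
# which no hand was detected. Reader validates all frame invariants;
# writer round-trips bit-faithfully.

# numbers are printed with %.17g so that write -> read restores every
# double bit-for-bit (jsonlite's own numeric formatting loses the last ulp)
num17 <- function(x) sub("^(-?)(\\.)", "\\10\\2", sprintf("%.17g", x))

frame_to_json <- function(frame) {
  if (is_hand_absent(frame)) {
    return(sprintf('{"t":%s,"pts":null}', num17(frame$t)))
  }
  rows <- apply(frame$landmarks, 1, function(p)
    paste0("[", paste(num17(p), collapse = ","), "]"))
  sprintf('{"t":%s,"hand":"%s","conf":%s,"pts":[%s]}',
          num17(frame$t), frame$handedness, num17(frame$confidence),
          paste(rows, collapse = ","))
}

json_to_frame <- function(line) {
  rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
  if (is.null(rec$pts)) return(hand_absent(rec$t))
  pts <- rec$pts
  if (is.list(pts)) pts <- do.call(rbind, pts)
  landmark_frame(rec$t, pts, handedness = rec$hand, confidence = rec$conf)
}

#' Write a landmark stream to a JSONL file
#'
#' @param frames List of [landmark_frame()] / [hand_absent()] values,
#'   time-ordered.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_stream <- function(frames, path) {
  lines <- vapply(frames, function(f) as.character(frame_to_json(f)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a landmark stream from a JSONL file
#'
#' Validates every frame invariant (21 landmarks, coordinates in
#' `[0, 1]`) and that timestamps strictly increase.
#'
#' @param path JSONL file written by [write_landmark_stream()] or any
#'   conforming producer.
#' @return List of frames.
#' @export
read_landmark_stream <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  frames <- lapply(lines, json_to_frame)
  ts <- vapply(frames, frame_time, numeric(1))
  if (length(ts) > 1 && any(diff(ts) <= 0))
    stop("timestamps must be strictly increasing within a stream")
  frames
}

#' A list-backed landmark provider
#'
#' Wraps a fixed sequence of frames as a provider: any source yielding
#' time-ordered frames (a recorded file, the simulator, a live adapter)
#' satisfies the same contract and is interchangeable. A provider is a
#' function `f(observation)` returning the next frame or `NULL` at end of
#' stream; open-loop providers ignore the observation.
#'
#' @param frames List of frames, or a path to a JSONL stream.
#' @return A provider function.
#' @export
stream_provider <- function(frames) {
  if (is.character(frames)) frames <- read_landmark_stream(frames)
  i <- 0L
  function(observation = NULL) {
    i <<- i + 1L
    if (i > length(frames)) NULL else frames[[i]]
  }
}
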