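# The virtual box-and-blocks world: layout geometry, block lifecycle
# (RESTING -> GRABBED -> SCORED / VANISHED), grab/carry/release rules,
# divider collision, out-of-bounds clamping and scoring. One block is
# live at a time; 150 blocks are spawned individually over a trial.

#' Axis-aligned pixel rectangle
#'
#' Rectangles are half-open, `[x0, x1) x [y0, y1)`, origin top-left,
#' y downward.
#'
#' @param x0,y0,x1,y1 Edges in pixels, `x0 < x1`, `y0 < y1`.
#' @return Named numeric vector with class `rect`.
#' @export
rect <- function(x0, y0, x1, y1) {
  stopifnot(x0 < x1, y0 < y1)
  structure(c(x0 = unname(x0), y0 = unname(y0),
              x1 = unname(x1), y1 = unname(y1)), class = "rect")
}

#' Point membership in a half-open rectangle
#' @param r A [rect()].
#' @param p Length-2 numeric point (x, y).
#' @return Logical.
#' @export
rect_contains <- function(r, p) {
  p[1] >= r["x0"] && p[1] < r["x1"] && p[2] >= r["y0"] && p[2] < r["y1"]
}

# closed-rectangle overlap (touching edges count as contact)
rects_overlap_closed <- function(a, b) {
  a["x0"] <= b["x1"] && b["x0"] <= a["x1"] &&
    a["y0"] <= b["y1"] && b["y0"] <= a["y1"]
}

block_rect <- function(block) {
  rect(block$center[1] - block$half_size, block$center[2] - block$half_size,
       block$center[1] + block$half_size, block$center[2] + block$half_size)
}

BLOCK_COLORS <- c("red", "green", "blue", "yellow")

#' Arena configuration
#'
#' @param blocks_total Number of virtual cubes available over a trial
#'   (150, as in the physical test's 150 one-inch cubes).
#' @param block_half_size Half the cube's on-screen edge, pixels. The
#'   default 30 px at 720p corresponds to roughly a 1-inch cube seen by a
#'   typical webcam with the hand about 50 cm away.
#' @param divider_width Width of the central partition band, pixels.
#' @param divider_top_fraction Height of the partition as a fraction of
#'   box height, measured from the box bottom.
#' @param assessed_side `"left"` or `"right"`: the hemiplegic (assessed)
#'   hand. Blocks spawn in the compartment adjacent to that hand.
#' @param spawn_margin Inset, in pixels, applied to the source compartment
#'   when drawing spawn positions; `NULL` = `block_half_size + 8` so
#'   spawned cubes lie wholly inside the compartment.
#' @param seed Integer seed driving spawn positions and colors.
#' @return An `arena_config` object.
#' @export
arena_config <- function(blocks_total = 150, block_half_size = 30,
                         divider_width = 24, divider_top_fraction = 0.55,
                         assessed_side = "right", spawn_margin = NULL,
                         seed = 1) {
  stopifnot(blocks_total >= 1, block_half_size > 0, divider_width > 0,
            divider_top_fraction > 0, divider_top_fraction < 1)
  assessed_side <- match.arg(assessed_side, c("left", "right"))
  if (is.null(spawn_margin)) spawn_margin <- block_half_size + 8
  structure(list(blocks_total = as.integer(blocks_total),
                 block_half_size = block_half_size,
                 divider_width = divider_width,
                 divider_top_fraction = divider_top_fraction,
                 assessed_side = assessed_side,
                 spawn_margin = spawn_margin,
                 seed = as.integer(seed)),
            class = "arena_config")
}

#' Box layout: play area, divider band and compartments
#'
#' The divider is a vertical band centered on the box midline rising from
#' the box bottom to `divider_top_fraction` of the box height, so a
#' transfer must arc over its top. The source compartment (where blocks
#' spawn) is the one adjacent to the assessed hand; the other compartment
#' is the scoring target.
#'
#' @param box A [rect()]: the full play area.
#' @param cfg An [arena_config()].
#' @return A `box_layout` with elements `box`, `divider`,
#'   `source_compartment`, `target_compartment`, `divider_top`,
#'   `spawn_margin`.
#' @export
box_layout <- function(box, cfg) {
  stopifnot(inherits(box, "rect"), inherits(cfg, "arena_config"))
  cx <- (box["x0"] + box["x1"]) / 2
  h <- box["y1"] - box["y0"]
  divider_top <- box["y1"] - cfg$divider_top_fraction * h
  divider <- rect(cx - cfg$divider_width / 2, divider_top,
                  cx + cfg$divider_width / 2, box["y1"])
  left <- rect(box["x0"], box["y0"], cx - cfg$divider_width / 2, box["y1"])
  right <- rect(cx + cfg$divider_width / 2, box["y0"], box["x1"], box["y1"])
  if (cfg$assessed_side == "right") { src <- right; tgt <- left }
  else { src <- left; tgt <- right }
  structure(list(box = box, divider = divider, divider_top = divider_top,
                 source_compartment = src, target_compartment = tgt,
                 spawn_margin = cfg$spawn_margin),
            class = "box_layout")
}

#' Default layout for a stream resolution
#'
#' Places the virtual box over the lower central part of the camera view.
#'
#' @param stream A [stream_config()].
#' @param cfg An [arena_config()].
#' @return A [box_layout()].
#' @export
default_box_layout <- function(stream = stream_config(), cfg = arena_config()) {
  w <- stream$frame_width; h <- stream$frame_height
  box_layout(rect(0.05 * w, 0.30 * h, 0.95 * w, 0.95 * h), cfg)
}

#' Clamp a point into the box region
#'
#' Component-wise nearest point of the play area; identity on interior
#' points and idempotent. Keeps carried blocks inside the virtual box.
#'
#' @param p Length-2 numeric point.
#' @param layout A [box_layout()].
#' @return Clamped point.
#' @export
clamp_to_box <- function(p, layout) {
  b <- layout$box
  c(min(max(p[1], b["x0"]), b["x1"]), min(max(p[2], b["y0"]), b["y1"]),
    use.names = FALSE)
}

#' Does a block contact the divider?
#'
#' Closed-rectangle intersection between the block's square and the
#' divider band; touching edges count as contact.
#'
#' @param block A block record (fields `center`, `half_size`).
#' @param layout A [box_layout()].
#' @return Logical.
#' @export
divider_collision <- function(block, layout) {
  isTRUE(rects_overlap_closed(block_rect(block), layout$divider))
}

# ---- arena state ------------------------------------------------------

new_event <- function(time, kind, block_id, pos) {
  list(time = time, kind = kind, block_id = block_id,
       x = unname(pos[1]), y = unname(pos[2]))
}

#' Initialise an arena
#'
#' Spawns the first block. Arena state is a plain list; all updates are
#' pure transitions so identical inputs replay to bit-identical logs.
#'
#' @param cfg An [arena_config()].
#' @param layout A [box_layout()].
#' @param time Spawn timestamp for the first block, seconds.
#' @return Arena state list.
#' @export
arena_init <- function(cfg, layout, time = 0) {
  arena <- list(cfg = cfg, layout = layout, blocks = list(),
                active_id = NA_integer_, spawned = 0L, score = 0L,
                events = list())
  spawn_next_block(arena, time)
}

# Draw the next block (position seeded-uniform in the spawn region, color
# seeded-uniform over the four colors) or return the arena unchanged once
# all blocks_total have been spawned.
spawn_next_block <- function(arena, time) {
  cfg <- arena$cfg
  if (!is.na(arena$active_id))
    stop("single-block rule violated: a block is still active")
  if (arena$spawned >= cfg$blocks_total) return(arena)
  id <- arena$spawned + 1L
  s <- arena$layout$source_compartment
  m <- arena$layout$spawn_margin
  rng <- rng_stream(derive_seed(cfg$seed, id))
  draw <- with_rng_stream(rng, {
    x <- runif(1, s["x0"] + m, s["x1"] - m)
    y <- runif(1, s["y0"] + m, s["y1"] - m)
    col <- sample(BLOCK_COLORS, 1)
    list(center = c(x, y, use.names = FALSE), color = col)
  })
  block <- list(id = id, color = draw$color, center = draw$center,
                half_size = cfg$block_half_size, state = "RESTING")
  arena$blocks[[id]] <- block
  arena$active_id <- id
  arena$spawned <- id
  arena$events[[length(arena$events) + 1L]] <-
    new_event(time, "SPAWN", id, draw$center)
  arena
}

set_block <- function(arena, block) { arena$blocks[[block$id]] <- block; arena }

push_event <- function(arena, time, kind, id, pos) {
  arena$events[[length(arena$events) + 1L]] <- new_event(time, kind, id, pos)
  arena
}

#' One arena transition for one frame's hand observation
#'
#' Applies the grab / carry + divider-collision / release rules for the
#' current fingertip positions and pinch state, then spawns a replacement
#' block if the active one was scored or vanished.
#'
#' * grab: a RESTING block becomes GRABBED iff both fingertips lie inside
#'   its square and the pinch is closed;
#' * carry: a GRABBED block follows the fingertip midpoint, clamped to the
#'   box (CLAMP event when clamping changed the point), then vanishes on
#'   divider contact (DIVIDER_COLLISION event) and the next block spawns;
#' * release: when the pinch opens, a GRABBED block released with its
#'   center inside the target compartment is SCORED (+1 point, settles to
#'   the compartment floor and persists); anywhere else it returns to
#'   RESTING at the clamped drop point (DROP event) and stays grabbable.
#'
#' @param arena Arena state from [arena_init()].
#' @param tips List with `thumb` and `index` pixel points, or `NULL` when
#'   no hand was detected (state frozen).
#' @param closed Logical: pinch state after the hysteresis update.
#' @param time Frame timestamp, seconds.
#' @return Updated arena state.
#' @export
arena_step <- function(arena, tips, closed, time) {
  if (is.null(tips) || is.na(arena$active_id)) return(arena)
  block <- arena$blocks[[arena$active_id]]

  if (block$state == "RESTING") {
    if (closed) {
      br <- block_rect(block)
      if (rect_contains(br, tips$thumb) && rect_contains(br, tips$index)) {
        block$state <- "GRABBED"
        arena <- set_block(arena, block)
        arena <- push_event(arena, time, "GRAB", block$id, block$center)
      }
    }
    return(arena)
  }

  if (block$state != "GRABBED") return(arena)

  if (!closed) {                                   # release
    drop <- clamp_to_box((tips$thumb + tips$index) / 2, arena$layout)
    if (rect_contains(arena$layout$target_compartment, drop)) {
      block$state <- "SCORED"
      block$center <- c(drop[1], arena$layout$box["y1"] - block$half_size,
                        use.names = FALSE)
      arena <- set_block(arena, block)
      arena$score <- arena$score + 1L
      arena$active_id <- NA_integer_
      arena <- push_event(arena, time, "SCORE", block$id, block$center)
      arena <- spawn_next_block(arena, time)
    } else {
      block$state <- "RESTING"
      block$center <- drop
      arena <- set_block(arena, block)
      arena <- push_event(arena, time, "DROP", block$id, drop)
    }
    return(arena)
  }

  # carry
  raw <- (tips$thumb + tips$index) / 2
  pos <- clamp_to_box(raw, arena$layout)
  block$center <- pos
  arena <- set_block(arena, block)
  if (any(pos != raw))
    arena <- push_event(arena, time, "CLAMP", block$id, pos)
  if (divider_collision(block, arena$layout)) {
    block$state <- "VANISHED"
    arena <- set_block(arena, block)
    arena$active_id <- NA_integer_
    arena <- push_event(arena, time, "DIVIDER_COLLISION", block$id, pos)
    arena <- spawn_next_block(arena, time)
  }
  arena
}

#' Tabulate an arena's event log
#' @param arena Arena state (or a list of event records).
#' @return A data.frame with columns time, kind, block_id, x, y.
#' @export
arena_events <- function(arena) {
  ev <- if (is.list(arena) && !is.null(arena$events)) arena$events else arena
  if (length(ev) == 0)
    return(data.frame(time = numeric(0), kind = character(0),
                      block_id = integer(0), x = numeric(0), y = numeric(0)))
  data.frame(time = vapply(ev, `[[`, numeric(1), "time"),
             kind = vapply(ev, `[[`, character(1), "kind"),
             block_id = vapply(ev, function(e) as.integer(e$block_id), integer(1)),
             x = vapply(ev, `[[`, numeric(1), "x"),
             y = vapply(ev, `[[`, numeric(1), "y"))
}

#' Write an event log as JSON Lines
#' @param events Event data.frame from [arena_events()], an arena state,
#'   or a `trial_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  if (inherits(events, "trial_result")) events <- events$events
  if (!is.data.frame(events)) events <- arena_events(events)
  lines <- vapply(seq_len(nrow(events)), function(i) {
    as.character(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE,
                                  digits = NA))
  }, character(1))
  writeLines(c('{"schema":"arbbt-events/1"}', lines), path)
  invisible(path)
}

#' Read an event log written by [write_event_log()]
#' @param path JSONL event-log path.
#' @return Event data.frame.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$schema, "arbbt-events/1"))
    stop("unrecognized event-log schema")
  recs <- lapply(lines[-1], jsonlite::fromJSON)
  do.call(rbind, lapply(recs, function(r)
    data.frame(time = r$time, kind = r$kind, block_id = as.integer(r$block_id),
               x = r$x, y = r$y)))
}
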