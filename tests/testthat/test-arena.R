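make_arena <- function(seed = 1, ...) {
  acfg <- arena_config(seed = seed, ...)
  lay <- default_box_layout(stream_config(), acfg)
  list(arena = arena_init(acfg, lay, 0), layout = lay, cfg = acfg)
}

# drive one arena transition with tips centered on `p`, `ap` pixels apart
tips_at <- function(p, ap = 20) {
  list(thumb = c(p[1] - ap / 2, p[2]), index = c(p[1] + ap / 2, p[2]))
}

test_that("spawning is seeded, confined to the source compartment, and exhausts", {
  a <- make_arena(seed = 9)
  b <- make_arena(seed = 9)
  expect_identical(a$arena$blocks[[1]], b$arena$blocks[[1]])
  expect_false(identical(a$arena$blocks[[1]]$center,
                         make_arena(seed = 10)$arena$blocks[[1]]$center))

  # walk one arena through many spawns: all centers in the shrunk source
  # region, all four colors appear
  acfg <- arena_config(blocks_total = 400, seed = 3)
  lay <- default_box_layout(stream_config(), acfg)
  arena <- arena_init(acfg, lay, 0)
  s <- lay$source_compartment
  m <- lay$spawn_margin
  colors <- character(0)
  for (i in 1:400) {
    blk <- arena$blocks[[arena$active_id]]
    expect_true(blk$center[1] >= s["x0"] + m && blk$center[1] <= s["x1"] - m)
    expect_true(blk$center[2] >= s["y0"] + m && blk$center[2] <= s["y1"] - m)
    colors <- c(colors, blk$color)
    arena$blocks[[arena$active_id]]$state <- "VANISHED"
    arena$active_id <- NA_integer_
    arena <- arbbt:::spawn_next_block(arena, i * 0.1)
  }
  expect_setequal(unique(colors), c("red", "green", "blue", "yellow"))
  # all 400 spawned: no further block
  expect_identical(arena$spawned, 400L)
  expect_true(is.na(arena$active_id))
  # spawning with an active block is a contract violation
  a2 <- make_arena()
  expect_error(arbbt:::spawn_next_block(a2$arena, 1), "single-block")
})

test_that("grab requires both fingertips inside the block and a closed pinch", {
  a <- make_arena(seed = 4)
  blk <- a$arena$blocks[[1]]
  pc <- default_pinch_config(stream_config())

  # closed pinch on the block: grab
  done <- arena_step(a$arena, tips_at(blk$center, ap = 30), closed = TRUE, 1)
  expect_identical(done$blocks[[1]]$state, "GRABBED")
  expect_identical(arena_events(done)$kind, c("SPAWN", "GRAB"))

  # closed pinch 200 px away: no grab
  off <- arena_step(a$arena, tips_at(blk$center - c(200, 0)), TRUE, 1)
  expect_identical(off$blocks[[1]]$state, "RESTING")

  # open pinch on the block (tips wider than the square): no grab
  open <- arena_step(a$arena, tips_at(blk$center, ap = 120), FALSE, 1)
  expect_identical(open$blocks[[1]]$state, "RESTING")

  # one fingertip just outside the square: no grab even though closed
  edge <- tips_at(blk$center + c(blk$half_size - 5, 0), ap = 20)
  part <- arena_step(a$arena, edge, TRUE, 1)
  expect_identical(part$blocks[[1]]$state, "RESTING")
})

test_that("a carried block follows the fingertip midpoint and stays in the box", {
  a <- make_arena(seed = 4)
  blk <- a$arena$blocks[[1]]
  ar <- arena_step(a$arena, tips_at(blk$center), TRUE, 1)
  ar2 <- arena_step(ar, list(thumb = c(100, 300), index = c(140, 300)), TRUE, 2)
  expect_equal(ar2$blocks[[1]]$center, c(120, 300))
  # far out of bounds: clamped to the boundary with a CLAMP event
  ar3 <- arena_step(ar2, list(thumb = c(-500, 300), index = c(-480, 300)), TRUE, 3)
  expect_equal(ar3$blocks[[1]]$center[1], unname(a$layout$box["x0"]))
  expect_true("CLAMP" %in% arena_events(ar3)$kind)
  # stationary tips leave the block stationary
  ar4 <- arena_step(ar3, list(thumb = c(-500, 300), index = c(-480, 300)), TRUE, 4)
  expect_identical(ar4$blocks[[1]]$center, ar3$blocks[[1]]$center)
})

test_that("clamp_to_box is the component-wise nearest interior point", {
  lay <- make_arena()$layout
  b <- lay$box
  inside <- c(b["x0"] + 10, b["y0"] + 10)
  expect_equal(clamp_to_box(inside, lay), unname(inside))
  left <- clamp_to_box(c(b["x0"] - 50, b["y0"] + 10), lay)
  expect_equal(left[1], unname(b["x0"]))
  p <- c(-1000, 1e6)
  expect_equal(clamp_to_box(clamp_to_box(p, lay), lay), clamp_to_box(p, lay))
})

test_that("divider contact follows closed-rectangle overlap geometry", {
  a <- make_arena()
  lay <- a$layout
  mid_x <- unname((lay$box["x0"] + lay$box["x1"]) / 2)
  below_top <- unname(lay$divider_top + 60)
  above_top <- unname(lay$divider_top - 31 - 1)  # bottom edge above divider_top
  blk <- function(x, y) list(center = c(x, y), half_size = 30)
  expect_true(divider_collision(blk(mid_x, below_top), lay))
  expect_false(divider_collision(blk(mid_x, above_top), lay))
  src_center <- c(unname((lay$source_compartment["x0"] +
                            lay$source_compartment["x1"]) / 2),
                  below_top)
  expect_false(divider_collision(blk(src_center[1], src_center[2]), lay))
  # brute-force oracle: scan a coordinate grid, compare with direct
  # interval-overlap arithmetic
  d <- lay$divider
  for (x in seq(mid_x - 80, mid_x + 80, by = 16)) {
    for (y in seq(unname(lay$divider_top) - 80, unname(lay$divider_top) + 80,
                  by = 16)) {
      expected <- (x + 30 >= d["x0"]) && (x - 30 <= d["x1"]) &&
        (y + 30 >= d["y0"]) && (y - 30 <= d["y1"])
      expect_identical(divider_collision(blk(x, y), lay), unname(expected))
    }
  }
})

test_that("carrying through the divider vanishes the block and respawns", {
  a <- make_arena(seed = 4)
  blk <- a$arena$blocks[[1]]
  lay <- a$layout
  ar <- arena_step(a$arena, tips_at(blk$center), TRUE, 1)
  mid_x <- unname((lay$box["x0"] + lay$box["x1"]) / 2)
  low_y <- unname(lay$divider_top + 50)
  ar <- arena_step(ar, tips_at(c(mid_x, low_y)), TRUE, 2)
  expect_identical(ar$blocks[[1]]$state, "VANISHED")
  ev <- arena_events(ar)
  expect_identical(ev$kind[ev$block_id == 1],
                   c("SPAWN", "GRAB", "DIVIDER_COLLISION"))
  # replacement spawned immediately
  expect_identical(ar$active_id, 2L)
  expect_identical(ar$blocks[[2]]$state, "RESTING")
  expect_identical(ar$score, 0L)
})

test_that("release location decides between scoring, and dropping back to rest", {
  lay_info <- make_arena(seed = 4)
  lay <- lay_info$layout
  tgt <- lay$target_compartment
  src <- lay$source_compartment
  tgt_pt <- c(unname((tgt["x0"] + tgt["x1"]) / 2), unname(tgt["y0"]) + 40)
  grab_then_release_at <- function(p) {
    a <- make_arena(seed = 4)
    blk <- a$arena$blocks[[1]]
    ar <- arena_step(a$arena, tips_at(blk$center), TRUE, 1)
    high <- c(blk$center[1], unname(lay$box["y0"]) + 10)
    ar <- arena_step(ar, tips_at(high), TRUE, 2)        # lift above divider
    ar <- arena_step(ar, tips_at(c(p[1], unname(lay$box["y0"]) + 10)), TRUE, 3)
    ar <- arena_step(ar, tips_at(p), TRUE, 4)           # lower to release point
    arena_step(ar, tips_at(p, ap = 120), FALSE, 5)      # open the pinch
  }
  # in the target compartment: scored, +1, settles to the floor, persists
  scored <- grab_then_release_at(tgt_pt)
  expect_identical(scored$blocks[[1]]$state, "SCORED")
  expect_identical(scored$score, 1L)
  expect_equal(scored$blocks[[1]]$center[2],
               unname(lay$box["y1"]) - scored$blocks[[1]]$half_size)
  expect_identical(scored$active_id, 2L)  # next block spawned
  # back in the source compartment: resting at the drop point, no score
  src_pt <- c(unname((src["x0"] + src["x1"]) / 2), unname(src["y0"]) + 40)
  dropped <- grab_then_release_at(src_pt)
  expect_identical(dropped$blocks[[1]]$state, "RESTING")
  expect_identical(dropped$score, 0L)
  expect_equal(dropped$blocks[[1]]$center, src_pt)
  # in the airspace over the divider band: neither compartment, no score
  mid_x <- unname((lay$box["x0"] + lay$box["x1"]) / 2)
  air <- grab_then_release_at(c(mid_x, unname(lay$box["y0"]) + 20))
  expect_identical(air$blocks[[1]]$state, "RESTING")
  expect_identical(air$score, 0L)
  # a dropped block is re-grabbable
  re <- arena_step(dropped, tips_at(src_pt), TRUE, 6)
  expect_identical(re$blocks[[1]]$state, "GRABBED")
})

test_that("trial event logs satisfy the lifecycle invariants", {
  cfg <- session_config(trial_duration = 30)
  res <- run_trial(simulated_subject_provider(
    subject_model(pinch_close_reliability = 0.8, tremor_sd = 6), cfg,
    seed = 13), cfg)
  ev <- res$events
  # time-ordered, inside the trial window
  expect_true(all(diff(ev$time) >= 0))
  expect_true(all(ev$time >= 0 & ev$time <= cfg$trial_duration))
  # every SCORE preceded by a GRAB of the same block
  for (id in ev$block_id[ev$kind == "SCORE"]) {
    tg <- ev$time[ev$kind == "GRAB" & ev$block_id == id]
    ts <- ev$time[ev$kind == "SCORE" & ev$block_id == id]
    expect_true(length(tg) >= 1 && min(tg) <= ts)
  }
  # three-way score reconciliation
  expect_identical(res$score, sum(ev$kind == "SCORE"))
  # no scored block ever collided with the divider
  expect_length(intersect(ev$block_id[ev$kind == "SCORE"],
                          ev$block_id[ev$kind == "DIVIDER_COLLISION"]), 0)
  # conservation: every spawned block is scored, vanished, or the single
  # live one
  spawned <- sum(ev$kind == "SPAWN")
  scored <- sum(ev$kind == "SCORE")
  vanished <- sum(ev$kind == "DIVIDER_COLLISION")
  expect_true((spawned - scored - vanished) %in% c(0L, 1L))
  # all event positions inside the box
  lay <- cfg$layout
  expect_true(all(ev$x >= lay$box["x0"] & ev$x <= lay$box["x1"]))
  expect_true(all(ev$y >= lay$box["y0"] & ev$y <= lay$box["y1"]))
})

test_that("event logs round-trip through their JSONL serialization", {
  cfg <- session_config(trial_duration = 10)
  res <- run_trial(simulated_subject_provider(subject_model(), cfg, 3), cfg)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(res$events, path)
  back <- read_event_log(path)
  expect_equal(back, res$events)
})
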