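test_that("scores classify into infra/therapeutic/supra with inclusive bounds", {
  expect_identical(classify_range(c(64, 65, 70, 85, 86)),
                   c("infra", "therapeutic", "therapeutic", "therapeutic",
                     "supra"))
  expect_identical(classify_range(0), "infra")
  expect_identical(classify_range(100), "supra")
  expect_error(classify_range(120), "\\[0, 100\\]")
  expect_error(classify_range(-1), "\\[0, 100\\]")
})

test_that("every score maps to exactly one range", {
  s <- seq(0, 100, by = 0.25)
  r <- classify_range(s)
  expect_true(all(r %in% c("infra", "therapeutic", "supra")))
  expect_identical(sum(r == "infra") + sum(r == "therapeutic") +
                     sum(r == "supra"), length(s))
})

test_that("the bingo parameter space enumerates 30 configurations", {
  dm <- build_difficulty_model(bingo_task())
  expect_identical(nrow(dm$configs), 30L)
  sizes <- tabulate(dm$configs$dq, 4)
  expect_identical(sizes, c(8L, 8L, 7L, 7L))
  expect_lte(max(sizes) - min(sizes), 1L)
  # the all-easiest configuration has weight 0 and sits in DQ1
  expect_identical(dm$configs$weight[1], 0L)
  expect_identical(dm$configs$dq[1], 1L)
  expect_identical(dm$max_weight, 2 + 4 + 1)
})

test_that("a single 4-value parameter maps values to DQ 1..4", {
  t <- make_task("q", parameters = list(
    list(name = "p", values = c("a", "b", "c", "d"),
         weights = c(0L, 1L, 2L, 3L))))
  dm <- build_difficulty_model(t)
  expect_identical(dm$configs$dq, 1:4)
  expect_identical(dm$configs$weight, 0:3)
})

test_that("difficulty quartiles match a brute-force sort oracle", {
  set.seed(43)
  for (rep in 1:50) {
    npar <- sample(1:3, 1)
    pars <- lapply(seq_len(npar), function(j) {
      nv <- sample(2:4, 1)
      list(name = paste0("p", j), values = as.character(seq_len(nv)),
           weights = as.integer(c(0, sample(0:5, nv - 1, replace = TRUE))))
    })
    t <- make_task("r", parameters = pars)
    dm <- build_difficulty_model(t)
    n <- prod(vapply(pars, function(p) length(p$values), integer(1)))
    expect_identical(nrow(dm$configs), as.integer(n))
    # oracle: sizes of the four groups over the sorted weights
    sizes <- rep(n %/% 4, 4) + c(rep(1, n %% 4), rep(0, 4 - n %% 4))
    expect_identical(tabulate(dm$configs$dq, 4), as.integer(sizes))
    # DQ non-decreasing in total weight
    expect_true(all(diff(dm$configs$weight) >= 0))
    expect_true(all(diff(dm$configs$dq) >= 0))
  }
})

test_that("MERS averages execution scores per designated subfunction", {
  catalog <- fixture_catalog()
  log <- data.frame(task_id = c("bingo", "s11_vigilance", "s05_n_back"),
                    score = c(70, 80, 90))
  m <- compute_mers(log, catalog)
  expect_equal(m[["sustained"]], 75)   # bingo and vigilance
  expect_equal(m[["working"]], 90)
  expect_true(is.na(m[["verbal"]]))
  empty <- compute_mers(log[0, ], catalog)
  expect_true(all(is.na(empty)))
  one <- compute_mers(data.frame(task_id = "bingo", score = 90), catalog)
  expect_equal(one[["sustained"]], 90)
})

test_that("running performance adjusts the PRE impairment by +1/-1/-2", {
  expect_identical(adjusted_impairment(3, 50), 4L)
  expect_identical(adjusted_impairment(3, 70), 2L)
  expect_identical(adjusted_impairment(3, 90), 1L)
  expect_identical(adjusted_impairment(3, NA), 3L)
  # clamping at both ends of the 0-4 scale
  expect_identical(adjusted_impairment(0, 70), 0L)
  expect_identical(adjusted_impairment(4, 50), 4L)
  expect_identical(adjusted_impairment(1, 90), 0L)
  expect_error(adjusted_impairment(5, 70), "0..4")
})

test_that("adjusted impairment is monotone non-increasing in MERS", {
  for (pre in 0:4) {
    vals <- adjusted_impairment(rep(pre, 5), c(10, 64, 65, 85, 86))
    expect_true(all(diff(vals) <= 0))
    expect_true(all(vals >= 0 & vals <= 4))
  }
})

test_that("impairment level selects the matching difficulty quartile", {
  bingo <- bingo_task()
  dm <- build_difficulty_model(bingo)
  expect_identical(select_difficulty(bingo, dm, 4, seed = 1)$dq, 1L)
  expect_identical(select_difficulty(bingo, dm, 3, seed = 1)$dq, 1L)
  expect_identical(select_difficulty(bingo, dm, 2, seed = 1)$dq, 2L)
  expect_identical(select_difficulty(bingo, dm, 0, seed = 1)$dq, 4L)
  c1 <- select_difficulty(bingo, dm, 2, seed = 9)
  c2 <- select_difficulty(bingo, dm, 2, seed = 9)
  expect_identical(c1, c2)
  # the drawn configuration really belongs to the task's parameter space
  expect_true(c1$values$dimension %in% c("4x4", "5x5", "6x6"))
  expect_true(c1$values$level %in% c("ordered", "disorder"))
})

test_that("one assembly cycle draws 3 SQ1, 2 SQ2, 2 SQ3, 1 SQ4 tasks", {
  catalog <- distinct_gss_catalog(12, duration = 5)
  scores <- suitability_quartiles(distinct_gss_scores(catalog))
  profile <- cognitive_profile(rep(2, 11))
  plan <- assemble_block(scores, catalog, profile, version = "v1",
                         block_size = 1L, session_minutes = 60,
                         seed = 4)
  s1 <- plan$sessions[[1]]
  expect_gte(nrow(s1), 8L)
  first_cycle <- s1$sq[1:8]
  expect_identical(as.integer(table(factor(first_cycle, levels = 1:4))),
                   c(3L, 2L, 2L, 1L))
})

test_that("80 draws yield exactly 30/20/20/10 per quartile", {
  catalog <- distinct_gss_catalog(12, duration = 5)
  scores <- suitability_quartiles(distinct_gss_scores(catalog))
  profile <- cognitive_profile(rep(2, 11))
  plan <- assemble_block(scores, catalog, profile, version = "v1",
                         block_size = 10L, session_minutes = 41,
                         seed = 8)
  expect_identical(plan$fallthroughs, 0L)
  drawn <- as.data.frame(plan)
  expect_identical(nrow(drawn), 80L)
  expect_identical(as.integer(table(factor(drawn$sq, levels = 1:4))),
                   c(30L, 20L, 20L, 10L))
})

test_that("sessions respect the duration cap and never repeat a task", {
  catalog <- fixture_catalog()
  profile <- table2_profile()
  scores <- score_tasks(catalog, profile)
  plan <- assemble_block(scores, catalog, profile, version = "v2",
                         block_size = 10L, session_minutes = 60, seed = 2)
  for (s in plan$sessions) {
    expect_lte(sum(s$duration), 60)
    expect_identical(anyDuplicated(s$task_id), 0L)
  }
})

test_that("an exhausted quartile falls through to the next one", {
  # single-task quartiles: a session longer than 4 tasks must reuse
  # quartiles via fall-through
  catalog <- distinct_gss_catalog(4, duration = 5)
  scores <- suitability_quartiles(distinct_gss_scores(catalog))
  profile <- cognitive_profile(rep(2, 11))
  plan <- assemble_block(scores, catalog, profile, version = "v1",
                         block_size = 1L, session_minutes = 21, seed = 3)
  s1 <- plan$sessions[[1]]
  expect_identical(nrow(s1), 4L)          # all four distinct tasks used
  expect_gte(plan$fallthroughs, 1L)       # cycle asked SQ1 three times
})

test_that("versions differ only through the MERS adjustment", {
  catalog <- fixture_catalog()
  profile <- table2_profile()
  scores <- score_tasks(catalog, profile)
  mers <- stats::setNames(rep(90, 11), subfunction_names())
  v1 <- assemble_block(scores, catalog, profile, mers = mers,
                       version = "v1", block_size = 2L, seed = 5)
  v2 <- assemble_block(scores, catalog, profile, mers = mers,
                       version = "v2", block_size = 2L, seed = 5)
  d1 <- as.data.frame(v1); d2 <- as.data.frame(v2)
  expect_identical(d1$task_id, d2$task_id)  # same draws, same seed
  # uniformly supra MERS pushes difficulty quartiles up (never down)
  expect_true(all(d2$dq >= d1$dq))
  expect_gt(mean(d2$dq), mean(d1$dq))
})

test_that("out-of-range executions are re-queued one quartile away", {
  bingo <- bingo_task()
  dm <- build_difficulty_model(bingo)
  filler <- make_task("filler", subfunction = "visual", duration = 55)
  catalog <- list(bingo, filler)
  mk_session <- function(task_id, duration) {
    data.frame(position = 1L, task_id = task_id, sq = 1L, dq = 1L,
               duration = duration, config = "p1=a",
               stringsAsFactors = FALSE)
  }
  # session 2 is full (55 of 60 min), session 3 has room for the bingo
  plan <- structure(
    list(sessions = list(mk_session("bingo", 10),
                         mk_session("filler", 55),
                         mk_session("filler", 20)),
         version = "v1", session_minutes = 60, seed = 1L,
         draw_quartiles = NULL, fallthroughs = 0L),
    class = "block_plan")
  # build a record at a known DQ2 configuration
  cfg2 <- dm$configs[dm$configs$dq == 2L, ][1, ]
  cfg2_str <- serialize_config(config_values(dm, cfg2))
  rec <- list(task_id = "bingo", session = 1L, score = 40,
              config = cfg2_str)
  # infra: re-queued one quartile easier into a later session
  upd <- relaunch(rec, dm, plan, catalog, seed = 2)
  added <- as.data.frame(upd)[nrow(as.data.frame(upd)), ]
  expect_identical(added$dq, 1L)
  expect_gt(added$session, 1)
  # therapeutic: untouched
  rec$score <- 75
  expect_identical(as.data.frame(relaunch(rec, dm, plan, catalog)),
                   as.data.frame(plan))
  # infra at DQ1 stays at DQ1 (clamped)
  cfg1 <- dm$configs[dm$configs$dq == 1L, ][1, ]
  rec1 <- list(task_id = "bingo", session = 1L, score = 30,
               config = serialize_config(config_values(dm, cfg1)))
  upd1 <- relaunch(rec1, dm, plan, catalog, seed = 2)
  add1 <- as.data.frame(upd1)[nrow(as.data.frame(upd1)), ]
  expect_identical(add1$dq, 1L)
  # supra: one quartile harder
  rec$score <- 95; rec$config <- cfg2_str
  upd3 <- relaunch(rec, dm, plan, catalog, seed = 2)
  add3 <- as.data.frame(upd3)[nrow(as.data.frame(upd3)), ]
  expect_identical(add3$dq, 3L)
  # no session with room left: logged, unchanged
  rec$session <- 3L
  expect_message(out <- relaunch(rec, dm, plan, catalog),
                 "no open session")
  expect_identical(as.data.frame(out), as.data.frame(plan))
})
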