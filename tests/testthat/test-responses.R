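test_that("the response list has the 11 canonical options in order", {
  m <- mat_apply(shape_start(), hrules = "shape", vrules = "size")
  rl <- suppressWarnings(response_list(m))
  expect_identical(names(rl), c(
    "correct", "r_diag", "r_left", "r_top", "wp_copy", "wp_matrix",
    "difference", "ic_neg", "ic_flip", "ic_size", "ic_inc"
  ))
  expect_length(rl, 11L)
  expect_true(all(vapply(rl, is_figure, logical(1))))
})

test_that("repetition distractors copy the cells adjacent to the blank", {
  m <- mat_apply(make_primitive("square", size.x = 10),
                 hrules = "size", vrules = "rotation")
  rl <- suppressWarnings(response_list(m))
  expect_identical(rl$r_left, m$Sq8)
  expect_identical(rl$r_top, m$Sq6)
  expect_identical(rl$r_diag, m$Sq5)
  expect_identical(rl$correct, m$Sq9)

  m4 <- mat_apply(make_primitive("square", size.x = 10),
                  hrules = "size", vrules = "rotation", mat.type = 4)
  rl4 <- suppressWarnings(response_list(m4))
  expect_identical(rl4$r_left, m4$Sq3)
  expect_identical(rl4$r_top, m4$Sq2)
  expect_identical(rl4$r_diag, m4$Sq1)
})

test_that("source-cell selection follows rule count and directional logic", {
  sq <- make_primitive("square", size.x = 10)
  # single rule, H / V / TL-LR -> Sq1
  expect_identical(select_source_cell(mat_apply(shape_start(), hrules = "shape")),
                   "Sq1")
  expect_identical(select_source_cell(mat_apply(sq, vrules = "shade")), "Sq1")
  expect_identical(
    select_source_cell(mat_apply(sq, hrules = "size", vrules = "size.inv")),
    "Sq1")
  # LL-TR or >= 2 rules -> Sq3
  expect_identical(
    select_source_cell(mat_apply(sq, hrules = "size", vrules = "size")),
    "Sq3")
  expect_identical(
    select_source_cell(mat_apply(sq, hrules = "shade", vrules = "rotation")),
    "Sq3")
  # 2x2: Sq3 when a rule runs both ways, else Sq2 (wp) / Sq1 (difference)
  m4diag <- mat_apply(sq, hrules = "size", vrules = "size", mat.type = 4)
  expect_identical(select_source_cell(m4diag, "wp"), "Sq3")
  expect_identical(select_source_cell(m4diag, "difference"), "Sq3")
  m4h <- mat_apply(sq, hrules = "shade", mat.type = 4)
  expect_identical(select_source_cell(m4h, "wp"), "Sq2")
  expect_identical(select_source_cell(m4h, "difference"), "Sq1")
})

test_that("wrong-principle distractors copy and recombine cells", {
  m <- mat_apply(shape_start(), hrules = "shape")
  wp <- gen_wrong_principle(m)
  expect_identical(wp$wp_copy, m$Sq1)
  expect_length(wp$wp_matrix$elements,
                length(m$Sq1$elements) + length(m$Sq2$elements))
  # degenerate matrix: wp_copy equals correct and is crossed out
  rl <- suppressWarnings(response_list(mat_apply(make_primitive("square"))))
  expect_true(is_crossed(rl$wp_copy))
  # 2x2 wp_matrix superimposes the rotated wp_copy
  m4 <- mat_apply(make_primitive("square", size.x = 10), hrules = "size",
                  mat.type = 4)
  wp4 <- gen_wrong_principle(m4)
  expect_identical(wp4$wp_copy, m4$Sq1)
  n_src <- length(m4$Sq2$elements)
  expect_length(wp4$wp_matrix$elements, n_src + length(m4$Sq1$elements))
  rot <- wp4$wp_matrix$elements[[n_src + 1]]$rotation
  expect_equal(rot, m4$Sq1$elements[[1]]$rotation + pi / 2)
})

test_that("the difference distractor superimposes a foreign figure", {
  m <- mat_apply(shape_start(), hrules = "shape")
  used <- unique(unlist(lapply(paste0("Sq", 1:9), function(nm) {
    c(m[[nm]]$name, vapply(m[[nm]]$elements, `[[`, character(1), "shape"))
  })))
  d <- gen_difference(m, seed = 1)
  foreign <- setdiff(vapply(d$elements, `[[`, character(1), "shape"), used)
  expect_gte(length(foreign), 1L)
  expect_false(any(foreign %in% used))
  # seed controls only the foreign draw; exhaustion returns NULL
  expect_null(gen_difference(m, seed = 1, candidates = used))
  rl <- suppressWarnings(response_list(m, seed = 1))
  rl2 <- suppressWarnings(response_list(m, seed = 2))
  for (nm in setdiff(names(rl), "difference")) {
    expect_identical(rl[[nm]], rl2[[nm]], info = nm)
  }
})

test_that("single-layer matrices cannot yield ic_inc", {
  # two rules so no repetition distractor is degenerate: the only warning
  # is the IC-Inc fallback
  m <- mat_apply(make_primitive("square"), hrules = "shade",
                 vrules = "rotation")
  expect_warning(rl <- response_list(m),
                 "IC-Inc cannot be obtained with a single figure")
  expect_true(is_crossed(rl$ic_inc))
  w <- response_warnings(rl)
  expect_true(any(vapply(w, function(x) x$option == "ic_inc", logical(1))))
})

test_that("single-direction rules make the parallel repetition degenerate", {
  # vertical-only rule: r_left (Sq8) equals the correct response
  m <- mat_apply(make_primitive("square"), vrules = "shade")
  w <- capture_warnings(rl <- response_list(m))
  expect_match(w, "r_left", all = FALSE)
  expect_true(is_crossed(rl$r_left))
  expect_false(is_crossed(rl$r_top))
  expect_false(is_crossed(rl$r_diag))
  # horizontal-only rule: r_top (Sq6) equals the correct response
  mh <- mat_apply(make_primitive("square"), hrules = "shade")
  wh <- capture_warnings(rlh <- response_list(mh))
  expect_match(wh, "r_top", all = FALSE)
  expect_true(is_crossed(rlh$r_top))
  expect_false(is_crossed(rlh$r_left))
})

test_that("incomplete correlates alter exactly one feature", {
  bg <- mat_apply(make_primitive("square", size.x = 10), hrules = "shade")
  fg <- mat_apply(make_primitive("pentagon", size.x = 6), vrules = "rotation")
  m <- com(bg, fg)
  rl <- suppressWarnings(response_list(m))
  correct <- rl$correct
  n_bg <- length(correct_response(bg)$elements)
  idx <- n_bg + seq_len(length(correct_response(fg)$elements))

  # ic_neg: fill inversion on the target layer only
  expect_false(is_crossed(rl$ic_neg))
  for (i in idx) {
    a <- correct$elements[[i]]$shade
    b <- rl$ic_neg$elements[[i]]$shade
    expect_identical(b, if (!is.na(a) && a == "black") "white" else "black")
  }
  for (i in seq_len(n_bg)) {
    expect_identical(rl$ic_neg$elements[[i]], correct$elements[[i]])
  }

  # ic_flip: quarter-turn of the target layer
  expect_equal(rl$ic_flip$elements[[idx[1]]]$rotation,
               correct$elements[[idx[1]]]$rotation + pi / 2)
  expect_identical(rl$ic_flip$elements[[1]], correct$elements[[1]])

  # ic_size: only the target figure is resized, by half
  expect_equal(rl$ic_size$elements[[idx[1]]]$size.x,
               correct$elements[[idx[1]]]$size.x * 0.5)
  expect_identical(rl$ic_size$elements[[1]], correct$elements[[1]])

  # ic_inc: the foreground figure is removed
  expect_length(rl$ic_inc$elements,
                length(correct$elements) -
                  length(correct_response(fg)$elements))
})

test_that("the tutorial item reproduces the documented fallbacks", {
  m <- build_item(tutorial_item())
  expect_identical(n_layers(m), 2L)
  expect_identical(m$mat.type, 9L)
  expect_warning(rl <- response_list(m), "IC-Neg")
  expect_true(is_crossed(rl$ic_neg))
  expect_length(rl, 11L)
  # logic matrix: ic_inc removes one randomly selected element
  expect_false(is_crossed(rl$ic_inc))
  expect_length(rl$ic_inc$elements, length(rl$correct$elements) - 1L)
})

test_that("response lists are deterministic and isolate the seed", {
  m <- build_item(tutorial_item())
  r1 <- suppressWarnings(response_list(m, seed = 5))
  r2 <- suppressWarnings(response_list(m, seed = 5))
  expect_identical(r1, r2)
  r3 <- suppressWarnings(response_list(m, seed = 12))
  # only seed-dependent options may move: difference, ic_inc (logic removal)
  for (nm in setdiff(names(r1), c("difference", "ic_inc"))) {
    expect_identical(r1[[nm]], r3[[nm]], info = nm)
  }
})

test_that("no non-crossed distractor equals the correct response", {
  specs <- sample_item_spec(fixture_config(seed = 202, n_items = 25,
                                           include_degenerate = TRUE))
  for (spec in specs) {
    m <- build_item(spec)
    rl <- suppressWarnings(response_list(
      m, seed = if (is.null(spec$seed)) 1L else spec$seed))
    for (nm in setdiff(names(rl), "correct")) {
      if (!is_crossed(rl[[nm]])) {
        expect_false(figure_equal(rl[[nm]], rl$correct),
                     info = paste(spec$name, nm))
      }
    }
    # crossed options carry a warning record
    crossed <- names(rl)[vapply(rl, is_crossed, logical(1))]
    warned <- vapply(response_warnings(rl), `[[`, character(1), "option")
    expect_true(all(crossed %in% warned), info = spec$name)
  }
})
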