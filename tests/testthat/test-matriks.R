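test_that("a default matrix exposes exactly the documented structure", {
  m <- mat_apply(make_primitive("square"))
  expect_identical(names(m),
                   c(paste0("Sq", 1:9), "hrule", "vrule", "mat.type"))
  expect_identical(m$mat.type, 9L)
  for (k in 1:9) expect_true(figure_equal(m[[k]], make_primitive("square")))

  m4 <- mat_apply(make_primitive("square"), mat.type = 4)
  expect_identical(names(m4),
                   c(paste0("Sq", 1:4), "hrule", "vrule", "mat.type"))
  expect_error(mat_apply(make_primitive("square"), mat.type = 6), "mat.type")
  expect_error(mat_apply(make_primitive("square"), hrules = "bogus"),
               "unknown rule")
})

test_that("horizontal and vertical applications of size accumulate", {
  m <- mat_apply(make_primitive("square", size.x = 10),
                 hrules = "size", vrules = "size")
  sx <- function(cell) cell$elements[[1]]$size.x
  # cell (i, j) is divided by (j * k) horizontally then (i * k) vertically
  expect_equal(sx(m$Sq5), 10 / (2 * 0.9) / (2 * 0.9))
  expect_equal(sx(m$Sq9), 10 / (3 * 0.9) / (3 * 0.9))
  # paper narrative: Sq5 is half of Sq1, then a quarter after both passes
  h_only <- mat_apply(make_primitive("square", size.x = 10), hrules = "size")
  expect_equal(sx(h_only$Sq5) / sx(h_only$Sq1), 0.5)
  expect_equal(sx(m$Sq5) / sx(m$Sq1), 0.25)
})

test_that("a single directional rule leaves the other axis constant", {
  m <- mat_apply(shape_start(), hrules = "shape")
  # row-major: within each column all cells identical
  for (j in 1:3) {
    col <- lapply(c(0, 3, 6) + j, function(k) m[[paste0("Sq", k)]])
    expect_true(figure_equal(col[[1]], col[[2]]))
    expect_true(figure_equal(col[[2]], col[[3]]))
  }
  # shape order left to right follows the concatenation order
  shown <- vapply(1:3, function(j) {
    cell <- m[[paste0("Sq", j)]]
    cell$name[unique(cell$constituent[visible_set(cell)])]
  }, character(1))
  expect_identical(shown, c("hexagon", "pentagon", "square"))

  mv <- mat_apply(make_primitive("square"), vrules = "shade")
  for (i in 1:3) {
    row <- lapply((i - 1) * 3 + 1:3, function(k) mv[[paste0("Sq", k)]])
    expect_true(figure_equal(row[[1]], row[[2]]))
    expect_true(figure_equal(row[[2]], row[[3]]))
  }
  expect_identical(mv$Sq1$elements[[1]]$shade, "white")
  expect_identical(mv$Sq4$elements[[1]]$shade, "gray")
  expect_identical(mv$Sq7$elements[[1]]$shade, "black")
})

test_that("logical rules are validated before generation", {
  sq4 <- make_primitive("square4")
  expect_error(mat_apply(sq4, hrules = "AND", mat.type = 4),
               "four-cell")
  expect_error(mat_apply(sq4, hrules = c("AND", "size")),
               "visuospatial")
  expect_error(mat_apply(sq4, hrules = "AND", vrules = "rotation"),
               "visuospatial")
  expect_error(mat_apply(sq4, hrules = "AND", vrules = "OR"),
               "differing directional logic")
  expect_error(mat_apply(sq4, hrules = "AND", vrules = "AND"),
               "both directions")
  expect_error(mat_apply(sq4, hrules = c("AND", "OR")),
               "one logical rule")
})

test_that("logical matrices satisfy row/column set semantics", {
  for (rule in c("AND", "OR", "XOR")) {
    mh <- mat_apply(make_primitive("miley"), hrules = rule, seed = 7)
    for (i in 1:3) {
      cells <- lapply((i - 1) * 3 + 1:3, function(k) mh[[paste0("Sq", k)]])
      v <- lapply(cells, visible_set)
      expect_identical(sort(v[[3]]), sort(logical_oracle(rule, v[[1]], v[[2]])),
                       info = paste("H", rule, "row", i))
    }
    mv <- mat_apply(make_primitive("square4"), vrules = rule, seed = 7)
    for (j in 1:3) {
      cells <- lapply(c(0, 3, 6) + j, function(k) mv[[paste0("Sq", k)]])
      v <- lapply(cells, visible_set)
      expect_identical(sort(v[[3]]), sort(logical_oracle(rule, v[[1]], v[[2]])),
                       info = paste("V", rule, "col", j))
    }
    # rows draw distinct partitions but the build is reproducible
    expect_identical(mh, mat_apply(make_primitive("miley"), hrules = rule,
                                   seed = 7))
    expect_false(identical(visible_set(mh$Sq1), visible_set(mh$Sq7)) &&
                 identical(visible_set(mh$Sq2), visible_set(mh$Sq8)))
  }
})

test_that("matrix generation is deterministic in all inputs", {
  args <- list(shape_start(), hrules = "shape", vrules = "size", seed = 11)
  expect_identical(do.call(mat_apply, args), do.call(mat_apply, args))
})

test_that("com layers matrices background to foreground", {
  a <- mat_apply(make_primitive("square4"), hrules = "AND")
  b <- mat_apply(make_primitive("miley"), vrules = "OR")
  ab <- com(a, b)
  expect_identical(n_layers(ab), 2L)
  expect_identical(ab$mat.type, 9L)
  # cell-wise concatenation in layer order
  expect_identical(ab$Sq1$elements,
                   c(a$Sq1$elements, b$Sq1$elements))
  expect_identical(ab$hrule, c(a$hrule, b$hrule))
  expect_identical(layer_rules(ab),
                   c(layer_rules(a), layer_rules(b)))
  # element counts add up in every cell
  for (k in 1:9) {
    nm <- paste0("Sq", k)
    expect_length(ab[[nm]]$elements,
                  length(a[[nm]]$elements) + length(b[[nm]]$elements))
  }
  # identity layering
  single <- com(a)
  expect_identical(single, a)
  # three layers associativity of cell contents
  c_ <- mat_apply(make_primitive("square"), hrules = "shade")
  abc <- com(a, b, c_)
  expect_identical(abc$Sq1$elements,
                   c(a$Sq1$elements, b$Sq1$elements, c_$Sq1$elements))
  expect_identical(n_layers(abc), 3L)
  # errors
  expect_error(com(a, mat_apply(make_primitive("square"), mat.type = 4)),
               "mat.type")
  expect_error(com(), "at least one")
})

test_that("correct_response returns the blank (last) cell", {
  sq <- make_primitive("square")
  m <- mat_apply(sq)
  expect_true(figure_equal(correct_response(m), sq))
  expect_identical(correct_response(m), m$Sq9)
  m4 <- mat_apply(sq, mat.type = 4)
  expect_identical(correct_response(m4), m4$Sq4)
  # AND rule: correct response is the intersection of Sq7 and Sq8
  ma <- mat_apply(make_primitive("miley"), hrules = "AND", seed = 3)
  expect_identical(sort(visible_set(correct_response(ma))),
                   sort(intersect(visible_set(ma$Sq7), visible_set(ma$Sq8))))
})

test_that("classify_direction reports H, V, and diagonal logics", {
  sq <- make_primitive("square", size.x = 10)
  expect_identical(
    classify_direction(mat_apply(sq, hrules = "size", vrules = "size")),
    c(size = "LL-TR"))
  expect_identical(
    classify_direction(mat_apply(sq, hrules = "size", vrules = "size.inv")),
    c(size = "TL-LR"))
  expect_identical(
    classify_direction(mat_apply(sq, hrules = "size.inv", vrules = "size.inv")),
    c(size = "LL-TR"))
  m <- mat_apply(sq, hrules = "shade", vrules = "rotation.4")
  expect_identical(classify_direction(m),
                   c(shade = "H", rotation = "V"))
  expect_length(classify_direction(mat_apply(sq)), 0L)
})
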