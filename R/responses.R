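# Canonical option order of a response list.
.OPTION_NAMES <- c("correct", "r_diag", "r_left", "r_top", "wp_copy",
                   "wp_matrix", "difference", "ic_neg", "ic_flip",
                   "ic_size", "ic_inc")

# Two full-panel diagonal strokes used to cancel infeasible options.
crossout_overlay <- function() {
  half <- 26  # spans the [-20, 20] canvas corner to corner (with margin)
  figure(list(
    element("cross.out", nv = 2L, size.x = half, rotation = pi / 4,
            lwd = 3L, tag = "cross.out"),
    element("cross.out", nv = 2L, size.x = half, rotation = -pi / 4,
            lwd = 3L, tag = "cross.out")
  ), "cross.out", c(1L, 1L))
}

# The crossed-out fallback: the correct response covered by a thick black
# cross. Marked with an attribute so degeneracy checks skip it.
crossed_out <- function(correct) {
  structure(cof(correct, crossout_overlay()), crossed = TRUE)
}

#' Is a response option a crossed-out fallback?
#' @param fig a `figure` from a response list.
#' @export
is_crossed <- function(fig) isTRUE(attr(fig, "crossed"))

#' Source cell for the wrong-principle and difference distractors
#'
#' For nine-cell matrices, `Sq1` is used when a single rule is manipulated
#' with V, H, or TL-LR directional logic; `Sq3` when a single rule follows
#' LL-TR logic or when two or more rules are manipulated (any logic) — this
#' prevents wrong-principle copies from passing as incomplete correlates.
#' For four-cell matrices, `Sq3` is used when at least one rule is applied
#' both horizontally and vertically; otherwise `Sq2` for the wrong-principle
#' matrix and `Sq1` for the difference distractor.
#'
#' @param m a `matriks`.
#' @param target `"wp"` or `"difference"` (only relevant for 2x2 matrices).
#' @return a cell name.
#' @export
select_source_cell <- function(m, target = c("wp", "difference")) {
  stopifnot(is_matriks(m))
  target <- match.arg(target)
  dirs <- classify_direction(m)
  if (m$mat.type == 9L) {
    if (length(dirs) >= 2L) return("Sq3")
    if (length(dirs) == 1L && dirs == "LL-TR") return("Sq3")
    return("Sq1")
  }
  if (any(dirs %in% c("TL-LR", "LL-TR"))) return("Sq3")
  if (target == "wp") "Sq2" else "Sq1"
}

# All names under which content appears in the matrix (element shapes and
# constituent names), used to keep the difference figure foreign.
matrix_content_names <- function(m) {
  cells <- lapply(paste0("Sq", seq_len(m$mat.type)), function(nm) m[[nm]])
  unique(unlist(lapply(cells, function(f) {
    c(f$name, vapply(f$elements, `[[`, character(1), "shape"))
  })))
}

#' Wrong-principle distractors
#'
#' `wp_copy` repeats a non-adjacent cell verbatim (the source cell).
#' `wp_matrix` recombines cells in a way that follows no rule of the
#' matrix: for 3x3 matrices the source cell superimposed with the
#' horizontally adjacent cell (`Sq2`); for 2x2 matrices the selected cell
#' superimposed with a quarter-turn rotation of `wp_copy`.
#'
#' @param m a `matriks`.
#' @param source source cell name (see [select_source_cell()]).
#' @return list with components `wp_copy` and `wp_matrix`.
#' @export
gen_wrong_principle <- function(m, source = select_source_cell(m, "wp")) {
  stopifnot(is_matriks(m))
  if (m$mat.type == 9L) {
    wp_copy <- m[[source]]
    wp_matrix <- cof(m[[source]], m$Sq2)
  } else {
    wp_copy <- m$Sq1
    rot <- wp_copy
    for (i in seq_along(rot$elements)) {
      rot$elements[[i]]$rotation <- rot$elements[[i]]$rotation + pi / 2
    }
    wp_matrix <- cof(m[[source]], rot)
  }
  list(wp_copy = wp_copy, wp_matrix = wp_matrix)
}

#' Difference distractor
#'
#' Merges matrix cells (for 3x3: the source cell plus `Sq4` and `Sq7`; for
#' 2x2: the source cell alone) and superimposes a figure that is not
#' manipulated anywhere in the matrix, drawn (seeded) from the registry
#' primitives tagged `d.ext` or `d.int`. Changing the seed changes only
#' which foreign figure is chosen.
#'
#' @param m a `matriks`.
#' @param source source cell name (see [select_source_cell()]).
#' @param seed integer seed for the foreign-figure draw.
#' @param candidates candidate primitive names; defaults to the full
#'   registry.
#' @return a `figure`, or `NULL` when no foreign figure is available (the
#'   caller then applies the crossed-out fallback).
#' @export
gen_difference <- function(m, source = select_source_cell(m, "difference"),
                           seed = 1L, candidates = NULL) {
  stopifnot(is_matriks(m))
  if (is.null(candidates)) {
    candidates <- Filter(function(nm) {
      any(c("d.ext", "d.int") %in% figure_tags(make_primitive(nm)))
    }, primitives())
  }
  eligible <- setdiff(candidates, matrix_content_names(m))
  if (!length(eligible)) return(NULL)
  pick <- if (length(eligible) == 1L) eligible else {
    with_seed(seed, sample(eligible, 1L))
  }
  merged <- if (m$mat.type == 9L) {
    cof(m[[source]], m$Sq4, m$Sq7)
  } else {
    m[[source]]
  }
  cof(merged, make_primitive(pick))
}

# Element indices of the correct response contributed by layer t (the
# correct response of a layered matrix is the cof of the layers' last
# cells, so offsets are cumulative element counts).
layer_element_indices <- function(m, t) {
  layers <- mat_layers(m)
  lens <- vapply(layers, function(l) length(correct_response(l)$elements),
                 integer(1))
  off <- sum(lens[seq_len(t - 1L)])
  off + seq_len(lens[t])
}

# Drop elements from a figure, remapping constituent names.
remove_elements <- function(fig, idx) {
  keep <- setdiff(seq_along(fig$elements), idx)
  if (!length(keep)) stop("cannot remove every element of a figure")
  cons <- fig$constituent[keep]
  used <- sort(unique(cons))
  figure(fig$elements[keep], fig$name[used],
         match(cons, used))
}

# Does the correct response involve a logical rule in any layer?
is_logic_matriks <- function(m) {
  any(is_logical_name(c(m$hrule, m$vrule)))
}

#' Incomplete-correlate distractors
#'
#' The four IC distractors alter the correct response in exactly one
#' feature. The altered figure is the foreground-most layer whose tags
#' support all IC manipulations (`fill` and `rotate`); if no layer
#' qualifies, the foreground layer is used and individually infeasible
#' options fall back to the crossed-out correct response:
#'
#' * `ic_neg` — fill inversion (white and black swap; gray and unfilled
#'   become black); requires the `fill` tag.
#' * `ic_flip` — quarter-turn clockwise rotation when the `rotate` tag is
#'   present, otherwise a mirror across the vertical axis.
#' * `ic_size` — the target figure shrinks to half size.
#' * `ic_inc` — the foreground figure is removed (multi-layer only; for
#'   logic matrices one visible element is removed at random, seeded).
#'
#' @param m a `matriks`.
#' @param seed integer seed (drives the random removal of `ic_inc` on
#'   logic matrices).
#' @return list with components `ic_neg`, `ic_flip`, `ic_size`, `ic_inc`
#'   (figures; infeasible ones are crossed out) and `warnings` (character
#'   vector, named by option).
#' @export
gen_incomplete_correlates <- function(m, seed = 1L) {
  stopifnot(is_matriks(m))
  correct <- correct_response(m)
  layers <- mat_layers(m)
  M <- length(layers)

  target <- M
  for (t in rev(seq_len(M))) {
    tg <- figure_tags(correct_response(layers[[t]]))
    if (all(c("fill", "rotate") %in% tg)) {
      target <- t
      break
    }
  }
  idx <- layer_element_indices(m, target)
  idx <- idx[vapply(correct$elements[idx], function(e) e$visible >= 1L,
                    logical(1))]
  if (!length(idx)) idx <- layer_element_indices(m, target)
  target_tags <- sort(unique(unlist(
    lapply(correct$elements[idx], `[[`, "tag")
  )))
  warn <- character(0)

  # fill inversion
  if ("fill" %in% target_tags) {
    ic_neg <- correct
    for (i in idx) {
      sh <- ic_neg$elements[[i]]$shade
      ic_neg$elements[[i]]$shade <-
        if (!is.na(sh) && sh == "black") "white" else "black"
    }
  } else {
    warn["ic_neg"] <- paste0("IC-Neg cannot be obtained: the figure cannot ",
                             "change its filling color")
    ic_neg <- crossed_out(correct)
  }

  # reflection/rotation
  ic_flip <- correct
  if ("rotate" %in% target_tags) {
    for (i in idx) {
      ic_flip$elements[[i]]$rotation <- ic_flip$elements[[i]]$rotation + pi / 2
    }
  } else {
    for (i in idx) {
      el <- ic_flip$elements[[i]]
      el$pos.x <- -el$pos.x
      el$rotation <- -el$rotation
      if (el$num == 2L) {
        t1 <- el$theta.1; t2 <- el$theta.2
        el$theta.1 <- pi - t2
        el$theta.2 <- pi - t1
      }
      ic_flip$elements[[i]] <- el
    }
  }

  # resize (only the target figure is resized)
  ic_size <- correct
  for (i in idx) {
    ic_size$elements[[i]]$size.x <- ic_size$elements[[i]]$size.x * 0.5
    ic_size$elements[[i]]$size.y <- ic_size$elements[[i]]$size.y * 0.5
  }

  # element removal
  if (M == 1L) {
    warn["ic_inc"] <- "IC-Inc cannot be obtained with a single figure"
    ic_inc <- crossed_out(correct)
  } else if (is_logic_matriks(m)) {
    vis <- visible_elements(correct)
    drop <- if (length(vis) == 1L) vis else {
      with_seed(as.integer(seed) + 1L, sample(vis, 1L))
    }
    ic_inc <- remove_elements(correct, drop)
  } else {
    ic_inc <- remove_elements(correct, layer_element_indices(m, M))
  }

  list(ic_neg = ic_neg, ic_flip = ic_flip, ic_size = ic_size,
       ic_inc = ic_inc, warnings = warn)
}

#' Generate the response list of a matrix
#'
#' Produces the 11 response options in canonical order: the correct
#' response, three repetition distractors (`r_diag`, `r_left`, `r_top` —
#' the cells diagonal, left, and top of the blank cell), two
#' wrong-principle distractors (`wp_copy`, `wp_matrix`), one difference
#' distractor, and four incomplete correlates (`ic_neg`, `ic_flip`,
#' `ic_size`, `ic_inc`).
#'
#' Any distractor that is infeasible, or that turns out equal to the
#' correct response (e.g. the left repetition under a purely vertical
#' rule), is replaced by the correct response covered with a thick black
#' cross, and a warning is recorded and emitted.
#'
#' @param m a `matriks`.
#' @param seed integer seed; affects only the seed-dependent options (the
#'   difference distractor and, on logic matrices, the random removal of
#'   `ic_inc`).
#' @return an object of class `response_list`: a named list of 11 figures
#'   with attributes `warnings` (list of `(option, message)` records) and
#'   `seed`.
#' @export
response_list <- function(m, seed = 1L) {
  stopifnot(is_matriks(m))
  correct <- correct_response(m)
  side9 <- m$mat.type == 9L

  opts <- list(correct = correct)
  opts$r_diag <- if (side9) m$Sq5 else m$Sq1
  opts$r_left <- if (side9) m$Sq8 else m$Sq3
  opts$r_top <- if (side9) m$Sq6 else m$Sq2

  wp <- gen_wrong_principle(m)
  opts$wp_copy <- wp$wp_copy
  opts$wp_matrix <- wp$wp_matrix

  warnings <- list()
  note <- function(option, message) {
    warnings[[length(warnings) + 1L]] <<- list(option = option,
                                               message = message)
    warning(message, call. = FALSE)
  }

  d <- gen_difference(m, seed = seed)
  if (is.null(d)) {
    note("difference",
         "Difference cannot be obtained: no figure foreign to the matrix is available")
    d <- crossed_out(correct)
  }
  opts$difference <- d

  ic <- gen_incomplete_correlates(m, seed = seed)
  for (nm in names(ic$warnings)) note(nm, ic$warnings[[nm]])
  opts$ic_neg <- ic$ic_neg
  opts$ic_flip <- ic$ic_flip
  opts$ic_size <- ic$ic_size
  opts$ic_inc <- ic$ic_inc

  # degenerate options (equal to the correct response) are crossed out
  for (nm in setdiff(.OPTION_NAMES, "correct")) {
    if (!is_crossed(opts[[nm]]) && figure_equal(opts[[nm]], correct)) {
      note(nm, paste0("the ", nm, " distractor is equal to the correct ",
                      "response and is covered by a thick black cross"))
      opts[[nm]] <- crossed_out(correct)
    }
  }

  structure(opts[.OPTION_NAMES], class = "response_list",
            warnings = warnings, seed = as.integer(seed))
}

#' Is an object a response list?
#' @param x object to test.
#' @export
is_response_list <- function(x) inherits(x, "response_list")

#' Warnings recorded while generating a response list
#' @param rl a `response_list`.
#' @return list of records with fields `option` and `message`.
#' @export
response_warnings <- function(rl) {
  stopifnot(is_response_list(rl))
  attr(rl, "warnings")
}

#' @export
print.response_list <- function(x, ...) {
  cat("<response_list> 11 options\n")
  crossed <- names(x)[vapply(x, is_crossed, logical(1))]
  if (length(crossed)) cat("crossed out:", paste(crossed, collapse = ", "), "\n")
  for (w in response_warnings(x)) {
    cat("warning [", w$option, "]: ", w$message, "\n", sep = "")
  }
  invisible(x)
}
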