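# The 15 feature fields of a drawable shape, in canonical order.
.FEATURE_FIELDS <- c(
  "shape", "size.x", "size.y", "theta.1", "theta.2", "rotation",
  "pos.x", "pos.y", "lty", "lwd", "num", "nv", "shade", "visible", "tag"
)

.NUMERIC_FIELDS <- c(
  "size.x", "size.y", "theta.1", "theta.2", "rotation", "pos.x", "pos.y"
)

# Fill names accepted by the shade field; NA means unfilled.
.SHADES <- c("white", "gray", "black")

#' Create one figure element (feature record)
#'
#' An element is the atomic drawable unit of a figure: a regular polygon
#' inscribed in an ellipse (`num = 1`) or a circular/elliptical arc
#' (`num = 2`). Its appearance is fully described by 15 fields.
#'
#' @param shape name of the shape the element belongs to.
#' @param size.x,size.y semi-major and semi-minor axis of the circumscribing
#'   ellipse, in canvas units (the cell canvas is `[-20, 20] x [-20, 20]`).
#' @param theta.1,theta.2 arc start and end angles in radians (used when
#'   `num = 2`).
#' @param rotation clockwise rotation of the circumscribing ellipse, radians.
#' @param pos.x,pos.y center of the element on the cell canvas.
#' @param lty line-type code (1 solid, 2 dashed, 3 dotted).
#' @param lwd line-width multiple, integer in 1..3.
#' @param num draw mode: 1 = polygon inscribed in the ellipse, 2 = arc.
#' @param nv number of vertices, integer in 2..100 (2 = line, 100 = circle).
#' @param shade fill name (`"white"`, `"gray"`, `"black"`) or `NA` for
#'   unfilled.
#' @param visible visibility level; 0 = hidden, >= 1 = drawn.
#' @param tag character vector of property tags (e.g. `"fill"`, `"rotate"`).
#' @return a named list with the 15 feature fields.
#' @export
element <- function(shape = "shape", size.x = 15, size.y = 15,
                    theta.1 = 0, theta.2 = 2 * pi, rotation = 0,
                    pos.x = 0, pos.y = 0, lty = 1L, lwd = 1L,
                    num = 1L, nv = 4L, shade = NA_character_,
                    visible = 1L, tag = character()) {
  el <- list(
    shape = as.character(shape),
    size.x = as.numeric(size.x), size.y = as.numeric(size.y),
    theta.1 = as.numeric(theta.1), theta.2 = as.numeric(theta.2),
    rotation = as.numeric(rotation),
    pos.x = as.numeric(pos.x), pos.y = as.numeric(pos.y),
    lty = as.integer(lty), lwd = as.integer(lwd),
    num = as.integer(num), nv = as.integer(nv),
    shade = as.character(shade),
    visible = as.integer(visible),
    tag = as.character(tag)
  )
  validate_element(el)
  el
}

validate_element <- function(el) {
  stopifnot(identical(names(el), .FEATURE_FIELDS))
  if (!(el$nv >= 2L && el$nv <= 100L)) {
    stop("invalid element: nv must be in [2, 100], got ", el$nv)
  }
  if (!(el$size.x > 0 && el$size.y > 0)) {
    stop("invalid element: size.x and size.y must be > 0")
  }
  if (!(el$num %in% c(1L, 2L))) {
    stop("invalid element: num must be 1 (polygon) or 2 (arc)")
  }
  if (is.na(el$visible) || el$visible < 0L) {
    stop("invalid element: visible must be a non-negative integer")
  }
  if (!(el$lwd %in% 1:3)) {
    stop("invalid element: lwd must be in {1, 2, 3}")
  }
  if (!is.na(el$shade) && !(el$shade %in% .SHADES)) {
    stop("invalid element: shade must be one of ",
         paste(.SHADES, collapse = ", "), " or NA")
  }
  invisible(el)
}

#' Construct a figure from elements
#'
#' A figure is an ordered collection of elements plus constituent names.
#' Element order is painter's-algorithm draw order (later elements are drawn
#' on top). `constituent` maps each element to the name it belongs to, so a
#' composite such as a four-line square keeps one name over four elements.
#'
#' @param elements list of feature records (see [element()]).
#' @param name character vector of constituent names.
#' @param constituent integer vector, one entry per element, giving the index
#'   into `name` of the constituent the element belongs to. Defaults to a
#'   one-to-one mapping.
#' @return an object of class `figure`.
#' @export
figure <- function(elements, name, constituent = NULL) {
  stopifnot(is.list(elements), length(elements) >= 1L)
  for (el in elements) validate_element(el)
  name <- as.character(name)
  if (is.null(constituent)) {
    if (length(name) != length(elements)) {
      stop("constituent mapping required when names and elements differ in length")
    }
    constituent <- seq_along(elements)
  }
  constituent <- as.integer(constituent)
  stopifnot(length(constituent) == length(elements),
            all(constituent >= 1L), all(constituent <= length(name)))
  structure(
    list(name = name, elements = elements, constituent = constituent),
    class = "figure"
  )
}

#' @export
print.figure <- function(x, ...) {
  cat("<figure> ", paste(x$name, collapse = ", "),
      " (", length(x$elements), " element",
      if (length(x$elements) != 1L) "s", ")\n", sep = "")
  cat("tags:", paste(sort(figure_tags(x)), collapse = " "), "\n")
  invisible(x)
}

#' Is an object a figure?
#' @param x object to test.
#' @export
is_figure <- function(x) inherits(x, "figure")

#' Union of all property tags carried by a figure's elements
#' @param fig a `figure`.
#' @return character vector of unique tags.
#' @export
figure_tags <- function(fig) {
  stopifnot(is_figure(fig))
  sort(unique(unlist(lapply(fig$elements, `[[`, "tag"))))
}

#' Number of constituent figures
#'
#' A concatenation of k figures counts k; a figure forced single (or a
#' registered composite such as the four-line square) counts 1 regardless of
#' its element count. Rules that require a minimum number of figures (the
#' shape permutation needs exactly 3) count constituents, not elements.
#'
#' @param fig a `figure`.
#' @return integer.
#' @export
count_constituents <- function(fig) {
  stopifnot(is_figure(fig))
  length(fig$name)
}

#' Concatenation of figures
#'
#' Stacks figures into one: the element sequence is the inputs' elements in
#' argument order, so later arguments are drawn on top. By default each
#' constituent keeps its own name and still counts as a separate figure;
#' with `single = TRUE` the result reports exactly one name and is treated
#' as a single figure by rules that count figures.
#'
#' @param ... figures to concatenate, background first.
#' @param single force the result to be a single named figure.
#' @param name the new name when `single = TRUE`.
#' @return a `figure`.
#' @export
cof <- function(..., single = FALSE, name = NULL) {
  figs <- list(...)
  if (length(figs) == 1L && !is_figure(figs[[1]]) && is.list(figs[[1]])) {
    figs <- figs[[1]]
  }
  if (length(figs) < 1L) stop("cof() needs at least one figure")
  for (f in figs) stopifnot(is_figure(f))
  elements <- do.call(c, lapply(figs, `[[`, "elements"))
  if (isTRUE(single)) {
    if (is.null(name)) stop("cof(single = TRUE) requires a name")
    nm <- as.character(name)
    stopifnot(length(nm) == 1L)
    return(figure(elements, nm, rep(1L, length(elements))))
  }
  nms <- unlist(lapply(figs, `[[`, "name"))
  offs <- cumsum(c(0L, utils::head(vapply(figs, function(f) length(f$name), 1L), -1L)))
  cons <- unlist(mapply(function(f, o) f$constituent + o, figs, offs,
                        SIMPLIFY = FALSE))
  figure(elements, nms, as.integer(cons))
}

#' Set the visibility level of figure elements
#'
#' Hidden elements (`level = 0`) are retained in the structure so that
#' logical rules can toggle them back on.
#'
#' @param fig a `figure`.
#' @param indices element indices to modify.
#' @param level new visibility level (non-negative integer).
#' @return a modified copy of `fig`.
#' @export
set_visibility <- function(fig, indices, level) {
  stopifnot(is_figure(fig))
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 1L || max(indices) > length(fig$elements))) {
    stop("set_visibility: element index out of range")
  }
  level <- as.integer(level)
  if (is.na(level) || level < 0L) stop("set_visibility: level must be >= 0")
  for (i in indices) fig$elements[[i]]$visible <- level
  fig
}

# Element indices belonging to constituent k.
constituent_elements <- function(fig, k) which(fig$constituent == k)

# Indices of elements currently drawn.
visible_elements <- function(fig) {
  which(vapply(fig$elements, function(e) e$visible >= 1L, logical(1)))
}

## ---------------------------------------------------------------------------
## Primitive registry

.registry <- new.env(parent = emptyenv())

#' Register a primitive figure
#'
#' The registry is extensible at run time: user-defined primitives become
#' available to [make_primitive()] and to the difference-distractor sampler.
#'
#' @param name primitive name.
#' @param builder zero-argument function returning a `figure` whose elements
#'   already carry the primitive's tags.
#' @export
register_primitive <- function(name, builder) {
  stopifnot(is.character(name), length(name) == 1L, is.function(builder))
  fig <- builder()
  stopifnot(is_figure(fig))
  if (length(figure_tags(fig)) < 1L) {
    stop("every primitive must carry at least one tag")
  }
  assign(name, builder, envir = .registry)
  invisible(name)
}

#' Names of all registered primitives
#' @export
primitives <- function() sort(ls(.registry))

#' Instantiate a primitive figure
#'
#' Returns the registry default for `name` with field overrides applied to
#' every element (composites apply the override to all their parts).
#'
#' @param name a registered primitive name; see [primitives()].
#' @param ... feature-field overrides, e.g. `size.x = 10`, `shade = "black"`.
#' @return a `figure`.
#' @export
#' @examples
#' sq <- make_primitive("square", size.x = 10)
#' figure_tags(sq)
make_primitive <- function(name, ...) {
  if (!exists(name, envir = .registry, inherits = FALSE)) {
    stop("unknown primitive: '", name, "' (see primitives())")
  }
  fig <- get(name, envir = .registry)()
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), .FEATURE_FIELDS)
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown feature field(s): ", paste(bad, collapse = ", "))
    }
    for (i in seq_along(fig$elements)) {
      for (fld in names(overrides)) {
        fig$elements[[i]][[fld]] <- overrides[[fld]]
      }
      fig$elements[[i]] <- do.call(element, fig$elements[[i]])
    }
  }
  fig
}

# One-element primitive helper.
prim1 <- function(name, tag, ...) {
  figure(list(element(shape = name, tag = tag, ...)), name)
}

# Registry defaults. Cell canvas is [-20, 20]^2; full-size primitives use
# size.x = size.y = 15. Tags gate rule and distractor feasibility:
#   fill   -> shade-based operations allowed
#   rotate -> rotation-based operations allowed
#   d.ext / d.int -> eligible as the foreign figure of the Difference
#                    distractor (external outline / internal detail)
populate_registry <- function() {
  tags_closed <- c("simple", "fill", "d.ext", "rotate")

  register_primitive("square", function()
    prim1("square", tags_closed, nv = 4L, rotation = pi / 4))
  register_primitive("triangle", function()
    prim1("triangle", tags_closed, nv = 3L, rotation = pi / 2))
  register_primitive("pentagon", function()
    prim1("pentagon", tags_closed, nv = 5L, rotation = pi / 2))
  register_primitive("hexagon", function()
    prim1("hexagon", tags_closed, nv = 6L))
  # rotating a circle changes nothing, so it carries no rotate tag
  register_primitive("circle", function()
    prim1("circle", c("simple", "fill", "d.ext"), nv = 100L))
  register_primitive("ellipse", function()
    prim1("ellipse", tags_closed, nv = 100L, size.y = 8))
  # black figures
  register_primitive("dot", function()
    prim1("dot", c("simple", "d.int"), nv = 100L,
          size.x = 2.5, size.y = 2.5, shade = "black"))
  # lines: nv = 2, endpoints on the ellipse major axis
  register_primitive("hline", function()
    prim1("hline", c("simple", "rotate"), nv = 2L))
  register_primitive("vline", function()
    prim1("vline", c("simple", "rotate"), nv = 2L, rotation = pi / 2))
  register_primitive("diagline", function()
    prim1("diagline", c("simple", "rotate"), nv = 2L, rotation = pi / 4))
  # circle sections (arcs)
  register_primitive("semicircle", function()
    prim1("semicircle", c("simple", "rotate", "d.ext"),
          nv = 100L, num = 2L, theta.1 = 0, theta.2 = pi))
  register_primitive("arc", function()
    prim1("arc", c("simple", "rotate", "d.int"),
          nv = 100L, num = 2L, theta.1 = 0, theta.2 = pi / 2))

  # square4: a square composed of 4 line segments (one name, 4 elements)
  register_primitive("square4", function() {
    tg <- c("compose4", "d.int")
    s <- 15
    figure(list(
      element("square4", nv = 2L, size.x = s, pos.y = s, tag = tg),
      element("square4", nv = 2L, size.x = s, pos.y = -s, tag = tg),
      element("square4", nv = 2L, size.x = s, rotation = pi / 2, pos.x = -s, tag = tg),
      element("square4", nv = 2L, size.x = s, rotation = pi / 2, pos.x = s, tag = tg)
    ), "square4", rep(1L, 4))
  })

  # miley: a flower of 4 elliptical petals; no fill tag (its color is fixed)
  register_primitive("miley", function() {
    tg <- c("compose4", "rotate", "d.int")
    petal <- function(a) {
      element("miley", nv = 100L, size.x = 8, size.y = 3.5,
              pos.x = 8 * cos(a), pos.y = 8 * sin(a),
              rotation = -a, tag = tg)
    }
    figure(lapply(c(0, pi / 2, pi, 3 * pi / 2), petal),
           "miley", rep(1L, 4))
  })

  # malta cross: 4 triangles pointing inward; fillable but not rotatable
  register_primitive("malta", function() {
    tg <- c("compose4", "fill", "d.int")
    blade <- function(a) {
      element("malta", nv = 3L, size.x = 7, size.y = 7,
              pos.x = 10 * cos(a), pos.y = 10 * sin(a),
              rotation = -(a + pi) + pi / 2, tag = tg)
    }
    figure(lapply(c(0, pi / 2, pi, 3 * pi / 2), blade),
           "malta", rep(1L, 4))
  })

  # eight-shaped: two stacked circles
  register_primitive("eight", function() {
    tg <- c("compose2", "rotate", "d.int")
    figure(list(
      element("eight", nv = 100L, size.x = 7, size.y = 7, pos.y = 7.5, tag = tg),
      element("eight", nv = 100L, size.x = 7, size.y = 7, pos.y = -7.5, tag = tg)
    ), "eight", rep(1L, 2))
  })

  # other figures: an upright cross of two lines
  register_primitive("cross", function() {
    tg <- c("compose2", "rotate", "d.int")
    figure(list(
      element("cross", nv = 2L, size.x = 15, tag = tg),
      element("cross", nv = 2L, size.x = 15, rotation = pi / 2, tag = tg)
    ), "cross", rep(1L, 2))
  })

  invisible(NULL)
}

## ---------------------------------------------------------------------------
## Figure equality

#' Compare two figures for display equality
#'
#' Compares the visible elements of both figures field by field, in order:
#' exact match on discrete fields, tolerance `tol` on numeric fields, set
#' equality on tags. Used by the response-list generator to detect
#' degenerate distractors (options equal to the correct response).
#'
#' @param a,b figures.
#' @param tol numeric tolerance.
#' @return logical.
#' @export
figure_equal <- function(a, b, tol = 1e-9) {
  stopifnot(is_figure(a), is_figure(b))
  va <- visible_elements(a)
  vb <- visible_elements(b)
  if (length(va) != length(vb)) return(FALSE)
  for (k in seq_along(va)) {
    ea <- a$elements[[va[k]]]
    eb <- b$elements[[vb[k]]]
    for (fld in .NUMERIC_FIELDS) {
      if (abs(ea[[fld]] - eb[[fld]]) > tol) return(FALSE)
    }
    for (fld in c("shape", "lty", "lwd", "num", "nv", "visible")) {
      if (!identical(ea[[fld]], eb[[fld]])) return(FALSE)
    }
    sa <- ea$shade; sb <- eb$shade
    if (is.na(sa) != is.na(sb)) return(FALSE)
    if (!is.na(sa) && sa != sb) return(FALSE)
    if (!setequal(ea$tag, eb$tag)) return(FALSE)
  }
  TRUE
}

.onLoad <- function(libname, pkgname) {
  populate_registry()
}
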