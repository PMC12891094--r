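# --- geometry -----------------------------------------------------------
# An element is a regular nv-gon inscribed in the (size.x, size.y) ellipse
# (num = 1) or an arc from theta.1 to theta.2 (num = 2), rotated clockwise
# by `rotation` about (pos.x, pos.y). Canvas is [-20, 20]^2, y up.

element_points <- function(el, n_arc = 72L) {
  if (el$num == 2L) {
    b <- seq(el$theta.1, el$theta.2, length.out = max(n_arc, 8L))
    closed <- FALSE
  } else {
    b <- 2 * pi * (seq_len(el$nv) - 1L) / el$nv
    closed <- el$nv > 2L
  }
  px <- el$size.x * cos(b)
  py <- el$size.y * sin(b)
  r <- el$rotation  # clockwise-positive
  x <- el$pos.x + px * cos(r) + py * sin(r)
  y <- el$pos.y - px * sin(r) + py * cos(r)
  list(x = x, y = y, closed = closed)
}

.SHADE_HEX <- c(white = "#FFFFFF", gray = "#808080", black = "#000000")

element_fill <- function(el) {
  if (is.na(el$shade)) "none" else unname(.SHADE_HEX[el$shade])
}

# --- panel assembly -----------------------------------------------------
# Everything drawable is first normalized to a list of panels:
# list(fig = figure or NULL (blank), label = character or NA).

panels_of <- function(obj, ...) UseMethod("panels_of")

#' @export
panels_of.figure <- function(obj, label = NA_character_, ...) {
  list(list(fig = obj, label = label))
}

#' @export
panels_of.matriks <- function(obj, hide = TRUE, question = FALSE, ...) {
  n <- obj$mat.type
  panels <- lapply(seq_len(n), function(k) {
    fig <- obj[[paste0("Sq", k)]]
    blank <- hide && k == n
    if (blank) fig <- NULL  # the respondent-facing blank cell
    list(fig = fig, label = NA_character_,
         question = blank && isTRUE(question))
  })
  panels
}

#' @export
panels_of.response_list <- function(obj, distractors = NULL, main = FALSE,
                                    labels = NULL, ...) {
  nms <- if (is.null(distractors)) names(obj) else as.character(distractors)
  unknown <- setdiff(nms, names(obj))
  if (length(unknown)) {
    stop("unknown response option(s): ", paste(unknown, collapse = ", "))
  }
  labs <- if (!is.null(labels)) {
    if (length(labels) != length(nms)) {
      stop("labels length (", length(labels),
           ") must equal the number of drawn panels (", length(nms), ")")
    }
    as.character(labels)
  } else if (isTRUE(main)) {
    nms
  } else {
    rep(NA_character_, length(nms))
  }
  mapply(function(nm, lb) list(fig = obj[[nm]], label = lb),
         nms, labs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

panel_grid <- function(obj, n_panels) {
  if (is_matriks(obj)) {
    side <- if (obj$mat.type == 9L) 3L else 2L
    c(side, side)
  } else {
    ncol <- min(n_panels, 4L)
    c(ceiling(n_panels / ncol), ncol)
  }
}

# --- SVG ----------------------------------------------------------------

.PANEL_PX <- 100      # panel edge, px
.PANEL_SCALE <- 2.25  # 90 px drawing area over the 40-unit canvas (5% margin)

fmt_num <- function(x) {
  x <- round(x, 3)
  x[abs(x) < 5e-4] <- 0
  sprintf("%.3f", x)
}

svg_element <- function(el, ox, oy) {
  if (el$visible < 1L) return(character(0))
  p <- element_points(el)
  x <- ox + .PANEL_PX / 2 + .PANEL_SCALE * p$x
  y <- oy + .PANEL_PX / 2 - .PANEL_SCALE * p$y
  pts <- paste(paste0(fmt_num(x), ",", fmt_num(y)), collapse = " ")
  fill <- element_fill(el)
  closed <- p$closed || fill != "none"
  dash <- switch(el$lty, NULL, "13.5,9", "2.25,6.75")
  attrs <- paste0(
    ' fill="', fill, '" stroke="#000000" stroke-width="', el$lwd, '"',
    if (!is.null(dash)) paste0(' stroke-dasharray="', dash, '"')
  )
  if (closed) {
    paste0('<polygon points="', pts, '"', attrs, ' />')
  } else {
    paste0('<polyline points="', pts, '"', attrs, ' fill="none" />')
  }
}

svg_panel <- function(panel, ox, oy) {
  out <- c(
    paste0('<g class="panel" transform="translate(0,0)">'),
    paste0('<rect x="', fmt_num(ox), '" y="', fmt_num(oy),
           '" width="', .PANEL_PX, '" height="', .PANEL_PX,
           '" fill="#FFFFFF" stroke="#000000" stroke-width="1" />')
  )
  if (!is.null(panel$fig)) {
    for (el in panel$fig$elements) {
      out <- c(out, svg_element(el, ox, oy))
    }
  }
  if (isTRUE(panel$question)) {
    out <- c(out, paste0(
      '<text x="', fmt_num(ox + .PANEL_PX / 2), '" y="',
      fmt_num(oy + .PANEL_PX / 2 + 12),
      '" font-family="sans-serif" font-size="36" text-anchor="middle">',
      '?</text>'))
  }
  if (!is.na(panel$label)) {
    out <- c(out, paste0(
      '<text x="', fmt_num(ox + .PANEL_PX / 2), '" y="',
      fmt_num(oy + .PANEL_PX - 3),
      '" font-family="sans-serif" font-size="8" text-anchor="middle">',
      panel$label, '</text>'))
  }
  c(out, '</g>')
}

#' Render an object to an SVG string
#'
#' Figures render as one panel; matrices as their cell grid with the last
#' cell blank; response lists as labeled option panels (optionally a named
#' subset, in the given order). The output is a deterministic function of
#' the object and arguments, so identical inputs give byte-identical SVG.
#'
#' @param obj a `figure`, `matriks`, or `response_list`.
#' @param ... passed to the panel builder: `hide` (matrices; default TRUE
#'   blanks the last cell), `question` (matrices; draw a question mark in
#'   the blank cell, off by default), `distractors` (response lists; subset
#'   of option names), `main` (logical; print option names under the
#'   panels), `labels` (custom panel labels).
#' @return a character scalar containing an SVG 1.1 document.
#' @export
render_svg <- function(obj, ...) {
  panels <- panels_of(obj, ...)
  grid <- panel_grid(obj, length(panels))
  nrow <- grid[1]; ncol <- grid[2]
  w <- ncol * .PANEL_PX
  h <- nrow * .PANEL_PX
  body <- character(0)
  for (k in seq_along(panels)) {
    i <- (k - 1L) %/% ncol
    j <- (k - 1L) %% ncol
    body <- c(body, svg_panel(panels[[k]], j * .PANEL_PX, i * .PANEL_PX))
  }
  paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="',
           w, '" height="', h, '" viewBox="0 0 ', w, ' ', h, '">'),
    body,
    '</svg>'
  ), collapse = "\n")
}

# --- base-graphics drawing ---------------------------------------------

draw_panel_base <- function(panel) {
  graphics::plot.new()
  graphics::plot.window(xlim = c(-21, 21), ylim = c(-21, 21), asp = 1)
  graphics::box()
  if (!is.null(panel$fig)) {
    for (el in panel$fig$elements) {
      if (el$visible < 1L) next
      p <- element_points(el)
      fill <- element_fill(el)
      if (p$closed || fill != "none") {
        graphics::polygon(p$x, p$y,
                          col = if (fill == "none") NA else fill,
                          border = "black", lty = el$lty, lwd = el$lwd)
      } else {
        graphics::lines(p$x, p$y, lty = el$lty, lwd = el$lwd)
      }
    }
  }
  if (isTRUE(panel$question)) {
    graphics::text(0, 0, "?", cex = 3)
  }
  if (!is.na(panel$label)) {
    graphics::mtext(panel$label, side = 1, line = 0, cex = 0.7)
  }
}

#' Draw a figure, matrix, or response list
#'
#' Prints the object on the active graphics device: a single panel for a
#' figure, the cell grid (blank last cell) for a matrix, and the option
#' panels for a response list. With `main = TRUE` the option names are
#' displayed under the corresponding panels; `distractors` selects a subset
#' of options; `labels` overrides the printed names.
#'
#' @param obj a `figure`, `matriks`, or `response_list`.
#' @param ... see [render_svg()] for the accepted arguments.
#' @return invisibly, a list with the number of drawn `panels`.
#' @export
#' @examples
#' \donttest{
#' draw(make_primitive("square"))
#' }
draw <- function(obj, ...) {
  panels <- panels_of(obj, ...)
  grid <- panel_grid(obj, length(panels))
  old <- graphics::par(mfrow = grid, mar = c(1.2, 0.4, 0.4, 0.4))
  on.exit(graphics::par(old))
  for (panel in panels) draw_panel_base(panel)
  invisible(list(panels = length(panels)))
}

# --- export -------------------------------------------------------------

path_stem <- function(path) sub("\\.[A-Za-z0-9]+$", "", path)

write_one <- function(obj, path, format, dpi, ...) {
  if (format == "svg") {
    writeLines(render_svg(obj, ...), path)
  } else {
    panels <- panels_of(obj, ...)
    grid <- panel_grid(obj, length(panels))
    grDevices::png(path, width = grid[2] * dpi, height = grid[1] * dpi,
                   res = dpi, type = "cairo")
    on.exit(grDevices::dev.off())
    draw(obj, ...)
  }
  path
}

#' Export an object to image files
#'
#' Writes SVG (exact vector primitives, byte-deterministic) or PNG at the
#' requested resolution. In composite mode one file is written; in split
#' mode, one file per matrix cell (`<stem>_SqN.<ext>`) or per response
#' option (`<stem>_<option>.<ext>`).
#'
#' @param obj a `figure`, `matriks`, or `response_list`.
#' @param path output file path; the extension is replaced per `format`.
#' @param format `"svg"` or `"png"`.
#' @param dpi raster resolution (PNG panels are `dpi` pixels square).
#' @param split write one file per cell/option instead of one composite.
#' @param ... passed to the panel builder (see [render_svg()]).
#' @return character vector of the file paths written.
#' @export
export <- function(obj, path, format = c("svg", "png"), dpi = 96L,
                   split = FALSE, ...) {
  format <- match.arg(format)
  stem <- path_stem(path)
  if (!split) {
    return(write_one(obj, paste0(stem, ".", format), format, dpi, ...))
  }
  if (is_matriks(obj)) {
    n <- obj$mat.type
    vapply(seq_len(n), function(k) {
      fig <- if (k == n) NULL else obj[[paste0("Sq", k)]]
      p <- paste0(stem, "_Sq", k, ".", format)
      if (is.null(fig)) {
        blank <- structure(list(name = "blank", elements = list(),
                                constituent = integer(0)), class = "figure")
        # an empty panel: write the border-only SVG/PNG directly
        if (format == "svg") {
          writeLines(paste(c(
            '<?xml version="1.0" encoding="UTF-8"?>',
            paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="100" height="100" viewBox="0 0 100 100">'),
            svg_panel(list(fig = NULL, label = NA_character_), 0, 0),
            '</svg>'), collapse = "\n"), p)
        } else {
          grDevices::png(p, width = dpi, height = dpi, res = dpi,
                         type = "cairo")
          draw_panel_blank()
          grDevices::dev.off()
        }
      } else {
        write_one(fig, p, format, dpi)
      }
      p
    }, character(1))
  } else if (is_response_list(obj)) {
    vapply(names(obj), function(nm) {
      p <- paste0(stem, "_", nm, ".", format)
      write_one(obj[[nm]], p, format, dpi)
      p
    }, character(1), USE.NAMES = FALSE)
  } else {
    write_one(obj, paste0(stem, ".", format), format, dpi, ...)
  }
}

draw_panel_blank <- function() {
  old <- graphics::par(mar = c(1.2, 0.4, 0.4, 0.4))
  on.exit(graphics::par(old))
  draw_panel_base(list(fig = NULL, label = NA_character_))
}
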