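# Base rule name used for directional-logic classification: "size.inv" and
# "size" are the same rule; "rotation.5" classifies as "rotation".
rule_base_name <- function(name) {
  name <- sub("\\.inv$", "", name)
  sub("^rotation(\\.[1-9])?$", "rotation", name)
}

is_reverse_name <- function(name) grepl("\\.inv$", name)

is_logical_name <- function(name) name %in% .LOGICAL_RULES

#' Build a Raven-like matrix from a start figure and rule lists
#'
#' The cell grid is row-major with `Sq1` top-left; the respondent-facing
#' blank is always the last cell (`Sq9` for 3x3, `Sq4` for 2x2). Generation
#' proceeds in three steps: (1) every cell is populated with `start`;
#' (2) if a logical rule (AND/OR/XOR) is requested it must be the only
#' non-identity rule, on a nine-cell matrix, in a single direction — the
#' whole matrix is then generated in one pass, one seeded set partition per
#' row (horizontal logic) or column (vertical logic); (3) otherwise every
#' horizontal rule is applied to each cell with step `n` equal to the
#' column index, then every vertical rule with `n` equal to the row index,
#' so a rule named in both directions accumulates.
#'
#' @param start a `figure`; the content of cell Sq1 before vertical rules.
#' @param hrules character vector of rule names applied with horizontal
#'   directional logic (variation across columns).
#' @param vrules character vector of rule names applied with vertical
#'   directional logic (variation across rows).
#' @param mat.type 9 (3x3) or 4 (2x2).
#' @param seed integer seed driving the logical-rule partitions.
#' @return an object of class `matriks`: a named list with entries
#'   `Sq1..SqN`, `hrule`, `vrule`, `mat.type`.
#' @export
#' @examples
#' m <- mat_apply(make_primitive("square", size.x = 10),
#'                hrules = "size", vrules = "size")
#' names(m)
mat_apply <- function(start, hrules = "identity", vrules = "identity",
                      mat.type = 9, seed = 42L) {
  stopifnot(is_figure(start))
  mat.type <- as.integer(mat.type)
  if (!(mat.type %in% c(4L, 9L))) stop("mat.type must be 4 or 9")
  hrules <- as.character(hrules)
  vrules <- as.character(vrules)
  if (!length(hrules)) hrules <- "identity"
  if (!length(vrules)) vrules <- "identity"
  # resolve every rule up front so unknown names fail before any work
  for (r in c(hrules, vrules)) rule_registry_lookup(r)

  side <- if (mat.type == 9L) 3L else 2L
  cells <- rep(list(start), mat.type)

  h_logic <- hrules[is_logical_name(hrules)]
  v_logic <- vrules[is_logical_name(vrules)]
  logic <- c(h_logic, v_logic)

  if (length(logic)) {
    others <- setdiff(c(hrules, vrules), c(.LOGICAL_RULES, "identity"))
    if (length(others)) {
      stop("a logical rule cannot be combined with a visuospatial rule (",
           paste(others, collapse = ", "), ")")
    }
    if (mat.type == 4L) {
      stop("a logical rule cannot be used to generate a four-cell matrix")
    }
    if (length(h_logic) && length(v_logic)) {
      if (identical(unique(h_logic), unique(v_logic))) {
        stop("a logical rule cannot be applied in both directions at once")
      }
      stop("two different logical rules cannot be concurrently applied to ",
           "the same figures with differing directional logic")
    }
    if (length(logic) > 1L) {
      stop("only one logical rule can be applied at a time")
    }
    rule <- logic[1]
    if (length(h_logic)) {
      for (i in seq_len(side)) {
        row <- make_logical_row(rule, start, i, seed)
        for (j in seq_len(side)) cells[[(i - 1L) * side + j]] <- row[[j]]
      }
    } else {
      for (j in seq_len(side)) {
        col <- make_logical_row(rule, start, j, seed)
        for (i in seq_len(side)) cells[[(i - 1L) * side + j]] <- col[[i]]
      }
    }
  } else {
    for (r in hrules) {
      for (i in seq_len(side)) {
        for (j in seq_len(side)) {
          k <- (i - 1L) * side + j
          cells[[k]] <- apply_rule(r, cells[[k]], n = j)
        }
      }
    }
    for (r in vrules) {
      for (i in seq_len(side)) {
        for (j in seq_len(side)) {
          k <- (i - 1L) * side + j
          cells[[k]] <- apply_rule(r, cells[[k]], n = i)
        }
      }
    }
  }

  m <- c(stats::setNames(cells, paste0("Sq", seq_len(mat.type))),
         list(hrule = hrules, vrule = vrules, mat.type = mat.type))
  structure(m, class = "matriks",
            n_layers = 1L,
            layer_rules = list(list(hrule = hrules, vrule = vrules)),
            seed = as.integer(seed))
}

#' Is an object a matriks?
#' @param x object to test.
#' @export
is_matriks <- function(x) inherits(x, "matriks")

#' @export
print.matriks <- function(x, ...) {
  side <- if (x$mat.type == 9L) 3L else 2L
  cat("<matriks> ", side, "x", side, ", ", n_layers(x), " layer",
      if (n_layers(x) != 1L) "s", "\n", sep = "")
  cat("hrule:", paste(x$hrule, collapse = ", "), "\n")
  cat("vrule:", paste(x$vrule, collapse = ", "), "\n")
  invisible(x)
}

#' Number of layers of a matrix
#' @param m a `matriks`.
#' @export
n_layers <- function(m) attr(m, "n_layers")

#' Per-layer rule provenance
#' @param m a `matriks`.
#' @return list with one `(hrule, vrule)` record per layer, background first.
#' @export
layer_rules <- function(m) attr(m, "layer_rules")

# Single-layer matrices that make up m, background first.
mat_layers <- function(m) {
  ls <- attr(m, "layers")
  if (is.null(ls)) list(m) else ls
}

#' Concatenation of matrices (layering)
#'
#' Stacks single-layer (or multi-layer) matrices into one multi-layer
#' matrix: each cell is the concatenation of the corresponding layer cells,
#' ordered from the background (first argument) to the foreground (last
#' argument), which is drawn on top. The layer hierarchy drives the
#' incomplete-correlate distractors.
#'
#' @param ... `matriks` objects sharing the same `mat.type`.
#' @return a `matriks` with `n_layers` equal to the total layer count.
#' @export
com <- function(...) {
  layers <- list(...)
  if (length(layers) < 1L) stop("com() needs at least one matrix")
  for (m in layers) stopifnot(is_matriks(m))
  mt <- unique(vapply(layers, function(m) m$mat.type, integer(1)))
  if (length(mt) != 1L) {
    stop("all layers must share the same mat.type; got ",
         paste(mt, collapse = " and "))
  }
  flat <- do.call(c, lapply(layers, mat_layers))
  if (length(flat) == 1L) return(flat[[1]])
  cellnames <- paste0("Sq", seq_len(mt))
  cells <- lapply(cellnames, function(nm) {
    do.call(cof, lapply(flat, `[[`, nm))
  })
  m <- c(stats::setNames(cells, cellnames),
         list(hrule = unlist(lapply(flat, `[[`, "hrule")),
              vrule = unlist(lapply(flat, `[[`, "vrule")),
              mat.type = mt))
  structure(m, class = "matriks",
            n_layers = length(flat),
            layer_rules = do.call(c, lapply(flat, layer_rules)),
            layers = flat,
            seed = attr(flat[[1]], "seed"))
}

#' The figure completing the matrix
#'
#' Returns the content of the blank (last) cell: `Sq9` for nine-cell
#' matrices, `Sq4` for four-cell ones. Distractors are defined relative to
#' this figure.
#'
#' @param m a `matriks`.
#' @return a `figure`.
#' @export
correct_response <- function(m) {
  stopifnot(is_matriks(m))
  m[[paste0("Sq", m$mat.type)]]
}

#' Directional logic of every manipulated rule
#'
#' A rule named only in `hrule` varies across columns (H); only in `vrule`,
#' across rows (V). The same rule in both directions defines a diagonal
#' logic: TL-LR (main diagonal) when one occurrence is reverse and the
#' other forward, LL-TR (secondary diagonal) when both are forward or both
#' reverse.
#'
#' @param m a `matriks`.
#' @return named character vector mapping base rule names to `"H"`, `"V"`,
#'   `"TL-LR"`, or `"LL-TR"`. Identity is not reported.
#' @export
classify_direction <- function(m) {
  stopifnot(is_matriks(m))
  h <- setdiff(m$hrule, "identity")
  v <- setdiff(m$vrule, "identity")
  bases <- unique(c(rule_base_name(h), rule_base_name(v)))
  out <- character(0)
  for (b in bases) {
    hb <- h[rule_base_name(h) == b]
    vb <- v[rule_base_name(v) == b]
    out[b] <- if (length(hb) && !length(vb)) {
      "H"
    } else if (!length(hb) && length(vb)) {
      "V"
    } else if (xor(any(is_reverse_name(hb)), any(is_reverse_name(vb)))) {
      "TL-LR"
    } else {
      "LL-TR"
    }
  }
  out
}
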