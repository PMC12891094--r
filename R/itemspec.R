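# JSON item-spec dialect. A figure serializes as
#   {"name": [str], "constituent": [int], "elements": [{15 fields}], "tags": [str]}
# and an item as
#   {"name": str, "start": figure-spec | [figure-spec per layer],
#    "hrules": [[str]], "vrules": [[str]], "mat_type": 4|9, "seed": int}
# Each (start, hrules, vrules) triple is one layer, background first.

#' Serialize a figure to its item-spec representation
#' @param fig a `figure`.
#' @return a plain list mirroring the JSON dialect.
#' @export
figure_to_spec <- function(fig) {
  stopifnot(is_figure(fig))
  list(
    name = as.list(fig$name),
    constituent = as.list(fig$constituent),
    elements = lapply(fig$elements, function(e) {
      e$tag <- as.list(e$tag)
      e
    }),
    tags = as.list(figure_tags(fig))
  )
}

spec_chr <- function(x) as.character(unlist(x))
spec_num <- function(x) if (is.null(x) || (length(x) == 1L && is.null(x[[1]]))) NA_real_ else as.numeric(unlist(x))

#' Rebuild a figure from its item-spec representation
#' @param spec a list as produced by [figure_to_spec()] (or parsed JSON).
#' @return a `figure`.
#' @export
figure_from_spec <- function(spec) {
  els <- lapply(spec$elements, function(e) {
    shade <- e$shade
    if (is.null(shade) || length(shade) == 0L) shade <- NA_character_
    element(
      shape = spec_chr(e$shape),
      size.x = as.numeric(e$size.x), size.y = as.numeric(e$size.y),
      theta.1 = as.numeric(e$theta.1), theta.2 = as.numeric(e$theta.2),
      rotation = as.numeric(e$rotation),
      pos.x = as.numeric(e$pos.x), pos.y = as.numeric(e$pos.y),
      lty = as.integer(e$lty), lwd = as.integer(e$lwd),
      num = as.integer(e$num), nv = as.integer(e$nv),
      shade = as.character(shade),
      visible = as.integer(e$visible),
      tag = spec_chr(e$tag)
    )
  })
  figure(els, spec_chr(spec$name), as.integer(unlist(spec$constituent)))
}

#' Write a figure to a JSON file
#' @param fig a `figure`.
#' @param path output path.
#' @export
write_figure_json <- function(fig, path) {
  jsonlite::write_json(figure_to_spec(fig), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a figure from a JSON file
#' @param path input path.
#' @return a `figure`.
#' @export
read_figure_json <- function(path) {
  figure_from_spec(jsonlite::read_json(path, simplifyVector = FALSE))
}

# Normalize an item spec so start / hrules / vrules are per-layer lists.
normalize_item_spec <- function(spec) {
  start <- spec$start
  if (!is.null(start$elements)) start <- list(start)  # single figure spec
  n <- length(start)
  norm_rules <- function(r) {
    if (is.null(r)) r <- "identity"
    if (!is.list(r)) r <- list(r)
    r <- lapply(r, spec_chr)
    if (length(r) == 1L && n > 1L) r <- rep(r, n)
    if (length(r) != n) {
      stop("item spec: rule lists must have one entry per layer")
    }
    r
  }
  list(
    name = if (is.null(spec$name)) NA_character_ else spec_chr(spec$name),
    start = start,
    hrules = norm_rules(spec$hrules),
    vrules = norm_rules(spec$vrules),
    mat_type = if (is.null(spec$mat_type)) 9L else as.integer(spec$mat_type),
    seed = if (is.null(spec$seed)) 42L else as.integer(spec$seed)
  )
}

#' Build the matrix described by an item spec
#'
#' Each layer's `(start, hrules, vrules)` triple is realized with
#' [mat_apply()] and the layers are composed with [com()], background
#' first.
#'
#' @param spec an item spec (list or parsed JSON).
#' @return a `matriks`.
#' @export
build_item <- function(spec) {
  spec <- normalize_item_spec(spec)
  layers <- lapply(seq_along(spec$start), function(i) {
    mat_apply(figure_from_spec(spec$start[[i]]),
              hrules = spec$hrules[[i]],
              vrules = spec$vrules[[i]],
              mat.type = spec$mat_type,
              seed = spec$seed)
  })
  do.call(com, layers)
}

#' Dry-run validation of an item spec
#'
#' Checks the preconditions of [build_item()] without rendering anything:
#' rule names must resolve; logical rules cannot be combined with a
#' visuospatial rule in the same layer, used on a four-cell matrix, or
#' applied with differing directional logic; the shape rule needs a
#' concatenation of exactly three single figures; rotation and shade need
#' the `rotate` / `fill` tags.
#'
#' @param spec an item spec (list or parsed JSON).
#' @return character vector of violations (empty when valid).
#' @export
validate_item_spec <- function(spec) {
  violations <- character(0)
  note <- function(...) violations <<- c(violations, paste0(...))
  spec <- tryCatch(normalize_item_spec(spec), error = function(e) {
    note(conditionMessage(e))
    NULL
  })
  if (is.null(spec)) return(violations)
  if (!(spec$mat_type %in% c(4L, 9L))) {
    note("mat_type must be 4 or 9, got ", spec$mat_type)
  }
  for (i in seq_along(spec$start)) {
    where <- paste0("layer ", i, ": ")
    fig <- tryCatch(figure_from_spec(spec$start[[i]]), error = function(e) {
      note(where, "invalid start figure: ", conditionMessage(e))
      NULL
    })
    rules <- c(spec$hrules[[i]], spec$vrules[[i]])
    for (r in rules) {
      ok <- tryCatch({rule_registry_lookup(r); TRUE},
                     error = function(e) {
                       note(where, conditionMessage(e))
                       FALSE
                     })
    }
    known <- rules[vapply(rules, function(r)
      !inherits(tryCatch(rule_registry_lookup(r), error = identity), "error"),
      logical(1))]
    logic <- known[is_logical_name(known)]
    others <- setdiff(known, c(.LOGICAL_RULES, "identity"))
    if (length(logic)) {
      if (length(others)) {
        note(where, "a logical rule cannot be combined with a visuospatial rule (",
             paste(others, collapse = ", "), ")")
      }
      if (spec$mat_type == 4L) {
        note(where, "a logical rule cannot be used to generate a four-cell matrix")
      }
      hl <- spec$hrules[[i]][is_logical_name(spec$hrules[[i]])]
      vl <- spec$vrules[[i]][is_logical_name(spec$vrules[[i]])]
      if (length(hl) && length(vl)) {
        note(where, "logical rules cannot be applied with differing directional logic")
      }
      if (!is.null(fig) && length(fig$elements) < 3L) {
        note(where, "logical rules require a start figure with at least 3 elements")
      }
    }
    if (!is.null(fig)) {
      tgs <- figure_tags(fig)
      if (any(rule_base_name(known) == "shape") && count_constituents(fig) != 3L) {
        note(where, "the shape rule requires a concatenation of exactly 3 single figures")
      }
      if (any(rule_base_name(known) == "rotation") && !("rotate" %in% tgs)) {
        note(where, "the rotation rule requires the 'rotate' tag")
      }
      if (any(rule_base_name(known) %in% c("shade", "multi.shade")) &&
          !("fill" %in% tgs)) {
        note(where, "the shade rules require the 'fill' tag")
      }
    }
  }
  violations
}

#' Write an item spec to a JSON file
#' @param spec an item spec.
#' @param path output path.
#' @export
write_item_spec <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an item spec from a JSON file
#' @param path input path.
#' @export
read_item_spec <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Serialize a matrix with cells, rules, and layer provenance
#' @param m a `matriks`.
#' @return a plain list mirroring the JSON dialect.
#' @export
matriks_to_spec <- function(m) {
  stopifnot(is_matriks(m))
  cells <- lapply(paste0("Sq", seq_len(m$mat.type)), function(nm)
    figure_to_spec(m[[nm]]))
  names(cells) <- paste0("Sq", seq_len(m$mat.type))
  c(cells, list(hrule = as.list(m$hrule), vrule = as.list(m$vrule),
                mat.type = m$mat.type, n_layers = n_layers(m),
                layer_rules = layer_rules(m)))
}

#' Serialize a response list (11 named options, warnings, seed)
#' @param rl a `response_list`.
#' @return a plain list mirroring the JSON dialect; the key is stored under
#'   `"correct"` explicitly.
#' @export
response_list_to_spec <- function(rl) {
  stopifnot(is_response_list(rl))
  list(
    options = lapply(rl, figure_to_spec),
    crossed = as.list(names(rl)[vapply(rl, is_crossed, logical(1))]),
    warnings = response_warnings(rl),
    seed = attr(rl, "seed")
  )
}
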