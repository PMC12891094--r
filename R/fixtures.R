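# Randomized-but-valid item specs for property testing: every sampled spec
# satisfies the mat_apply() preconditions by construction.

# start-figure pools keyed by what the rule needs
.START_ANY <- c("square", "circle", "hexagon", "pentagon", "triangle", "ellipse")
.START_ROTATE <- c("square", "hexagon", "pentagon", "triangle", "ellipse")
.START_FILL <- c("square", "circle", "hexagon", "pentagon", "triangle",
                 "ellipse", "malta")
.START_LOGICAL <- c("square4", "miley")  # >= 3 elements each

.DEFAULT_RULES <- c("size", "size.inv", "rotation", "rotation.inv",
                    "shape", "shape.inv", "shade", "lty", "lwd",
                    "AND", "OR", "XOR")

#' Configuration for the fixture generator
#'
#' @param seed integer seed for the fixture stream (independent of the item
#'   seeds it emits).
#' @param n_items number of item specs to sample.
#' @param allowed_rules rule names the sampler may use.
#' @param layer_range integer `c(min, max)` number of layers, within 1..4.
#' @param mat_types subset of `c(4, 9)`.
#' @param include_degenerate also emit the known warning-path cases
#'   (single-layer matrix, vertical-only rule, unfillable foreground).
#' @return a list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_items = 10L,
                           allowed_rules = .DEFAULT_RULES,
                           layer_range = c(1L, 2L),
                           mat_types = c(4L, 9L),
                           include_degenerate = FALSE) {
  allowed_rules <- as.character(allowed_rules)
  if (!length(allowed_rules)) stop("allowed_rules must be non-empty")
  for (r in allowed_rules) rule_registry_lookup(r)
  layer_range <- as.integer(layer_range)
  if (length(layer_range) != 2L || layer_range[1] < 1L || layer_range[2] > 4L ||
      layer_range[1] > layer_range[2]) {
    stop("layer_range must be c(min, max) within [1, 4]")
  }
  mat_types <- as.integer(mat_types)
  if (!length(mat_types) || !all(mat_types %in% c(4L, 9L))) {
    stop("mat_types must be a non-empty subset of c(4, 9)")
  }
  if (all(is_logical_name(allowed_rules)) && !(9L %in% mat_types)) {
    stop("unsatisfiable config: logical rules require nine-cell matrices")
  }
  structure(list(seed = as.integer(seed), n_items = as.integer(n_items),
                 allowed_rules = allowed_rules, layer_range = layer_range,
                 mat_types = mat_types,
                 include_degenerate = isTRUE(include_degenerate)),
            class = "fixture_config")
}

# one layer spec (start figure + rules) for a sampled rule
sample_layer <- function(rule) {
  base <- rule_base_name(rule)
  if (is_logical_name(rule)) {
    start <- make_primitive(sample(.START_LOGICAL, 1L))
    if (stats::runif(1) < 0.5) {
      return(list(start = figure_to_spec(start), hrules = rule,
                  vrules = "identity"))
    }
    return(list(start = figure_to_spec(start), hrules = "identity",
                vrules = rule))
  }
  start <- switch(base,
    shape = {
      nms <- sample(.START_ANY, 3L)
      do.call(cof, lapply(nms, make_primitive))
    },
    rotation = make_primitive(sample(.START_ROTATE, 1L)),
    shade = ,
    multi.shade = make_primitive(sample(.START_FILL, 1L)),
    make_primitive(sample(.START_ANY, 1L))
  )
  # incremental rules occasionally go diagonal (same rule, both directions)
  diagonal <- base %in% c("size", "rotation") && stats::runif(1) < 0.2
  horizontal <- stats::runif(1) < 0.5
  list(
    start = figure_to_spec(start),
    hrules = if (horizontal || diagonal) rule else "identity",
    vrules = if (!horizontal || diagonal) rule else "identity"
  )
}

degenerate_specs <- function() {
  list(
    # single layer: triggers the IC-Inc warning
    list(name = "degenerate_single_layer",
         start = figure_to_spec(make_primitive("square")),
         hrules = list("shade"), vrules = list("identity"),
         mat_type = 9L, seed = 42L),
    # vertical-only rule: r_left (Sq8) equals the correct response
    list(name = "degenerate_vertical_only",
         start = figure_to_spec(make_primitive("square")),
         hrules = list("identity"), vrules = list("shade"),
         mat_type = 9L, seed = 42L),
    # no layer supports the fill manipulation: ic_neg falls back
    tutorial_item()
  )
}

#' Sample randomized-but-valid item specs
#'
#' Every emitted spec passes [build_item()] without error: logical rules
#' are only paired with nine-cell matrices and starts of at least three
#' elements (alone in their layer), shape rules with concatenations of
#' three single figures, rotation/shade rules with suitably tagged starts.
#' The same config seed reproduces the same spec sequence.
#'
#' @param cfg a [fixture_config()].
#' @return list of item specs (see [build_item()]).
#' @export
sample_item_spec <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  specs <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_items), function(i) {
      n_layers <- sample(seq(cfg$layer_range[1], cfg$layer_range[2]), 1L)
      rules <- sample(cfg$allowed_rules, n_layers, replace = TRUE)
      mat_type <- if (any(is_logical_name(rules))) 9L else
        sample(cfg$mat_types, 1L)
      layers <- lapply(rules, sample_layer)
      list(
        name = sprintf("item_%03d", i),
        start = lapply(layers, `[[`, "start"),
        hrules = lapply(layers, `[[`, "hrules"),
        vrules = lapply(layers, `[[`, "vrules"),
        mat_type = mat_type,
        seed = sample.int(10000L, 1L)
      )
    })
  })
  if (cfg$include_degenerate) specs <- c(specs, degenerate_specs())
  specs
}

#' The worked tutorial item: a two-layer 3x3 logic matrix
#'
#' Layer 1 (background): the AND rule applied with horizontal logic to a
#' square composed of four lines. Layer 2 (foreground): the OR rule applied
#' with vertical logic to a four-petal flower. Neither layer can change its
#' filling color, so the response list of this item carries an `ic_neg`
#' crossed-out fallback.
#'
#' @param seed integer seed for the logical partitions.
#' @return an item spec (see [build_item()]).
#' @export
tutorial_item <- function(seed = 42L) {
  list(
    name = "tutorial",
    start = list(figure_to_spec(make_primitive("square4")),
                 figure_to_spec(make_primitive("miley"))),
    hrules = list("AND", "identity"),
    vrules = list("identity", "OR"),
    mat_type = 9L,
    seed = as.integer(seed)
  )
}
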