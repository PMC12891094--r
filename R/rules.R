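# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.LOGICAL_RULES <- c("AND", "OR", "XOR")

# lty codes: 1 solid, 2 dashed, 3 dotted
.LTY_FORWARD <- c(2L, 3L, 1L)  # dashed, dotted, solid for n = 1..3
.LTY_REVERSE <- c(2L, 1L, 3L)  # dashed, solid, dotted

#' Look up a transformation rule by name
#'
#' Recognized names: `identity`; `lwd`, `lwd.inv`; `lty`, `lty.inv`;
#' `rotation`, `rotation.X` for X in 1..9 (step angle `pi/X`, default
#' `pi/4`) and their `.inv` forms; `size`, `size.inv`; `shape`,
#' `shape.inv`; `shade`; `multi.shade`; `AND`, `OR`, `XOR`. The shade rule
#' and the logical rules have no reverse form.
#'
#' @param name rule identifier.
#' @return a list of class `rule` with fields `name`, `base`, `category`
#'   (`"identity"`, `"incremental"`, `"permutational"`, `"logical"`),
#'   `direction` (`"forward"` or `"reverse"`), and rule constants (`theta`
#'   for rotation, `k` for size, `lty_map`/`lwd_map`/`shade_map` for the
#'   margin and shade rules).
#' @export
rule_registry_lookup <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name %in% c("shade.inv", "multi.shade.inv")) {
    stop("no reverse rule is available for '", sub("\\.inv$", "", name), "'")
  }
  if (name %in% paste0(.LOGICAL_RULES, ".inv")) {
    stop("logical rules cannot be applied in reverse: '", name, "'")
  }
  rule <- function(base, category, direction = "forward", ...) {
    structure(list(name = name, base = base, category = category,
                   direction = direction, ...), class = "rule")
  }
  if (name == "identity") return(rule("identity", "identity"))
  if (name %in% .LOGICAL_RULES) return(rule(name, "logical"))
  if (name == "size") return(rule("size", "incremental", k = 0.9))
  if (name == "size.inv") return(rule("size", "incremental", "reverse", k = 0.6))
  if (name == "lwd") return(rule("lwd", "permutational", lwd_map = 1:3))
  if (name == "lwd.inv") return(rule("lwd", "permutational", "reverse", lwd_map = 3:1))
  if (name == "lty") return(rule("lty", "permutational", lty_map = .LTY_FORWARD))
  if (name == "lty.inv") return(rule("lty", "permutational", "reverse", lty_map = .LTY_REVERSE))
  if (name == "shape") return(rule("shape", "permutational"))
  if (name == "shape.inv") return(rule("shape", "permutational", "reverse"))
  if (name == "shade") return(rule("shade", "permutational", shade_map = .SHADES))
  if (name == "multi.shade") return(rule("multi.shade", "permutational", shade_map = .SHADES))
  m <- regmatches(name, regexec("^rotation(\\.([1-9]))?(\\.inv)?$", name))[[1]]
  if (length(m)) {
    x <- if (m[3] == "") 4L else as.integer(m[3])
    dir <- if (m[4] == ".inv") "reverse" else "forward"
    return(rule("rotation", "incremental", dir, theta = pi / x))
  }
  stop("unknown rule: '", name, "'")
}

as_rule <- function(rule) {
  if (inherits(rule, "rule")) rule else rule_registry_lookup(rule)
}

require_tag <- function(fig, tag, rule_name) {
  if (!(tag %in% figure_tags(fig))) {
    stop("rule '", rule_name, "' requires the '", tag,
         "' tag, which the figure does not carry")
  }
}

#' Apply a transformation rule to a figure
#'
#' Realizes one cell of a rule's progression: `n` is the step index, linked
#' by the matrix builder to the column (horizontal logic) or row (vertical
#' logic) of the cell. The input figure is never mutated.
#'
#' Effects by rule: `identity` returns the figure unchanged; `size` divides
#' `size.x`/`size.y` by `n * k` (k = 0.9; the reverse multiplies by `n * k`
#' with k = 0.6); `rotation.X` increases the clockwise rotation by
#' `n * pi/X` (reverse decreases); `lwd` sets the line width to the n-th
#' multiple of the base width, n in 1..3 (reverse decreasing); `lty` sets
#' the line type per its n-indexed map; `shade` sets the fill to the n-th
#' entry of (white, gray, black) ignoring any previous fill; `multi.shade`
#' assigns each constituent a random fill drawn with seed `n`; `shape`
#' makes exactly one of three single constituents visible (forward order
#' A, B, C for n = 1..3; reverse C, B, A).
#'
#' @param rule a rule name or a `rule` from [rule_registry_lookup()].
#' @param fig a `figure` satisfying the rule's requirements.
#' @param n step index (>= 1).
#' @return a transformed `figure`.
#' @export
apply_rule <- function(rule, fig, n) {
  rule <- as_rule(rule)
  stopifnot(is_figure(fig))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("step index n must be an integer >= 1")

  switch(rule$base,
    identity = fig,
    logical = ,
    AND = , OR = , XOR =
      stop("logical rules operate on whole rows/columns; use make_logical_row()"),
    size = {
      f <- if (rule$direction == "forward") {
        function(s) s / (n * rule$k)
      } else {
        function(s) s * (n * rule$k)
      }
      for (i in seq_along(fig$elements)) {
        fig$elements[[i]]$size.x <- f(fig$elements[[i]]$size.x)
        fig$elements[[i]]$size.y <- f(fig$elements[[i]]$size.y)
      }
      fig
    },
    rotation = {
      require_tag(fig, "rotate", rule$name)
      delta <- n * rule$theta * (if (rule$direction == "forward") 1 else -1)
      for (i in seq_along(fig$elements)) {
        fig$elements[[i]]$rotation <- fig$elements[[i]]$rotation + delta
      }
      fig
    },
    lwd = {
      nn <- min(max(n, 1L), 3L)  # base width multiples clamp to 1..3
      for (i in seq_along(fig$elements)) {
        fig$elements[[i]]$lwd <- rule$lwd_map[nn]
      }
      fig
    },
    lty = {
      if (n > 3L) stop("rule 'lty': step index n must be in 1..3, got ", n)
      for (i in seq_along(fig$elements)) {
        fig$elements[[i]]$lty <- rule$lty_map[n]
      }
      fig
    },
    shade = {
      require_tag(fig, "fill", rule$name)
      if (n > 3L) stop("rule 'shade': step index n must be in 1..3, got ", n)
      for (i in seq_along(fig$elements)) {
        if ("fill" %in% fig$elements[[i]]$tag) {
          fig$elements[[i]]$shade <- rule$shade_map[n]
        }
      }
      fig
    },
    multi.shade = {
      require_tag(fig, "fill", rule$name)
      if (n > 3L) stop("rule 'multi.shade': step index n must be in 1..3, got ", n)
      fills <- with_seed(n, sample(rule$shade_map, count_constituents(fig),
                                   replace = TRUE))
      for (k in seq_len(count_constituents(fig))) {
        for (i in constituent_elements(fig, k)) {
          if ("fill" %in% fig$elements[[i]]$tag) {
            fig$elements[[i]]$shade <- fills[k]
          }
        }
      }
      fig
    },
    shape = {
      if (count_constituents(fig) != 3L) {
        stop("rule 'shape' requires a concatenation of exactly 3 single figures, got ",
             count_constituents(fig))
      }
      if (n > 3L) stop("rule 'shape': step index n must be in 1..3, got ", n)
      show <- if (rule$direction == "forward") n else 4L - n
      for (k in 1:3) {
        lvl <- if (k == show) 1L else 0L
        fig <- set_visibility(fig, constituent_elements(fig, k), lvl)
      }
      fig
    },
    stop("unknown rule base: ", rule$base)
  )
}

#' Realize one row (or column) of a logical rule
#'
#' Partitions the element indices of `fig` into three non-empty disjoint
#' sets A, B, C (a seeded shuffle split into contiguous blocks of sizes as
#' equal as possible, remainder to A then B; the seed is derived from
#' `seed + index` so each row/column of a matrix draws its own partition,
#' reproducibly). The three cells are then realized by visibility toggles:
#'
#' * `AND`: \{A, C\}, \{A, B\}, \{A\} — cell 3 is the intersection.
#' * `OR` : \{A, C\}, \{A, B\}, \{A, B, C\} — cell 3 is the union.
#' * `XOR`: \{A, C\}, \{A, B\}, \{B, C\} — cell 3 is the symmetric
#'   difference.
#'
#' @param rule `"AND"`, `"OR"`, or `"XOR"` (name or rule object).
#' @param fig a `figure` with at least 3 elements.
#' @param index row or column index (1-based).
#' @param seed integer seed.
#' @return list of 3 figures, with the drawn `partition` (a list with
#'   components `A`, `B`, `C` of element indices) attached as an attribute.
#' @export
make_logical_row <- function(rule, fig, index, seed = 42L) {
  rule <- as_rule(rule)
  if (!(rule$base %in% .LOGICAL_RULES)) {
    stop("make_logical_row() requires a logical rule (AND, OR, XOR)")
  }
  stopifnot(is_figure(fig))
  ne <- length(fig$elements)
  if (ne < 3L) {
    stop("logical rules require a figure with at least 3 elements, got ", ne)
  }
  perm <- with_seed(as.integer(seed) + as.integer(index), sample.int(ne))
  base <- ne %/% 3L
  rem <- ne %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
  cut2 <- sizes[1] + sizes[2]
  part <- list(A = sort(perm[seq_len(sizes[1])]),
               B = sort(perm[(sizes[1] + 1):cut2]),
               C = sort(perm[(cut2 + 1):ne]))
  sets <- switch(rule$base,
    AND = list(c("A", "C"), c("A", "B"), "A"),
    OR  = list(c("A", "C"), c("A", "B"), c("A", "B", "C")),
    XOR = list(c("A", "C"), c("A", "B"), c("B", "C"))
  )
  cells <- lapply(sets, function(s) {
    keep <- sort(unlist(part[s], use.names = FALSE))
    f <- set_visibility(fig, seq_len(ne), 0L)
    set_visibility(f, keep, 1L)
  })
  attr(cells, "partition") <- part
  cells
}
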