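# Shared test helpers and independent oracles.

# Indices of elements currently drawn (independent re-derivation, not the
# package-internal helper).
visible_set <- function(fig) {
  which(vapply(fig$elements, function(e) e$visible >= 1L, logical(1)))
}

# Brute-force set oracle for a logical row: what cell 3's visible set must
# be, given cells 1 and 2.
logical_oracle <- function(rule, v1, v2) {
  switch(rule,
    AND = intersect(v1, v2),
    OR = union(v1, v2),
    XOR = union(setdiff(v1, v2), setdiff(v2, v1))
  )
}

# Field values across all elements of a figure.
field_values <- function(fig, fld) {
  vapply(fig$elements, function(e) e[[fld]], numeric(1))
}

# A three-constituent start for shape-rule tests.
shape_start <- function() {
  cof(make_primitive("hexagon"), make_primitive("pentagon"),
      make_primitive("square"))
}

count_panels <- function(svg) {
  length(gregexpr('<g class="panel"', svg, fixed = TRUE)[[1]])
}

tutorial_responses <- function(seed = 1L) {
  suppressWarnings(response_list(build_item(tutorial_item()), seed = seed))
}
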