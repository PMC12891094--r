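---
title: "Generating Raven-like matrices: model, rules, and distractors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating Raven-like matrices: model, rules, and distractors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ravgen)
```

This vignette is the package's own account of how its items are built: the
figure model, the transformation-rule engine, the distractor taxonomy, and —
where the design was genuinely open — which choice was made and why.

## The figure model

Every drawable element is a 15-field feature record. The cell canvas is an
abstract square **[-20, 20] × [-20, 20]** with center (0, 0); full-size
primitives default to `size.x = size.y = 15`. The canvas is dimensionless
and resolution-independent: geometry lives in canvas units and only the
renderer maps it to pixels.

An element is either a regular `nv`-gon inscribed in the
(`size.x`, `size.y`) ellipse (`num = 1`), or a circular arc from `theta.1`
to `theta.2` (`num = 2`). Lines are the degenerate polygon `nv = 2`;
circles and ellipses use `nv = 100`. `rotation` is clockwise-positive,
matching the rotation rule's "clockwise by n·θ" semantics; the renderer
translates this to the mathematical convention by negating the angle. The
`theta.1`/`theta.2` fields are treated as arc start and end angles — the
most natural reading for the "circle section" primitives — which is a
modeling decision of this package, not an assertion about any upstream
drawing library.

Fill names `white`, `gray`, `black` map to `#FFFFFF`, `#808080`, `#000000`
at render time; `NA` means unfilled. `visible` is an integer: 0 hides an
element (it stays in the structure so logical rules can toggle it back),
and levels above 1 are reserved as foreground hints but render identically.

Composite primitives (the four-line `square4`, the four-petal `miley`
flower, the `malta` cross) are registered as *single* figures: one name,
several elements. This matters for two counters:

* `count_constituents()` counts **names** — the shape permutation rule
  demands exactly 3 constituents;
* logical rules partition **elements** — `square4` and `miley` qualify with
  their 4 elements even though they count as one figure.

Tags gate feasibility: `fill` permits shading operations, `rotate` permits
rotations, `d.ext`/`d.int` mark figures usable as the foreign figure of the
Difference distractor. A circle carries no `rotate` tag (rotating it is a
no-op); `miley` and `square4` carry no `fill` tag, which is what makes the
tutorial item's color-inversion distractor infeasible (see below).

## Rules and the step index

Each rule realizes one cell of a progression through a step index *n*,
which the matrix builder links to the **column** index for horizontal rules
and the **row** index for vertical rules. The Table-of-rules constants are:

| rule | kind | effect at step n | default |
|---|---|---|---|
| `size` | incremental | axes divided by *n·k* | *k* = 0.9 (`size.inv` multiplies, *k* = 0.6) |
| `rotation.X` | incremental | clockwise by *n*·π/X | X = 4 (θ = π/4); `.inv` anticlockwise |
| `lwd` | permutational | width multiple *n* ∈ {1,2,3} | reverse decreasing |
| `lty` | permutational | dashed, dotted, solid | reverse: dashed, solid, dotted |
| `shade` | permutational | white, gray, black (ignores prior fill) | no reverse form |
| `shape` | permutational | constituent *n* of 3 visible | reverse order C, B, A |
| `AND`/`OR`/`XOR` | logical | whole row/column at once | no reverse form |

Two readings deserve a note:

* **The formula applies to every cell, including n = 1.** Under `size`,
  cell (1,1) is divided by 1·0.9 like any other. This keeps the rule a pure
  function of (figure, n) — so horizontal then vertical application simply
  accumulates — and yields the clean ratios one expects from the rule: with
  a single horizontal `size`, the center cell is exactly **half** the
  top-left cell (10/1.8 over 10/0.9), and exactly a **quarter** of it after
  adding the vertical pass. The alternative (exempting n = 1) breaks those
  ratios.
* **`multi.shade`** is specified elsewhere as "normal shade after a seeded
  per-figure randomization", but applying the deterministic shade last
  would erase the randomization. It is implemented as the seeded
  per-constituent random fill itself (`sample` over white/gray/black with
  seed *n*), so each cell of the progression draws its own assignment.

Applying a rule never mutates its input; all operations return fresh
values.

### Logical rules

`make_logical_row()` partitions the element indices into three non-empty
sets A, B, C: a seeded shuffle split into contiguous blocks with sizes as
equal as possible (remainder to A, then B). The partition algorithm is a
package choice — only the set semantics are contractual, and they are
property-tested against a brute-force oracle: the third cell's visible set
equals the intersection (`AND`), union (`OR`), or symmetric difference
(`XOR`) of the first two.

The per-row seed is `seed + row index` (columns analogously), so rows draw
distinct partitions but the whole matrix is reproducible from one seed.
Logical rules refuse: combination with any visuospatial rule, four-cell
matrices, two different logical rules with differing directional logic —
and, as a conservative extension, the *same* logical rule in both
directions, a case the upstream error taxonomy leaves unstated.

### Directional logic

A rule only in `hrules` varies across columns (H); only in `vrules`,
across rows (V). The same rule in both directions defines a diagonal:
forward + reverse gives the main diagonal (TL-LR), twice forward or twice
reverse gives the secondary diagonal (LL-TR). Horizontal rules are applied
first (columns left to right within each row), then vertical ones; since
incremental rules are commutative in their step, the internal order is
unobservable in the output, but it is documented here as the contract.

One known limitation: permutational rules (`shape`, `shade`) *overwrite*
rather than compose, so naming one in both directions yields the vertical
assignment, not a diagonal permutation. Diagonal logic is meaningful for
the incremental rules.

## Layers

`com()` stacks matrices cell-wise, background first; the foreground layer
is drawn on top (painter's algorithm — the SVG stream emits foreground
elements last). The resulting object keeps per-layer provenance, which the
distractor generator needs.

## The response list

`response_list()` always returns 11 named options in a fixed order:
`correct`, 3 repetitions, 2 wrong-principle, 1 difference, 4 incomplete
correlates.

* **Repetitions** copy the cells adjacent to the blank: left `Sq8`, top
  `Sq6`, diagonal `Sq5` on 3×3 (on 2×2: `Sq3`, `Sq2`, `Sq1`).
* **Source cell** for wrong-principle and difference: `Sq1` when a single
  rule runs H, V, or TL-LR; `Sq3` under LL-TR or when two or more rules are
  manipulated — so a wrong-principle copy cannot pass as an incomplete
  correlate. On 2×2, `Sq3` when a rule runs both ways, else `Sq2`
  (wrong-principle) / `Sq1` (difference).
* **Wrong principle**: `wp_copy` is the source cell verbatim; `wp_matrix`
  superimposes another cell — deterministically the horizontally adjacent
  `Sq2`, a package choice where the definition says only "another cell".
  On 2×2 the superimposed figure is `wp_copy` rotated a quarter turn.
* **Difference** merges the source cell with `Sq4` and `Sq7` (all the
  cells its definition lists) and superimposes a registry figure tagged
  `d.ext`/`d.int` whose name occurs nowhere in the matrix, drawn with the
  list's seed. Changing the seed changes only seed-dependent options. If
  the registry is exhausted the option falls back to the crossed-out
  correct response.
* **Incomplete correlates** alter the correct response in one feature,
  targeting the foreground-most layer whose tags support all four
  manipulations (`fill` and `rotate`); failing that, the foreground layer
  is used and the individually infeasible options are crossed out.
  Numerical choices, where the taxonomy names no magnitude: fill inversion
  swaps white and black and sends gray/unfilled to black; the flip is a
  quarter turn clockwise (mirror across the vertical axis for
  non-rotatable figures); the resize factor is 0.5. `ic_inc` removes the
  foreground figure — impossible on single-layer matrices (warning
  verbatim: *"IC-Inc cannot be obtained with a single figure"*); on logic
  matrices one visible element is removed at random (seeded).

**Degeneracy.** Any option equal to the correct response is replaced by the
crossed-out correct response (two full-panel diagonal strokes, `lwd = 3`)
with a warning; the fallback is applied uniformly to every option family.
Equality is field-wise over visible elements: exact on discrete fields,
tolerance 1e-9 on numeric fields. A purely vertical rule degenerates
`r_left`; a purely horizontal rule symmetrically degenerates `r_top`.

## What the fixture generator emulates — and what it does not

`sample_item_spec()` produces randomized item specs that are valid by
construction: logical rules only on nine-cell matrices with ≥3-element
starts and alone in their layer; the shape rule only with three-figure
concatenations; rotation/shade only with suitably tagged starts; one rule
per layer; incremental rules occasionally doubled into a diagonal. With
`include_degenerate = TRUE` it adds the known warning paths (single layer,
vertical-only rule, unfillable layers).

This emulates the *structural* variety of rule-based item banks, not their
psychometric properties: sampled items carry no difficulty model, no
empirical distractor attractiveness, and the one-rule-per-layer policy
under-represents single-layer multi-rule items (which `mat_apply` itself
supports). A green property suite therefore establishes contract
correctness — set semantics, rule algebra, list composition — not that the
items measure anything.

## Determinism and seeds

Every random draw (logical partitions, difference figure, random removal,
fixture stream) flows through a seed argument and restores the caller's
RNG state afterwards. Identical inputs give bit-identical matrices,
response lists, and SVG bytes; fixture seeds are independent of the item
seeds they emit, so test corpora and item randomness vary separately.

## Rendering

SVG is the source of truth: panels are 100 px squares mapping the canvas at
scale 2.25 (a 5% margin), numbers are written with three decimals, and the
output is byte-stable. PNG output draws the same geometry through R's cairo
device at the requested dpi — it is not rasterized from the SVG file, since
no rasterizer is assumed, but both paths share `element_points()` so the
geometry cannot drift. Matrix renderings always blank the last cell; the
optional question-mark glyph is off by default. Line types map to dash
patterns solid/none, dashed (6,4), dotted (1,3) in canvas units.

## Known limitations

* Only the rules listed above are implemented; quantitative progressions
  (numerosity), paired progressions, mental transformation, movement, and
  edge changes are out of scope, as are solving matrices and estimating
  difficulty.
* Distractors cannot be customized post hoc; regenerate with different
  seeds or registries instead.
* The default figure registry is a representative set, not an exhaustive
  shape library; `register_primitive()` extends it at run time.
* The CLI config is JSON only.
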