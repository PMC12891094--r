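# ravgen

Rule-based generation of Raven-like progressive matrices — the item format
used by most fluid-intelligence tests — together with their multiple-choice
response lists. The package is aimed at researchers in psychometrics and
cognitive psychology who need large banks of novel, reproducible matrix
reasoning items with theory-grounded distractors, without drawing each
stimulus by hand.

## What it generates

A Raven-like item is a 2×2 or 3×3 grid of abstract figure panels whose last
cell is blank; the respondent picks the option completing the pattern. Three
components produce an item:

1. **Figures.** Every drawable shape is a record of 15 features (shape name,
   ellipse semi-axes `size.x`/`size.y`, arc angles `theta.1`/`theta.2`,
   clockwise `rotation`, position, line type/width, draw mode, vertex count
   `nv` ∈ [2, 100], fill, visibility, tags). Primitives (square, circle,
   lines, composites such as a four-line square or a four-petal flower) live
   in an extensible registry; `cof()` concatenates figures into new ones.
   Tags (`fill`, `rotate`, `d.ext`, …) gate which rules and distractor
   manipulations apply.

2. **Rules.** `mat_apply(start, hrules, vrules, mat.type)` populates the grid
   by applying transformation rules along a directional logic — horizontal
   (across columns, step *n* = column index), vertical (across rows,
   *n* = row index), or diagonal when the same rule runs both ways.
   Incremental rules apply a fixed change per step (`size`: axes divided by
   *nk*, *k* = 0.9; `rotation.X`: clockwise rotation by *n*·π/X, default
   π/4). Permutational rules permute discrete features (`shape`, `shade`
   with n ↦ white/gray/black, `lty`, `lwd`, `multi.shade`). Logical rules
   (`AND`, `OR`, `XOR`) partition the start figure's elements into sets
   A, B, C per row/column and show {A,C}, {A,B}, then the intersection,
   union, or symmetric difference. `com()` layers single-rule matrices into
   multi-layer items, background to foreground.

3. **Response list.** `response_list(m)` returns the correct response plus
   ten distractors modeling the error taxonomy observed on Raven's tests:
   three Repetitions (the cells left, top, and diagonal of the blank), two
   Wrong Principle (copy of a non-adjacent cell; recombination of cells),
   one Difference (cell merge plus a figure foreign to the matrix, seeded),
   and four Incomplete Correlates (fill inversion, quarter-turn/mirror,
   half-size, element removal — each a single-feature alteration of the
   correct response). Infeasible or degenerate options are replaced by the
   correct response covered with a thick black cross, with a warning.

## Worked example

```r
library(ravgen)

sq <- make_primitive("square", size.x = 10)
figure_tags(sq)
#> [1] "d.ext"  "fill"   "rotate" "simple"

m <- mat_apply(sq, hrules = "size", vrules = "size")
names(m)
#>  [1] "Sq1"      "Sq2"      "Sq3"      "Sq4"      "Sq5"      "Sq6"
#>  [7] "Sq7"      "Sq8"      "Sq9"      "hrule"    "vrule"    "mat.type"
m$Sq5$elements[[1]]$size.x       # 10/(2*0.9)/(2*0.9): both passes accumulate
#> [1] 3.08642
classify_direction(m)            # same rule both ways = secondary diagonal
#>    size
#> "LL-TR"
```

The center cell's semi-axis is 10/(2·0.9) after the horizontal pass and
3.086 after the vertical one — half, then a quarter, of the top-left cell.

A two-layer logic item and its response list:

```r
logic <- com(mat_apply(make_primitive("square4"), hrules = "AND"),
             mat_apply(make_primitive("miley"),  vrules = "OR"))
logic
#> <matriks> 3x3, 2 layers
#> hrule: AND, identity
#> vrule: identity, OR

rl <- response_list(logic, seed = 12)
#> Warning: IC-Neg cannot be obtained: the figure cannot change its filling color
names(rl)
#>  [1] "correct"    "r_diag"     "r_left"     "r_top"      "wp_copy"
#>  [6] "wp_matrix"  "difference" "ic_neg"     "ic_flip"    "ic_size"
#> [11] "ic_inc"
```

Neither layer can change its fill, so the color-inversion distractor falls
back to the crossed-out correct response (hence the warning). Draw or export
everything:

```r
draw(logic)                                  # 3x3 grid, blank last cell
draw(rl, main = TRUE)                        # 11 labeled option panels
export(logic, "item.svg")                    # deterministic SVG
export(rl, "item.svg", split = TRUE)         # item_correct.svg, item_r_diag.svg, ...
```

## Batch generation and CLI

`generate_bank(config, out_dir)` reads a JSON config (explicit item specs
and/or a `fixture` block sampling randomized-but-valid items), renders every
item and its 11 options, and writes `manifest.json` plus a Markdown contact
sheet. A script front-end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ravgen.R", package="ravgen"))')" \
    generate --config config.json --out bank/
```

`validate --spec config.json` dry-runs the precondition checks (rule/figure
arity, logical-rule constraints) without rendering.

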