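---
title: "treekit: data model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{treekit: data model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treekit)
```

This vignette is the package's own account of what it computes and why
the design looks the way it does: the data model, the parsing and
writing algorithms, the manipulation semantics, the statistics and their
formulas, the synthetic-data generator, and the numerical choices that a
careful user should know about.

## The data model

A `phylotree` is a rooted tree stored as parallel vectors in
*pre-order*: node 1 is the root, every parent precedes its children, and
siblings appear left to right. Each node carries an optional label, an
optional branch length (the branch leading *into* the node, `NA` when
undefined), an ordered set of children (any arity — multifurcations are
first-class), an annotation map, and an optional hybrid id.

Two consequences of this layout do a lot of work:

* a node "reference" is just its 1-based pre-order index, which makes
  indexing into the node list deterministic and documentable. Ids are
  reassigned after every topology change;
* the descendants of node *v* occupy the contiguous index block
  `v .. v + size(v) - 1`, so clade extraction is a vector slice and the
  MRCA of a set is found by walking up from the smallest index until the
  block covers the largest — an O(depth) operation that is independent
  of the brute-force ancestor-set intersection the tests compare it to.

All user-facing functions are *pure*: they return a new tree and never
mutate their argument. In a language with reference semantics the
manipulation methods would mutate in place; in R, copy-on-modify of flat
vectors is cheap and functional style composes better, so that is the
API here. `prune()` accordingly returns `list(tree =, clade =)` rather
than mutating one and returning the other.

Phylogenetic networks are represented as trees-with-duplicates: two node
records sharing a hybrid id (written `#H1` in extended Newick) denote
one network node. This keeps every traversal tree-shaped at the cost of
not sharing subtree memory — a deliberate trade. Operations that would
separate the two records of one hybrid node (rerooting through it,
pruning one copy away from the other) refuse with an error rather than
silently producing a non-network.

## Parsing

The Newick parser is iterative with an explicit stack, never
call-stack recursive. A node is allocated the moment its subtree's text
begins, which makes allocation order pre-order by construction; `(`
pushes, `)` pops, `,` starts a sibling. Fully pectinate (caterpillar)
trees therefore parse at any depth — the property a recursive-descent
parser loses around a few thousand nested parentheses. The parser and
writer hot paths are compiled (Rcpp), the same choice ape makes for its
C core; everything above them is plain R.

Dialect decisions, all documented in `?read_newick`:

* unquoted labels exclude `()[]{}:;,=` and whitespace; underscores are
  kept verbatim (some traditions convert them to spaces; round-trip
  safety wins here);
* single-quoted labels use `''` to escape a quote;
* BEAST annotation blocks are accepted after the label, after the colon
  and after the branch length, and NHX blocks likewise; all blocks on
  one node merge into a single annotation map. Tools in the wild differ
  on whether node- and branch-placed annotations are distinct things;
  merging them is this package's documented choice;
* annotation values that look numeric become numbers, `{a,b}` becomes
  an ordered vector, quoted values stay text — so maps round-trip;
* bracketed comments that are not annotations (no leading `&`) are
  discarded, standard Newick semantics;
* a label suffix `#H1` marks a hybrid record (id `"H1"`); the marker is
  only recognised in unquoted labels;
* branch lengths accept decimal and scientific notation. Negative
  lengths are kept with a warning rather than rejected or clamped —
  real BEAST output contains tiny negative lengths, and silently
  altering data is worse than carrying it;
* malformed input (unbalanced parentheses, dangling comma, unterminated
  quote or comment, missing `;`) errors with a 1-based character
  offset.

Multi-tree Newick input is newline-separated: one statement per
non-blank line, errors reported with the line number. A single
statement, read with `read_newick()`, may itself contain newlines
between tokens — whitespace between tokens never changes a parse.

The Nexus reader requires the `#NEXUS` header and a TREES block, matches
keywords case-insensitively, applies an optional TRANSLATE map, and
tolerates rooting comments (`[&R]`, `[&U]`). Labels that are not
translate keys are left verbatim, since internal-node labels are
routinely untranslated in the wild. The PhyloXML and NeXML readers
handle the structural subset (clades with names and branch lengths;
node/edge lists with otu references) and warn — once, listing names —
about elements they ignore. PhyJSON has no settled specification, so the
schema supported here is the package's own minimal convention, spelled
out in `?read_phyjson`: `{"trees": [...]}` of nested
`{name, length, children, annotations, hybrid}` objects.

## Writing

The writer mirrors the parser: an explicit stack, one pass, per-node
token `label [&pre] :length [&&post]`. Three contracts matter:

* **undefined lengths are omitted** — a node with `NA` length gets no
  colon token at all, and reparsing restores the `NA`;
* **polytomies are written as-is**, never resolved;
* **branch lengths round-trip exactly**: each number is printed with the
  shortest of 15, 16 or 17 significant digits that `strtod` maps back to
  the same double (`%g` already trims, so 15 digits is the shortest
  representation whenever 15 suffice).

Labels are quoted only when they contain characters illegal in unquoted
Newick. Some tools quote every label; since any quoting policy that
round-trips is equivalent on reparse — the level at which correctness is
defined here — the as-needed policy wins on readability and size.

Annotation writing is callback-based: `write_newick(tree, annotator =)`
calls the annotator once per node with a `node_data()` view and splices
the returned fragment before the colon (BEAST convention) or after the
length (NHX, signalled by a `placement` attribute on the function). The
default is no annotations. `beast_annotation()` quotes values containing
`[ ] , = { }` or spaces; `nhx_annotation()` has no quoting mechanism in
its dialect, so such values — and vector values — are errors there.

Nexus output is a minimal TREES block without a TRANSLATE table (labels
inline); the reader accepts both forms. Multi-tree output is the
caller's concern (join Newick statements with `\n`), except in the CLI's
`convert`, which writes multi-tree Nexus blocks itself.

## Manipulation semantics

`reroot(tree, node, proportion)` splits the branch above `node` at
`proportion` (measured from the node; default 0.5) rather than
re-hanging the tree at the node itself: the branch-splitting reading
supports midpoint-style usage and gives the optional-proportion
signature a meaning. Edges between the old root and the attachment are
reversed, each keeping the length of the edge it subtends; an old root
left unary is suppressed with lengths summed; the new root gets length
0.0, so rerooted trees serialise ending `:0;`. Conserved exactly (to
1e-9 relative in the tests): the leaf set, total branch length, and
every leaf-to-leaf path length.

Unary suppression — whether from rerooting or `prune()` or the explicit
`suppress_unary()` — merges a degree-2 node into its child: lengths sum
(`NA` counts as absent; two `NA`s stay `NA`), and the *child's* label and
annotations win while the suppressed node's annotations are dropped.
Child preference is the only rule that keeps clade-level annotations
attached to the clade they describe. `remove_child()` deliberately does
*not* auto-suppress, because silent suppression breaks annotation
round-trips; suppression is always an explicit or documented step.

`ladderise()` orders children by descendant-leaf count ascending, ties
broken by the lexicographically smallest descendant leaf label so the
result is deterministic on label-distinct trees. `get_clade()` copies
deeply — no aliasing between source and extract — and *retains* the
clade root's incoming branch length, which the IE-ratio convention below
depends on.

## Statistics

**Root-to-tip distances** sum branch lengths from (but excluding) the
root to each leaf; an undefined length on a needed path is an error
naming the leaf. **Tree length** is the sum of all defined lengths.

**IE ratio**: internal branch-length sum divided by external (leaf)
branch-length sum, skipping undefined lengths in both. The clade
convention is the part worth stating twice: an extracted clade keeps its
root's incoming branch and counts it as internal. On
`((a:2,b:2):1,(c:1,d:1):4);` this yields 0.25 for the `{a,b}` clade
(1 / (2+2)), 2.00 for `{c,d}` (4 / (1+1)) and 0.83 for the whole tree
(5 / 6, the root's undefined length skipped). `annotate_ie_ratios()`
formats to two decimals, rounding half away from zero (matching
`toFixed`-style formatting), and stores the formatted string.

**Sackin** is the sum of leaf depths (any arity). **Colless** is the sum
over internal nodes of the absolute leaf-count difference between the
two children and therefore requires a strictly bifurcating tree — a
polytomy is an error naming the node, never silently resolved, because
the package never resolves polytomies anywhere.

**Gamma** (Pybus–Harvey): with `n` leaves and internode intervals
`g_2..g_n`, where `g_k` is the duration during which `k` lineages exist
and `T = Σ_{j=2}^{n} j·g_j`,

$$\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\sum_{j=2}^{i} j\,g_j - T/2}
{T\sqrt{1/(12(n-2))}}.$$

It requires an ultrametric (checked to 1e-6 relative on root-to-tip
distances), strictly bifurcating tree with at least three leaves, and is
invariant under global branch-length rescaling. Negative values mean
internal nodes concentrated near the root. On `((A:1,B:1):1,C:2);` the
formula gives −0.3464; the tests also cross-check against an independent
implementation in ape.

**Root-to-tip regression** is ordinary least squares of root-to-tip
distance on caller-supplied tip times: the slope is the clock-rate
estimate, `r2` the coefficient of determination. No dates are parsed
from labels — time parsing and local-clock model search belong to
downstream tools, not here.

## The synthetic-tree generator

The generator exists to produce controlled inputs: trees of exact size
and shape (`yule` random joins, `caterpillar` for maximum depth,
`balanced` for minimum), exponential branch lengths with a chosen mean
(default 1.0, a neutral choice of unit), optional annotations on every
node, and optional hybrid-record injection as a parser fixture. The
ultrametric variant uses a coalescent-style pure-birth construction —
with `k` lineages the next join is an Exp(rate `k`) depth increment — so
root-to-tip distances are equal by construction and the gamma statistic
has expectation ~0 over replicates, which the tests verify at `n = 50`
over 500 replicates.

Randomness comes from an explicit splitmix64 stream keyed by the seed,
not from R's session RNG: the same seed gives byte-identical Newick
output on any platform, and generating a tree never disturbs
`.Random.seed`.

What the generator emulates is the *structural* variety of real files —
sizes, shapes, annotation dialects, missing lengths, quoted labels,
polytomies, hybrid records. What it does not emulate: real substitution
processes, rate heterogeneity, sampling-through-time tip date patterns,
or the idiosyncratic formatting of specific tools. Passing tests
demonstrate structural and numerical correctness of parsing,
manipulation and statistics; they are not evidence about inference on
real data.

## Numerical choices and problem sizes

* Branch-length serialisation: shortest round-tripping decimal, no fixed
  precision.
* Ultrametricity tolerance: 1e-6 relative; rerooting conservation
  checked at 1e-9 relative; IE-ratio formatting: two decimals, half away
  from zero.
* Ladderisation ties: smallest descendant leaf label, radix (byte)
  order.
* Degenerate inputs: a bare `;` is a single unlabelled node; a
  single-node tree has root-to-tip distance 0; an all-undefined-lengths
  tree has tree length 0; an IE ratio with zero external sum is an
  error (division by zero), as is a gamma on fewer than three leaves.
* The test suite exercises: the full worked example exactly; 1000
  serialisation round-trips and 1000 parser-oracle comparisons on messy
  trees of up to 64 leaves; 1000 MRCA/imbalance oracle comparisons; 500
  seeded rerootings with all-pairs path-length checks; 500 pure-birth
  gamma replicates at 50 tips; and one full read/write cycle each of a
  10^6-tip random tree and a 10^5-tip caterpillar. These sizes keep a
  complete run comfortably fast on a single CPU while covering the
  scaling behaviour the stack-based core is designed for.

## Known limitations

* Networks are records-with-shared-ids, not a DAG; network-aware
  algorithms (e.g. reticulation-aware distances) are out of scope.
* Writers cover Newick and Nexus only; PhyloXML/NeXML/PhyJSON are
  read-only.
* Nexus support is the TREES block (plus TRANSLATE); character and data
  blocks are ignored territory.
* The recursive XML readers are not intended for million-tip documents;
  the scaling path is Newick.
* No confidence intervals on the root-to-tip regression, and no local
  clock search — the regression here is the primitive, not the analysis.
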