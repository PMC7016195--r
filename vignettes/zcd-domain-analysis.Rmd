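---
title: "Methods: detecting and comparing the P2X7 ballast Zn-coordinating cysteine domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and comparing the P2X7 ballast Zn-coordinating cysteine domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zcdtools)
```

# The domain and its grammar

The intracellular C-terminal "ballast" region of the P2X7 receptor folds
around a dinuclear zinc site held by cysteines arranged in three ordered
clusters. The conserved core — the Zn-coordinating cysteine-based domain
(ZCD) — can be written as three consensus motifs in the compact notation
used throughout the comparative literature:

```{r patterns}
zcd_patterns()[1:3, 1:2]
```

The grammar has three element kinds: an uppercase letter is an **exact**
position, `(A/B)` (or a trailing `A/B` binding to the preceding letter, as
in `ITTS/T`) is a **residue class**, and `x`/`xN` are **wildcard** runs.
`parse_pattern()` compiles a notation string into a position table;
`format()` prints the canonical form, and compiling the printed form gives
back the same pattern (a tested round-trip invariant).

Counting cysteine-capable positions over the three compiled clusters gives
the domain's defining arithmetic: seven obligate cysteines, eight when
cluster3's optional `(C/S)` slot holds a cysteine. Both numbers are
recomputed (never hard-coded) in the acceptance checks.

```{r cys}
cl <- zcd_patterns(compiled = TRUE)[c("cluster1", "cluster2", "cluster3")]
c(obligate = sum(sapply(cl, count_cysteine_positions, include_optional = FALSE)),
  total    = sum(sapply(cl, count_cysteine_positions, include_optional = TRUE)))
```

# Scanning and domain assembly

`scan_motif()` reports **every** window whose unsatisfied constrained
positions stay within the mismatch budget; overlapping matches are all
returned and resolved downstream. Wildcards never mismatch; an unknown
residue `X` satisfies wildcards but no constrained position (a deliberate,
conservative choice for low-quality translations); windows containing a
gap character are ineligible. The scanner is validated against an
independently coded brute-force per-window checker on random sequences.

`detect_zcd()` assembles cluster1 → cluster2 → cluster3 matches whose
inter-cluster spacers fall within configured ranges, scores each candidate
by its total satisfied constrained positions, and resolves overlaps to the
maximum-score, then leftmost, hit (at most one hit per non-overlapping
region).

Key defaults in `zcd_config()` and the reasoning behind them:

* **Spacer ranges `[5, 60]` residues each.** The region upstream of the
  clusters varies considerably in length across species, so rigid spacing
  would lose true hits. No sequence-derived calibration is bundled (the
  reference human sequence is not shipped), so the ranges are deliberately
  wide and config-overridable.
* **`max_mismatch = 1` per cluster, `obligate_cys = TRUE`.** The
  zinc-coordinating cysteines are the near-invariant, defining feature of
  the domain; tolerating a single mismatch per cluster at non-cysteine
  positions absorbs lineage-specific variation without inflating the false
  positive rate (measured < 1% on 1,000 length-500 uniform decoys by the
  acceptance suite — with the default configuration the measured rate is
  zero).
* **`nanor_nterm_max = 150`** separates `NANOR_LIKE` (ZCD plus a short
  N-terminal region) from `ZCD_OTHER` (a residual class for longer
  architectures without a channel domain). The boundary is an engineering
  choice — no quantitative threshold exists in the comparative literature.
* **`cterm_tail_max = 100`.** In every known architecture the ZCD sits at
  the protein's C-terminus; ZCD-only sequences violating this are
  downgraded to `UNCLASSIFIED` with a warning rather than silently
  classified.

## Companion features

The **C-cys anchor** (the palmitoylated juxtamembrane motif that prevents
receptor desensitization) is called in tiers, searched upstream of the ZCD
when one exists: the full mammalian 18-mer `SNCCRSHIYPWCKCCQPC` (two
mismatches allowed by default), else the conserved `SxxCC` core, else the
teleost single-cysteine context `LIGTGCYSK`, else absent.

The **GDP-site report** locates the guanosine-pocket residues relative to
cluster landmarks. The offsets were derived once from the printed human
residue numbering: the `F/Y–P` pair at human 581–582 and the terminal `G`
at 590 pin cluster3's start to human 569, which places R574 at cluster3
offset 6 (a wildcard slot — consistent with its loss outside mammals),
R578 on the pattern's obligate R, K583 at offset 15, I568 immediately
before the cluster, and C572 on the obligate cysteine. Likewise `I507TTS`
pins cluster2 to human 497–510 (E496 immediately upstream). The proximal
R546–H547 pair, Y550 and the WRF motif are found by scanning a composite
`R(H/Y)x2Yx8WRF` template in the cluster2–cluster3 spacer; a Y at the H547
offset is reported as `substituted`, reflecting the H→Y quasi-conservation
seen outside mammals. Residues that cannot be pinned from motif offsets
(Q460, A348, the T357YSS site except when the full anchor locates it) are
never guessed: the annotator emits them only when locatable.

The **P2X channel domain** is scored by a bundled heuristic signature set
(`inst/extdata/p2x_signatures.tsv`) — four short consensus patterns loosely
modelled on conserved P2X elements, scored as the fraction matched with a
0.5 threshold. This is explicitly a synthetic stand-in for a real
domain-database lookup; users with InterPro-style calls should supply them
via the sidecar TSV, which overrides the heuristic per sequence.

# Phylogenetics

**Alignment.** ZCD regions are aligned by their motif anchors: cluster
pattern columns are pinned exactly and the two spacers are left-justified
and gap-padded to the longest spacer. This replaces a general-purpose
aligner for the domain's well-anchored geometry; externally computed
alignments can be imported as aligned FASTA instead.

**Distances.** Pairwise distances are maximum-likelihood estimates under
the JTT empirical substitution model: with $Q$ the JTT rate matrix
(published exchangeabilities and equilibrium frequencies, normalized to
one expected substitution per site per unit time; constants parsed from a
bundled PAML-format file, `inst/extdata/jtt.dat`, Jones–Taylor–Thornton
1992), the estimate is
$\hat t = \arg\max_{t \ge 0} \sum_{(a,b)} N_{ab} \log\left(\pi_a P_{ab}(t)\right)$,
with $P(t) = e^{Qt}$ computed from a one-time eigendecomposition of the
reversible $Q$ and the maximization done by bracketed scalar search to
tolerance $10^{-6}$. Gap handling is pairwise deletion by default
(matching the common default in desktop phylogenetics software; complete
deletion is available), `X` is treated as missing, and distances are
capped at 10 substitutions/site with a saturation flag — bounded
optimization with an explicit signal rather than unbounded estimates. The
estimator is checked against an exhaustive grid search (agreement within
$10^{-3}$) and against an independent ML implementation.

**Trees.** `nj_tree()` is a from-scratch Saitou–Nei neighbor-joining
implementation: Q-criterion agglomeration, ties broken deterministically
by the lexicographically smallest label-sorted pair, negative branch
estimates clamped to zero with the total deficit recorded on the tree.
Correctness is established two ways: exact inversion (topology and branch
lengths) of additive matrices from every unrooted topology of 4–6 taxa,
and topological agreement with an independent NJ implementation on random
non-additive matrices.

**Support.** `bootstrap_support()` resamples alignment columns with
replacement (default 100 replicates), rebuilds the distance matrix and NJ
tree per replicate, and labels each internal edge with the percentage of
replicates containing the same bipartition. Fixed seeds give byte-identical
Newick output. Degenerate (all-constant) alignments still produce supports
but carry a flag.

# Synteny

Following the five-marker convention, `synteny_window()` takes up to five
markers on each side of a focal gene (fewer at scaffold ends);
`shared_markers()` intersects two windows' ortholog-group labels, always
excluding the focal genes' own group. Ortholog groups are *inputs* — the
orthology inference that produces them is out of scope. Distance along a
scaffold is ordinal, not base pairs; an optional `gap_bound` flags markers
separated by large ordinal jumps. The default edge threshold is one shared
marker (single conserved markers are biologically reportable); the
stricter ancestral-synteny reading requires two, exposed as
`threshold = 2` rather than fixed, because no numeric criterion for a
"conserved synteny block" is established.

# What the generators emulate — and what they do not

`simulate_zcd_proteins()` builds sequences with the layout *N-terminal
background (optionally with planted P2X signatures and a C-cys anchor) —
cluster1 — spacer — cluster2 — spacer (optionally with the planted GDP
block) — cluster3 — tail*, realizing each consensus position and then
substituting constrained positions with probability `mu_c` and all
unconstrained positions with probability `mu_u`. Default geometry: spacers
of 10–40 and 30–58 residues (the second matching the ~58-residue human
cluster2–cluster3 spacer), N-termini of 30–120 residues, uniform
amino-acid background (conservative for false-positive estimation; JTT
equilibrium frequencies available as an alternative). Every generator
returns a truth record, and closed-loop tests compare detection output
against it, never against hand-entered coordinates.

`evolve_along_tree()` performs site-independent JTT substitution along a
guide tree with no indels, so leaves return pre-aligned.

Limitations to keep in mind when interpreting green tests: no indels are
simulated (the anchored alignment and the evolver both assume ungapped
geometry); backgrounds are i.i.d., without the compositional biases,
repeats or low-complexity regions of real proteomes; the planted P2X
signatures are the same set the detector scores, so the P2X-domain call is
validated as plumbing, not as a discriminator of real channel domains; and
spacer lengths are drawn inside the detection window, so the recall
experiments measure the motif engine, not the spacer-range calibration.
Passing tests therefore demonstrate the pipeline's internal correctness
and its behavior under the modelled noise, not performance on real
proteome mining.

# Problem sizes and numerical choices

The validation experiments use: 200 planted proteins at `mu_c = 0,
mu_u = 0.3` and 1,000 length-500 decoys for recall/false-positive
measurement; all 123 unrooted topologies of 4–6 taxa with uniform branch
lengths in [0.1, 1.5] for the NJ inversion check; five 2-taxon runs
(root length 400, branch 0.3) against a grid of step $10^{-4}$ for the
distance oracle; twenty 6-taxon runs (balanced tree, branch length 0.2,
root length 500) for topology recovery; and 4 species × 2 planted markers
for the synteny loop. Tolerances: $10^{-3}$ for the grid-vs-ML agreement
(the grid's own resolution dominates), $10^{-8}$ for additive-matrix
inversion, exact equality for topology comparisons (Robinson–Foulds
distance zero).

Other numerical decisions: likelihoods are floored at $10^{-300}$ before
logging; transition probabilities are clipped at zero after the
eigendecomposition round-trip; NJ tie-breaks and the bootstrap seed policy
make every tree output deterministic; and `write_newick()` prints branch
lengths with 12 significant digits so that reruns are byte-identical.
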