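---
title: "Classifying regulatory-element constraint from alignment chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying regulatory-element constraint from alignment chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement and its model

`relic` operationalises "how conserved is this regulatory element?" as a
purely coordinate-level quantity. For a reference element $e$ of length
$L_e$ and a target genome $g$ whose pairwise alignment to the reference is
given as UCSC chains, the aligned-base fraction is

$$ f_{e,g} \;=\; \frac{\#\{\,b \in e : b \text{ lies in an ungapped block of some chain for } g\,\}}{L_e}. $$

Two thresholds turn fractions into the per-element statistics
$N_1 = \#\{g : f_{e,g} \ge 0.9\}$ and $N_2 = \#\{g : f_{e,g} \le 0.1\}$
(both boundaries inclusive), and into the four-tier classification
described in `?classify_matrix`. The tiers are deliberately strict
set-logic rules on the fraction matrix, not a probabilistic model: they are
reproducible, auditable, and their sensitivity to the two thresholds can be
explored directly (`hi`, `lo` are arguments everywhere).

Assumptions worth stating. (1) Chains are taken at face value; a base
covered by *any* chain counts as aligned (`mode = "any"`). Alignment
pipelines can emit overlapping chains, and restricting to the single
best-scoring chain is available as `mode = "best"` for sensitivity
analysis; shared bases always count once, so $f \le 1$ by construction.
(2) The measurement is directional — reference elements projected outward.
The reverse direction (target REs onto the reference) is out of scope.
(3) Fractions of the form $k/L$ compare exactly against decimal thresholds
in double precision because IEEE division is correctly rounded (e.g.
$27/30$ equals the literal `0.9` bit-for-bit), and the package keeps the
integer aligned-base counts as matrix attributes so any boundary case can
be re-checked in integer arithmetic.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hi` | 0.9 | high-alignment threshold (fraction, inclusive) |
| `lo` | 0.1 | low-alignment threshold (fraction, inclusive) |
| `window` | 2000 bp | TSS half-window for proximal/promoter labels |
| `max_qtl_len` | 1e6 bp | QTLs strictly longer are excluded |
| `k` | panel-dependent | "mapped in at least k genomes" count |
| `mode` | `"any"` | chain coverage rule (`any` / `best`) |
| `outgroup_rule` | `"strict"` | clade-specific outgroup test (`<= lo` vs `< hi`) |

Defaults mirror the quantitative definitions in the source analyses: the
0.9/0.1 pair is the only quantitative reading of "successfully mapped" /
"unmappable" given anywhere, so the classifier reuses it; the 2 kb window
is the TSS-proximal definition and doubles as the promoter definition
(introducing a second constant would be arbitrary); the QTL filter reads
"larger than 1 Mb" literally, so exactly 1 Mb is kept.

Decisions that were genuinely open, and the choices made:

- **Window semantics.** "Within ≤ 2 kb of the TSS" does not say whether a
  partially overlapping element qualifies, nor whether the window is
  symmetric. We use symmetric TSS ± 2 kb and ≥ 1 bp overlap (the inclusive
  reading); precedence is TSS-window > gene body > intergenic, and
  promoter > exon > intron > intergenic in the four-way scheme, so the
  three-way `tss_proximal` set equals the four-way `promoter` set under an
  equal window.
- **Nearest gene.** Interval-to-interval gap (0 when overlapping), ties to
  the lexicographically smaller gene id; distance-to-TSS would be a
  different, also defensible metric, but interval gap is the least
  assumptive reading of "genomic proximity".
- **Outgroup rule.** "Not mapped in non-clade species" could mean
  $f \le 0.1$ or merely $f < 0.9$. The strict reading is the default;
  `outgroup_rule = "lenient"` implements the other without asserting which
  the source used.
- **Percent truncation.** Category percentages are floor-truncated (2 d.p.
  interspecific, 1 d.p. intraspecific), computed in integer arithmetic
  (`truncated_percent`). This is the only convention under which the
  published counts reproduce their printed percentages (22,123/135,254
  prints 16.35; rounding would give 16.36).
- **TE class attribution.** Overlapping TE calls of different classes are
  resolved disjointly — longer element wins shared bases, ties by
  lexicographic class order — so per-class covered bases sum exactly to
  the merged union coverage. TE coverage itself is always a union measure
  (merge first), never a sum over calls.
- **Unclassified is explicit.** The three named tiers cover a minority of
  real elements; everything else is labelled, counted, and never dropped.

## The synthetic world

`simulate_dataset()` emits coordinates and chains, never nucleotides:
every downstream statistic consumes coordinates, and a sequence-level
simulator would add minutes of runtime without adding coverage of any code
path.

For each taxon at divergence $t$ (MYA), each neutral base survives with
probability $p = e^{-\lambda t}$, realised *segmentally*: retained runs
and gaps alternate with geometric lengths whose means are $p\,m$ and
$(1-p)\,m$ for mean cycle length $m$. Defaults are $\lambda = 0.01$/MYA —
chosen so that retention at the far end of the panel (96 MYA) is
$e^{-0.96} \approx 0.38$, matching the roughly 40% of a pig-sized genome
alignable to human — and $m = 5$ kb, because chain gaps in real mammalian
pairwise alignments are dominated by kilobase-scale indels and TE
insertions. The segment scale matters: elements (0.2–1 kb) shorter than a
typical segment are retained or lost nearly whole, giving the bimodal
fraction distribution that the 0.9/0.1 thresholds presuppose. An early
draft used 500 bp segments; elements then straddled boundaries and
fractions piled up mid-range, which both contradicts the block structure
of real chains and defeats the ≤ 0.1 branch of the classifier. With these
defaults the per-genome high-alignment counts decline near-linearly with
divergence time (linear fit of $e^{-x}$ over $x \in [0, 1]$; observed
R² ≈ 0.95 across seeds), reproducing the direction and quality of the
published count-versus-time regressions.

Truth tiers override the neutral process inside element boundaries:
constrained elements are forced retained everywhere, species-specific ones
forced deleted in every non-conspecific taxon, clade-specific ones split
by clade membership, and unclassified ones retained over exactly half
their length (fraction ≈ 0.5 fails every strict rule). `noise` flips each
forced base independently — modelling alignment imperfection, not
biological ambiguity — so at `noise = 0.02` a 200 bp constrained element
still aligns at ≈ 0.98 and classification accuracy stays near 1. TEs are
placed at genome density 0.30 with a 1.55× multiplier inside
species-specific elements, mirroring the observed contrast between overall
(~30%) and lineage-specific (~46%) TE coverage. One global seed plus fixed
per-taxon offsets drive all randomness; re-running a config is
byte-identical and the caller's RNG state is restored.

What the simulator does **not** emulate — and therefore what a green test
does not establish: nucleotide-level substitution (no phyloP scores are
computed, only aggregated; the bundled score track is a caricature with
tier-dependent means), chain inversions and translocations (simulated
chains are collinear and plus-strand; minus-strand handling is covered by
hand-built fixtures instead), duplications mapping one source base to many
targets, and any phylogenetic correlation between taxa (each taxon's loss
process is independent given its branch length).

## Numerical and degenerate-input choices

- Projection results carry integer `aligned_bases`; fractions are derived,
  never accumulated in floating point.
- An interval on a sequence no chain covers projects to fraction 0 — a
  legitimate measurement, not an error. Malformed chains, by contrast,
  abort the load (silently skipping them would bias fractions downward).
- Regression on a constant response returns slope 0, R² 0, p 1 (the
  0/0 convention made explicit); constant predictors and n < 3 are errors.
- PCA centres but does not scale columns (all entries share the [0, 1]
  scale; scaling would amplify near-constant genomes' noise), uses SVD,
  and fixes signs by making each loading column's largest-magnitude entry
  positive, so outputs are platform-reproducible. A zero-variance matrix
  reports explained-variance ratios of 0 rather than NaN.
- Elements with no scored bases get `NA` means and are excluded from
  category aggregates; category SD is the population formula (n
  denominator) because the summaries describe the full element set.

## Known limitations

Two-way lifting, net/axt formats and BigWig tracks are unsupported;
multi-clade (≥ 3-level) hierarchies reduce to one clade/outgroup split;
the intraspecific summary assumes the reference itself is excluded from
the panel; and the simulator's independence across taxa means it cannot
generate hemiplasy-like patterns where clade structure and alignment
pattern disagree.
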