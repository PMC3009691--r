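---
title: "Deriving enzyme-specific sequence patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving enzyme-specific sequence patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzpat)
```

This vignette documents the model behind `enzpat`, the parameters that
matter, the numerical choices made where the design was genuinely open, and
what the synthetic test bed does and does not demonstrate about real data.

## The problem and the model

Enzyme function is encoded by EC numbers, a four-level hierarchy in which
trailing levels may be unspecified (`1.1.2.-` means "an oxidoreductase
acting on CH-OH groups with a cytochrome acceptor, serial unknown"). The
protocol converts a trusted, EC-annotated protein database into a library
of deterministic PROSITE-syntax patterns, each tied to a set of EC numbers,
that can later be matched against query proteomes with a clear yes/no
outcome. Determinism is a feature: a pattern match is an auditable claim,
at the cost of sensitivity compared with probabilistic profiles — a single
substitution at a conserved position suffices to lose a match.

The pipeline is: classify and deduplicate the database; compute pairwise
local-alignment E-values between enzymes; cluster by complete linkage cut
at E = 10⁻³; extract conserved alignment columns per cluster node into
patterns; verify every pattern against the whole database with an
EC-relationship calculus; select a strict (specificity 1.0) and a loose
(specificity ≥ 0.75) pattern set.

### Why complete linkage

Complete linkage defines the distance between clusters as the *maximum*
over all cross-pair distances, with an absent pair counting as infinite.
Together with the symmetrification rule — when the two alignment directions
disagree, keep the *higher* E-value — this is what keeps clusters clean
with respect to domain composition: a two-domain protein A–B is similar to
both the A family and the B family, but since no member of A is similar to
any member of B, the two families can never be pulled into one cluster
through the multidomain intermediary. Single linkage (or, less severely,
average linkage) would chain them. The price is over-fragmentation: some
enzymes remain unclustered. These are retained as one-node trees whose
"pattern" is their exact sequence, so resubmitting a known enzyme still
yields its annotation.

### The EC-relationship calculus

A pattern EC claims function only down to its own resolution. Scoring a
match between a pattern EC `p` and a target EC `t` is therefore
asymmetric:

* **TP** — `t` agrees with `p` at every level `p` specifies and is itself
  specified there (`p = 1.2.3.-`, `t = 1.2.3.4` is TP: the claim is only
  sub-subclass-deep).
* **FP** — a level specified in both differs.
* **NA** — `t` is less resolved than the claim, with no conflict
  (`p = 1.2.3.4`, `t = 1.2.3.-`: the target might or might not have the
  claimed serial).

Across EC *sets*, TP takes precedence over FP, and FP over NA: evaluation
may stop at the first TP, and NA requires that no TP or FP pair exists.
Matches on putative entries are always NA (their function is not trusted
either way), and matches on non-enzymes are always FP.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| enzyme length window | 100–7000 aa | EC-annotated entries outside it are not used for pattern building |
| putative keywords | putative, hypothetical, fragment, probable, by similarity | case-insensitive description markers |
| min alignment columns | 50 | hits covering fewer columns are discarded |
| E-value cutoff | 10⁻³ | hit filter and clustering cut (boundary values retained/merged) |
| masking window / entropy | 12 aa / 2.2 bits | low-complexity masking before the similarity search |
| node-size cap | 1000 sequences | nodes at or above it are never aligned (they produce short, unspecific patterns anyway) |
| min conserved positions | 8 | patterns conserving fewer positions are rejected |
| %pce threshold | 0.9 | per-tree coverage target of the iterative pattern loop |
| loose-set specificity floor | 0.75 | strict set additionally requires specificity 1.0 |

All of these are arguments of the corresponding functions (and of
`run_pipeline()`); the defaults above are the protocol's operating point.

## Numerical and design choices

**Pairwise alignment and E-values.** The built-in aligner delegates
Smith–Waterman local alignment (BLOSUM62, gap open 11 / extend 1) to
`Biostrings::pairwiseAlignment()` and converts scores to E-values with the
Karlin–Altschul form `E = K·m·n·exp(−λS)`. The default constants are the
published gapped BLOSUM62(11,1) values λ = 0.267, K = 0.041;
`calibrate_evalue_params()` refits both from the empirical score tail of
random sequence pairs should the scoring scheme change. The scorer is
symmetric, so the built-in route emits both hit directions with one
E-value; the "keep the higher E-value" symmetrification still matters for
imported BLAST tables, where the two directions genuinely differ. E-values
are clamped below at 10⁻¹⁸⁰ (imported E-values of 0 included) so ordering
and `max()` stay well-defined.

**One-directional hits.** A pair reported in only one direction yields no
distance: the missing direction's E-value exceeded the reporting threshold,
and the symmetrified maximum would exceed the clustering cutoff anyway.

**Multiple HSPs.** Several hits in one direction are collapsed to that
direction's best (minimum) E-value before symmetrification.

**Tie-breaking.** Equal inter-cluster distances are resolved toward the
lexicographically smallest sorted pair of the clusters' smallest member
ids. Any fixed rule would do; this one makes forests reproducible across
platforms and input orderings, which the test suite relies on.

**Low-complexity masking.** A windowed Shannon-entropy masker (windows of
12 residues under 2.2 bits are replaced by `X`) stands in for SEG-style
filtering; it is a documented masker in its own right, applied to the
similarity search only, and externally pre-masked sequences can be supplied
instead. Stored sequences, alignments and patterns always use the unmasked
residues.

**Multiple alignment.** The built-in provider is a center-star progressive
alignment: the sequence with the best summed global-alignment score is the
center, every other sequence is aligned to it, and the pairwise alignments
are merged under "once a gap, always a gap". For the tightly clustered,
high-identity nodes this protocol produces, center-star is adequate and
fast; ClustalW ALN files can be imported for externally computed
alignments. Conservation is always *recomputed* from the rows rather than
trusting a printed markup line: a fully conserved, gap-free column is a
"star", a gap-free column whose residues fall inside one ClustalW strong
group (STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW) is a "colon".
Weak ("period") groups are not used. Class elements emit the *observed*
residue set, not the whole strong group — tighter patterns, in keeping
with the protocol's specificity-first design.

**Qualified nodes and leaves.** Patterns are attempted at the root and at
nodes whose EC set is strictly smaller than their parent's (under the
union semantics used here a child's set is always a subset, so "fewer"
means strictly smaller cardinality). Single-sequence leaves inside
multi-leaf trees are never attempted — a one-sequence "alignment" has no
conservation structure; exact-sequence patterns are reserved for genuinely
unclustered records. The iterative coverage loop attempts all untried,
pattern-less internal nodes sharing the current worst (highest) merge
E-value in one batch, never revisits a node, and stops at %pce ≥ 0.9 or
when candidates run out. A tree can legitimately end with no pattern; the
failure reasons are recorded per node.

**Degenerate inputs.** Gap elements spanning runs where some row has no
residue get `min = 0`; all-gap runs are dropped. Patterns are trimmed to
their first/last conserved column, so they never begin or end with a
wildcard. A pattern whose verification produced neither TP nor FP evidence
(only NA) has specificity defined as 1.0 — there is no counterevidence —
and the strict set additionally excludes patterns whose EC set is exactly
one unresolved EC, while tolerating unresolved ECs alongside resolved ones
of the same sub-subclass. False negatives are deliberately not computed:
with several patterns per function spread over unrelated families, a
per-pattern FN count is not meaningful.

**Annotation metrics.** Against a standard of truth (SOT), each SOT EC is
creditable once; a predicted EC with no TP relation that agrees with a SOT
EC on the first three levels scores a once-only *sub-subclass hit*, which
is also how unresolved predictions (`1.1.1.-`) contribute. The
contribution split reports the percentages of the union of identified SOT
ECs found only by method 1, only by method 2, or by both.

## The synthetic test bed

`generate_family()` draws a uniform-random ancestor and i.i.d. mutated
descendants: substitutions are uniform over the 19 alternative residues (so
pairwise identity has the closed form `(1−r)² + r²/19` per site, which the
tests check), and indels delete or insert geometric-length runs (mean 2)
at a per-site rate. `generate_database()` wraps families into a
Swiss-Prot-dialect flat file together with keyworded putative decoys
(exact member copies by default, so the neutral verification channel is
demonstrably exercised), uniform-random non-enzymes, and optional
two-domain concatenations carrying the union of two families' ECs. All
randomness flows through R's default Mersenne–Twister generator seeded per
spec, making output byte-identical across platforms.

The reference study used by the acceptance script and the end-to-end tests
is five families of eight members at 8% per-site substitution with
distinct fully resolved ECs, plus 20 decoys, 50 non-enzymes and two
multidomain entries — sized so the complete pipeline (≈ 900 pairwise
alignments) runs in well under a minute on one CPU while still exercising
family recovery, the multidomain non-bridging property, decoy neutrality
and both pattern sets.

What passing these tests shows: the clustering equals a brute-force
complete-linkage oracle; the matcher equals an enumeration oracle; the
protocol's thresholds act as closed boundaries; families separated by
design are recovered as separate trees with perfectly specific patterns.
What they do *not* show: performance on real databases, where families
share ancient homology rather than being independent random draws, where
compositional bias makes masking consequential, and where annotation
errors and fragments blur the three groups. Uniform substitution without a
substitution-matrix bias also makes conserved columns easier to find than
in real alignments of equally diverged sequences; results on real data
depend on alignment quality in ways the synthetic bed cannot probe.

## Known limitations

* Deterministic patterns trade sensitivity for specificity by design;
  there is no score, only match/no-match.
* The center-star aligner is adequate for high-identity clusters but
  inferior to progressive/iterative MSA tools on diverged nodes; the ALN
  importer exists for exactly that case.
* The built-in E-value surrogate is calibrated, not NCBI-BLAST-compatible;
  imported BLAST tables are the fidelity route for large runs.
* Tree statistics (`tree_variability()`) describe clustering granularity
  per EC group; they are descriptive, not inferential.
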