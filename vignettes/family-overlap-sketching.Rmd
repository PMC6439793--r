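---
title: "Sketch-based overlap detection between protein families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sketch-based overlap detection between protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sketchoverlap)
```

## The problem and the model

A protein family database assigns regions of protein sequences to named
families, under the quality-control rule that no residue should belong to
more than one family. When a candidate family arrives — typically the
result set of a similarity search, i.e. a collection of matched regions —
the curation question is which of three situations holds: the candidate
covers entirely new residue space; it overlaps exactly one existing
family (and may be a *superior model*, covering that family plus
additional true members); or it overlaps several families, which is
benign when they all belong to one clan of related families and suspect
otherwise.

`sketchoverlap` treats a family as a finite set. Each covered residue at
1-based coordinate $i$ of protein $p$ contributes the element
$(p, \lfloor i/w \rfloor)$, where $w$ is the chunking window. Overlap
questions then become set-similarity questions:

$$\mathrm{JI}(A,B) = \frac{|A \cap B|}{|A \cup B|}, \qquad
  \mathrm{JC}(A,B) = \frac{|A \cap B|}{|A|}.$$

The containment $\mathrm{JC}$ is the asymmetric statistic that detects
super/subset relationships: $\mathrm{JC}(F, Q) = 1$ exactly when family
$F$ is fully inside query $Q$.

## The estimator

Every element is hashed with a seeded hash $h$; $A' = \{h(x) : x \in A\}$.
The bottom-$n$ sketch is

$$\mathrm{MIN}_n(S) = \begin{cases}
  \text{the } n \text{ smallest elements of } S & |S| \ge n\\
  S & \text{otherwise.}
\end{cases}$$

Since the hash values are a uniform pseudo-random relabelling of the
elements, $\mathrm{MIN}_n(A' \cup B')$ is a uniform $n$-sample of the
union, and it is computable from the two sketches alone because
$\mathrm{MIN}_n(\mathrm{MIN}_n(A') \cup \mathrm{MIN}_n(B')) =
\mathrm{MIN}_n(A' \cup B')$ — an identity `merge_sketches()` implements
and the test suite checks element-for-element against the brute-force
union. The estimators are

$$\widehat{\mathrm{JI}} =
  \frac{|\mathrm{MIN}_n(A' \cup B') \cap \mathrm{MIN}_n(A') \cap \mathrm{MIN}_n(B')|}
       {|\mathrm{MIN}_n(A' \cup B')|}, \qquad
  \widehat{\mathrm{JC}} =
  \frac{|\mathrm{MIN}_n(A') \cap B'|}{|\mathrm{MIN}_n(A')|}.$$

Both are sample proportions of ``element lies in the intersection''
over a uniform sample without replacement, so they are unbiased with
standard error at most $\sqrt{p(1-p)/n}$, shrinking further by the
finite-population factor when $n$ approaches the set size, and they
become *exact* (bit-for-bit equal to the set-arithmetic oracles
`exact_jaccard_index()` / `exact_containment()`) as soon as $n$ covers
the union. Note the containment estimator needs full membership in $B'$:
the family index therefore stores, per family, both the sketch and the
complete hash set. That is a deliberate memory trade; chunking with
$w > 1$ is the built-in mitigation, shrinking the stored sets roughly
$w$-fold.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `capacity` / `n` | 200 | sketch elements | estimator standard error $\approx \sqrt{p(1-p)/n}$; 25–200 are practical, 200 gives SE $\le 0.035$ |
| `window` / `w` | 4 | residues | set-size reduction factor; $w = 1$ is exact residue resolution |
| `hash_seed` | 42 | — | fixed so sketches are reproducible across runs and machines; distinct seeds give independent estimators |
| `jc_threshold` | 0.5 | containment | a family "overlaps" when either containment direction reaches it |
| `superiority_threshold` | 0.95 | containment | tolerance for declaring $F \subseteq Q$ from a noisy estimate |

The default $w = 4$ balances speed against the false-overlap risk:
residues $i, j$ of one protein collide in a chunk only when
$\lfloor i/w \rfloor = \lfloor j/w \rfloor$, which forces $|i - j| < w$,
so two domains separated by at least $w$ residues can never be confused,
while windows much above 16 make spurious overlaps between the domains
of multidomain proteins increasingly likely. The suite demonstrates both
sides: families with all inter-family gaps $\ge w$ have chunked
$\mathrm{JI} = 0$ exactly, and a crafted pair with a gap below $w$ shows
a positive chunked $\mathrm{JI}$ despite sharing no residue.

`jc_threshold` applies to the *maximum* of the two containment
directions because either direction is curatorially interesting: the
query swallowing a family (superior model) and the query sitting inside
a family (redundant candidate) both constitute overlap. No single
published cut-off exists for "overlaps"; 0.5 — a majority of the smaller
set — is the package default and is fully configurable. The superiority
flag additionally requires the query to have strictly more distinct
elements than the family, so equality never counts as improvement.

## Numerical and design choices

- **Hash.** Tokens are serialized as accession bytes, one 0x00 separator
  byte (forbidden in accessions), then the chunk as an 8-byte big-endian
  integer — an injective encoding, so distinct tokens can only collide
  through the hash itself. The hash is FNV-1a over those bytes with the
  seed folded into the offset basis and a splitmix64 finalizer, mixed in
  64-bit state; the emitted value is the top 53 bits, because 53-bit
  integers are exactly representable in R doubles. That makes sorting,
  membership and decimal serialization bit-exact end to end. The
  collision budget is $\binom{m}{2}/2^{53}$: negligible ($<10^{-5}$) at
  the $10^4$–$10^6$ elements exercised here, and still below one
  expected pair at $10^8$ elements, though a 64-bit container would be
  preferable at that scale.
- **Ties.** Hash sets have set semantics before sketching (duplicate
  raw elements collapse), and hash values are distinct integers, so
  "the $n$ smallest" is unambiguous and sketches are strictly
  increasing by construction.
- **Degenerate inputs.** The estimators divide by a sample size that is
  zero for empty input; rather than returning 0 or NaN, the package
  raises a typed `sketchoverlap_empty_input` condition. One-sided empty
  cases (empty against non-empty) are well defined and return 0.
  Mismatched hash parameters or capacities raise
  `sketchoverlap_incompatible_params` instead of silently comparing
  incomparable sketches.
- **Coordinates.** Region tables are 1-based inclusive; the chunk is
  $\lfloor i/w \rfloor$ of the 1-based coordinate directly. A 0-based
  convention would only shift chunk boundaries by one residue; what
  matters is that indexing and querying share one convention, which the
  parameter check enforces.
- **Complexity split.** The exact oracles use hash-map membership
  (`match`), linear in the set sizes — the honest cost the sketches are
  compared against. The estimators use binary search into the sorted
  stored sets, so a full query–database comparison touches, per family,
  only the sketches plus at most $n$ membership probes in each
  direction: bounded by $n$, not by family cardinality. A test asserts
  this by counting probed elements under a mocked membership routine —
  identical counts for a 400-element and a 40 000-element family.
- **Clan rule.** `multi_family_same_clan` requires *all* overlapping
  families to share one assigned clan; if any overlapping family has a
  different clan or no clan assignment the report says
  `multi_family_mixed`. This is the strict reading; a partial-clan
  variant would be easy to add but blurs the "benign within one clan"
  interpretation.
- **Report ordering.** Overlapping families sort by
  `jc_family_in_query` descending, then family id — deterministic
  output for identical inputs, which the persistence tests rely on.

## The synthetic generator

`synth_config()` / `generate_families()` produce region tables with
*planted, exactly known* relationships: disjoint pairs, subset pairs,
and pairs with a chosen containment fraction. Shared residues are
realized as identical intervals on pair-shared proteins and private
residues on family-private proteins, so $|A|$, $|B|$ and $|A \cap B|$
are known by construction and recorded in a truth table; the test suite
verifies that the exact oracles recover every truth value from the
emitted TSV at $w = 1$. Family sizes are drawn log-uniformly from the
configured range (real family sizes span orders of magnitude), and each
family is laid out as one to five contiguous intervals per protein,
mimicking domain matches rather than scattered residues. Defaults: 20
families, 50 pool proteins of 1000 residues, sizes 50–500.

What the generator does *not* emulate: sequence content and homology
(families are sets, never alignments), match score distributions,
fragmented or partial domain hits, and the long-tailed protein-count
distribution of a real database release. Passing tests therefore show
that the estimators and classification behave as the set theory says on
exactly constructed inputs — they do not validate profile-HMM search
quality or any biological claim about a particular database.

## Problem sizes used by the checks

The bundled checks run at desk scale, chosen so the whole suite
completes in well under an hour on one core: 200 random pairs with
cardinalities up to 500 for saturated-sketch exactness, 100 pairs for
the merge identity, 1000 independent hash seeds at $n = 200$ for the
bias/spread check, and benchmark families of $10^2$–$10^6$ residues.
The benchmark asserts *orderings only* — exact-comparison time grows
with family size, sketch-comparison time does not, and estimator time
grows with $n$ — never absolute seconds, which are hardware-bound.

## Known limitations

- The stored full hash sets make index memory linear in total residue
  coverage divided by $w$; for very large databases at $w = 1$ this is
  the dominant cost.
- 53-bit hash values are comfortable up to about $10^7$–$10^8$ distinct
  elements; beyond that, collision-induced overestimates of overlap
  become possible (see the collision budget above).
- Classification quality at small $n$ degrades for families much larger
  than $n$ near the decision threshold, as the containment estimate's
  standard error approaches $0.5/\sqrt{n}$; raising `capacity` (or
  re-scoring borderline cases with `cmd_exact()`) is the remedy.
- Overlap is detected at family level only; the package does not report
  *which* residues overlap, nor does it implement release-time
  tolerance rules for short overlaps.
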