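---
title: "Methods: temporal-interval networks and condition-gated complex detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal-interval networks and condition-gated complex detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipin)
```

## The model

`tipin` treats a protein complex as a group of proteins that (a) interact
reliably, (b) are expressed together during a bounded stretch of the cell
cycle, (c) share a subcellular compartment, and (d) are functionally
homogeneous. The pipeline encodes each requirement as an explicit, testable
condition rather than leaving it to the topology of a single static graph.

**Undulation, not level.** Expression is normalized per gene to
`gep(t) = (ev_t − min ev) / (max ev − min ev)`, the undulation above the
gene's own base level. This deliberately discards absolute expression level:
a lowly but periodically expressed gene counts as active at its peaks. A
gene with constant expression has no undulation; we set its profile to all
zeros, so it is never active for any positive threshold. Proteins present in
the PPI network but absent from the expression table are likewise treated as
never active — the construction has no profile to consult, and inventing one
would manufacture edges.

**Temporal-interval networks.** The temporal network at time *t* keeps an
edge iff both endpoints are active (`gep ≥ φ`, inclusive) and scores it with
the static reliability. Interval networks intersect consecutive temporal
networks over every closed interval `[t_low, t_high]`, scoring each edge
with the interval minimum. The implementation computes them bottom-up by
interval length with the recurrence `b[l,h] = min(b[l,h−1], b[l+1,h])`,
holding at most two diagonal bands in memory; an independent brute-force
minimum over the interval serves as the test oracle. The diagonal (length-1)
networks are included in the identification sweep, giving `T·(T+1)/2`
networks; the source material counts `T·(T−1)/2` in one place and
`T·(T+1)/2` in another, and we follow the larger count because the
length-1 networks are exactly the temporal networks and excluding them would
forfeit complexes visible at a single time point.

**Admission conditions.** A cluster grows only while a frontier protein
(linked to the cluster by an edge of score ≥ r) keeps all three conditions
true:

- *Joint colocalization*: the AND of the members' 22-compartment vectors
  must stay non-zero. Both the count `JC` and the coexpression quantity `JQ`
  are anti-monotone under set growth, which the suite checks by property
  tests; this also allows incremental evaluation during expansion.
- *Joint coexpression*: `JQ ≥ γ`, where `JQ` is the mean over the interval's
  `l + 4` window of the product of the members' normalized profiles. The
  window adds two time points on each side of the interval and truncates at
  the boundaries (start at 1 when `t_low < 3`, end at T when
  `t_high > T − 2`).
- *Expanding-cluster condition*: per ontology (CC, MF, BP), the minimum
  protein similarity between the candidate and its r-reliably linked cluster
  members must clear σ, ω, θ respectively; admission requires two of the
  three flags. A candidate with no r-reliable link to the cluster in a given
  ontology contributes value 0 (the flag fails): an expansion candidate that
  cannot be reliably tied to the cluster should not join on similarity
  grounds alone.

**GO similarity kernel.** The term-level similarity is
`exp(−c1·l) · tanh(c2·h) · tanh(c3·d)` with `c1 = 0.2`, `c2 = 0.3`,
`c3 = 30`, where the *mica* is the common ancestor with maximal information
content, `l` is the sum of the shortest-path lengths from the mica to the
two terms, and `h`, `d` are the mica's depth and information content. The
two quotient factors in the original exponential notation are analytically
`tanh`; the suite verifies the identity to 1e−12. Protein similarity
averages best-match term similarities in both directions over the *directly*
annotated term sets (no ancestor closure — the averaging formula is defined
over the annotating sets as given).

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `phi` | active threshold on normalized expression, \[0, 1\] | 0.1 | published value for STRING-based networks; low values retain more dynamics |
| `r` | reliability threshold, 1–999 | 999 | published value for STRING (990 for DIP) |
| `sigma`, `omega`, `theta` | CC/MF/BP minimal-similarity thresholds | 0.7, 0.6, 0.1 | published values (DIP variant: 0.7, 0.1, 0.3) |
| `gamma` | joint-coexpression threshold | 0.01 | **no published value**; required tuning parameter, flagged here and in the reference docs |
| `lambda` | overlap-score match threshold | 0.2 | standard in the complex-matching literature |
| `psi` | enrichment significance level | 0.01 | standard; strict inequality `p < psi` |
| `min_size` | smallest reported cluster | 2 | published size distributions count pairs |

## Numerical and procedural choices

Where the source description is silent, the implementation fixes behaviour
as follows (each is a deliberate design decision, not an accident of code):

- **Duplicate scored pairs** keep the maximum score (conservative upper
  bound on reliability); self-interactions are dropped and counted.
- **Seed order**: descending weighted degree within the interval network,
  ties by protein ID; **frontier order**: descending best edge score to the
  cluster, ties by ID; one admission per iteration with frontier
  recomputation. These rules make the algorithm fully deterministic —
  identical inputs give byte-identical catalogs.
- **Membership exclusivity is per interval network**: a protein placed in a
  cluster cannot seed or join another cluster in the same network but may
  participate in other intervals; exact member-set deduplication with
  interval provenance then merges the sweep's output (a `dedup = "none"`
  switch preserves raw per-interval counts).
- **Condition order** is colocalization → coexpression → expansion with
  short-circuiting, cheapest first.
- **`JQ` denominator**: the quantity is averaged over the `l + 4` window
  (`denominator = "window"`); the literal formula divides the windowed sum
  by T, available as `denominator = "T"`. Window averaging keeps γ
  comparable across interval lengths.
- **Missing localization** defaults to "localized everywhere" so that absent
  GFP data cannot veto a cluster; `strict = TRUE` inverts this.
- **Information content** is descendant-annotation frequency with natural
  log, `d = −ln(n_t / n_corpus)`; depth is the longest root-to-term path;
  mica ties on IC are broken by the smaller path sum, then lexicographically.
  The similarity kernel's original publication fixes its own IC convention,
  which is not restated in the method description we implement; our choice is
  a documented deviation point, not a claim about that original.
- **MMR** follows the printed formula (mean over known complexes of the best
  overlap score). The prose invokes a one-to-one mapping, so a true
  maximum-weight bipartite matching variant is provided (`mmr = "matching"`,
  via igraph); both values are always reported.
- **Hypergeometric tail** uses the stable survival function; the test oracle
  is exhaustive subset enumeration up to N = 15. Enrichment applies no
  multiple-testing correction (matching the evaluated protocol); a complex's
  p-value is the minimum over its members' terms.
- Threshold comparisons are inclusive (`≥`) everywhere except the enrichment
  significance call, which is strict (`p < ψ`), matching the printed
  inequalities. Scores are integers and interval minima are exact.

## What the synthetic generator emulates — and what it does not

`generate_bundle()` plants vertex-disjoint complexes (default 10, sizes 3–6)
in a background of 100 proteins over a 12-point time course. Members of a
complex carry maximal-reliability (999) pairwise edges, share one
subcellular compartment, share a complex-specific GO term of depth 5 in all
three ontologies, and are expressed above base level exactly on the `l + 4`
window around a planted interval. Background proteins get uniform random
expression, random compartments, a shallow generic GO term, and random edges
scored 1–900 — below every published reliability threshold, so background
cannot complete spurious r-reliable clusters (verified by a post-check).
Expression noise adds Gaussian perturbations scaled by the signal amplitude.

A green recovery test therefore establishes that the pipeline's plumbing —
normalization, activity, interval intersection, window logic, the three
conditions, deduplication, and the matching metrics — is correct end to end.
It does **not** establish performance on real data: the generator has no
scale-free topology, no correlated noise, no overlapping complexes (except
in the stress mode), no missing-data patterns, and its GO ontology is a toy.
The published full-scale benchmark numbers additionally depend on database
downloads and the unpublished γ, and are out of scope.

The degradation property (recovery non-increasing in noise) is stressed at
`phi = 0.5` rather than the default 0.1: at the published low threshold,
activity is nearly noise-proof — which is precisely the argument for a low
threshold — so the default setting exhibits an (uninformative) flat profile.
Measured at `phi = 0.5` over 20 seeds, mean exact recovery is 1.00 / 1.00 /
0.76 at noise 0 / 0.25 / 0.6 (recomputed by the test each run).

## Known limitations

- γ must be tuned per data set; the default 0.01 is a placeholder with a
  documented sensitivity to interval length under `denominator = "T"`.
- The identification is non-overlapping within an interval network by
  construction; overlapping complexes are only recoverable when their
  activity intervals differ.
- Protein/gene identifiers are matched by exact string equality across
  inputs; no alias resolution is attempted.
- The OBO reader handles the `is_a` backbone of OBO 1.2 (sufficient for GO
  releases and the generated ontologies); other relationship types are
  ignored.
- Complexity is O(N²) per interval network and there are T·(T+1)/2 networks;
  for genome-scale networks with long time courses, memory stays modest (two
  diagonal bands of edge vectors) but runtime grows quadratically in T.
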