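---
title: "Methods: network pharmacology with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The model

Network pharmacology treats a multi-herb preparation as a multi-target
perturbation: each herb contributes compounds, each compound binds a set of
protein targets, and a disease is represented as a gene set. The analytic
chain implemented here is:

1. **ADME screening.** Compounds are retained when their oral
   bioavailability (OB, percent) and drug-likeness (DL, unitless in
   $[0,1]$) clear configurable thresholds. The defaults, OB $\ge 30$ and
   DL $\ge 0.18$, are the conventional TCMSP cutoffs; both comparisons are
   inclusive ("$\ge$") because the screening rule is stated that way in the
   sources these tables come from, with a strict mode available.
2. **Cross-herb deduplication.** The compound identity key is the `MOL`
   accession, not the free-text name (two herbs can list the same molecule
   under different names, and the same name can label different
   stereoisomers). Every herb-level listing beyond the first per accession
   counts as one duplicate removed, so `unique + removed = listings` holds
   exactly.
3. **Target intersection.** Disease-gene lists from several databases are
   unioned with provenance, then intersected with the union of compound
   targets. All gene symbols are uppercased before any set operation:
   source tables mix protein and gene nomenclature, and set arithmetic must
   be deterministic. No alias or ortholog resolution is attempted.
4. **Tripartite network.** An undirected simple graph over three
   partitions (herb, compound, gene); edges exist only for herb membership
   and surviving compound-target pairs, so a compound's degree decomposes
   exactly as herb memberships plus mapped targets inside the common gene
   set. Key compounds are those whose degree *strictly exceeds* the
   whole-network mean degree $2E/N$ — "exceeding" is read as $>$, and the
   mean is taken over all nodes of all three partitions, isolated nodes
   included. Ties in top-$k$ selection break lexicographically so the
   selection is reproducible.
5. **PPI hub analysis.** Scored interaction edges (STRING convention,
   0–1 or 0–1000 scale) are filtered at a *strict* confidence threshold
   ($> 0.9$ by default; STRING's own "highest confidence" preset is
   $\ge$, available via `strict = FALSE`). Duplicate undirected edges keep
   the maximum score because exports often contain both orientations.
   Query genes with no surviving edge are dropped from the node set and
   reported — this is what makes a 48-gene query yield, say, a 45-node
   network — and hubs are again strict above-mean nodes.
6. **Enrichment.** For a query of $n$ genes against a pathway of $K$ genes
   in a universe of $N$, the statistic is the hypergeometric upper tail
   $P(X \ge k)$, equal to the one-sided Fisher exact test of the 2×2
   table. It is computed in-package from log-binomials with log-sum-exp
   accumulation; tests verify it against `stats::phyper`,
   `fisher.test`, and an exhaustive enumeration oracle for $N \le 12$.
   The default filter is raw $p < 0.05$ with results sorted by $p$ and
   truncated to the top 30; Benjamini–Hochberg adjustment (our own
   step-up, tested against `p.adjust`) is opt-in because the convention
   this workflow follows reports raw Fisher p-values. Note that DAVID — a
   common choice for this analysis — actually computes an EASE-adjusted
   Fisher score; the plain test here is therefore slightly
   anti-conservative relative to DAVID output.
7. **Docking ingestion.** Docking is executed by external tools; only
   their binding-energy output (kcal/mol) is ingested. Lower energy means
   stronger predicted binding; negative energy means spontaneous binding.
   Duplicate poses keep the minimum energy, ranking is ascending with
   lexicographic tie-breaks, and missing cells stay `NA`, never zero.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `ob_min` | 30 | percent | conventional TCMSP bioavailability cutoff |
| `dl_min` | 0.18 | – | conventional TCMSP drug-likeness cutoff |
| `ppi_min_score` | 0.9 | confidence (0–1) | "highest confidence" interaction threshold, applied strictly |
| `p_max` | 0.05 | probability | raw Fisher significance filter |
| `top_n` | 30 | pathways | bubble-plot presentation convention |
| universe $N$ | union of the GMT | genes | the only self-contained default when the annotation background is unstated; configurable |

Query genes missing from the universe shrink $n$ (with a message) rather
than inflating $N$; inflating the universe with unannotated genes would
bias every p-value downward.

## The synthetic world

`sim_config()` defaults state the world of a nine-herb formula study and
are not tuned per test: 9 herbs × 131 listings ≈ 1180 compounds; bioactive
fraction 0.145 (≈ 171/1180); cross-herb duplicate rate 0.105 (≈ 18/171); a
269-gene target universe; 255 disease genes of which exactly
`round(48/255 × 255) = 48` overlap the drug-target union (the overlap is
*constructed*, not sampled, so downstream counts are sharp); PPI edge
density 0.45 with 80% of edges above the 0.9 threshold (post-filter
density ≈ 0.37, the density implied by a 45-node/366-edge network); three
isolated query genes (so 48 query genes induce 45 nodes); four planted PPI
hubs wired to every non-isolated gene.

Planted hub compounds get target counts `c(150, 110, 90, 75, 60)`
*before* restriction to the common genes. After thinning by the overlap
fraction 48/269 these land near the printed per-compound counts of the
top-5 compounds in this kind of study (≈ 27, 20, 16, 13, 11 against
30/14/14/10/8), while background compounds draw from a heavy-tailed
negative binomial (mean 8, size 2). Hub herb memberships
`c(3, 5, 1, 4, 3)` are likewise the published top-5 pattern.

The planted enrichment boost deserves its own note. The planted pathway's
overlap with the query is set to `round(K n / N) + boost`. Ranking is by
p-value across pathways of *heterogeneous* sizes, and the planted pathway
must beat the minimum of ~100 null p-values, so the margin that matters is
the boost measured in null standard deviations at the *largest* configured
pathway size ($K = 80$, $n = 48$, $N = 269$ gives $\sigma \approx 2.9$).
The default `boost = 12` is ≈ 4σ at that worst case; a first draft used
8 (4σ at the *mean* size) and a pre-freeze power analysis showed it loses
first rank in ~10% of replicates precisely when the planted pathway is
large. The detection property the test suite checks (first rank in ≥ 95%
of 200 replicates) is the operational definition of "planted", so the
default is calibrated to deliver it at the worst-case size.

A single integer seed drives every generator through a fixed splitting
scheme (`seed × 101 + stage offset`, reduced mod $2^{31}-1$), so one
number reproduces the entire fixture set byte-for-byte.

What the generator does **not** emulate: real TCMSP chemistry (OB/DL are
drawn from uniform ranges, not computed from structure), real PPI topology
(background edges are Erdős–Rényi, not scale-free), pathway overlap
structure (null pathways are independent uniform draws), and gene-symbol
semantics. A green synthetic test therefore establishes that the *pipeline
arithmetic* — filtering, set operations, degree bookkeeping, the
enrichment statistic — is correct and that planted signal of realistic
magnitude is recovered; it says nothing about the biological validity of
any particular database snapshot.

## Numerical and degenerate-input choices

- The hypergeometric tail is accumulated in log space and clamped at 1;
  $k = 0$ returns exactly 1.
- Mean degrees are reported exactly as $2E/N$ and rounded to 3 decimals
  only for display; hub selection uses the unrounded value.
- Empty screens, empty intersections and header-only tables are legal and
  flow through with warnings, never errors; an empty universe, an empty
  network, or infeasible hypergeometric margins are errors.
- Venn tabulation is capped at 6 sources (region count doubles per
  source).
- Conflicting OB/DL across listings of one accession warn and keep the
  first occurrence.

## Known limitations

- The bundled compound table records only per-compound *counts* of mapped
  targets; gene-level assignments were never published, so the bundled
  target map (`synthetic_wjd_target_map()`) is a deterministic synthetic
  stand-in that reproduces those counts exactly. Degree and partition
  checks are valid against it; gene-identity claims are not.
- Two published degree values (quercetin 34, stigmasterol 12) exceed by
  one what the published table itself implies (33 and 11); the package
  reproduces the table-implied values and does not assert the printed
  ones. Similarly the published whole-network mean degree 4.906 is not
  derivable from the published table under any edge-counting convention
  we tried (our fixture gives 5.34 over 106 nodes).
- EASE-style adjustment of the Fisher score is not implemented.
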