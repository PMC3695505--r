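---
title: "Detecting duplicon insertion breakpoints and reconstructing inserted sequences"
author: "duprec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting duplicon insertion breakpoints and reconstructing inserted sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duprec)
library(data.table)
```

## The problem

When a copy-number analysis reports that a genomic segment has *gained*
copies in a sequenced individual, two questions remain unanswered: **where**
did the extra copies insert, and **what sequence** do they actually carry?
Neither is trivial. The new copy is, by construction, highly similar to a
region that already exists in the reference, so reads sampled from it map
back onto the original locus; the only direct evidence of the insertion is
the thin layer of read pairs that straddle its two junctions. And because
each copy accumulates its own substitutions and indels after duplication,
the reference sequence of the source region is only an approximation of the
inserted sequence.

`duprec` addresses both questions for *low-copy, non-tandem* duplications,
given (i) a reference genome, (ii) paired-end alignments and (iii) a list of
candidate copy-number-gain regions produced by any external CNV caller.
Tandem expansions, breakage–fusion–bridge patterns, chromothripsis and
retrotransposon mechanics are out of scope, as is CNV calling itself.

## Pipeline overview

For every candidate region `H` the pipeline proceeds in two phases.

**Breakpoint detection.**

1. *Homolog recruitment* (`find_homologs`). All reference regions with
   more than 95% identity to `H` over a comparable block (length difference
   under 20%) are collected into a homology set `H1..Hn`, `H1` being the
   candidate itself. Reads are then interpreted relative to the whole set:
   a read pair bridging two pre-existing homologs is not insertion
   evidence.
2. *Pair collection and triage* (`collect_pairs`, `triage`). Every mate
   pair with at least one end on a member or its 1 kb flank is classified
   into five classes: two-end (both ends inside the set), concordant or
   discordant one-end (one end inside, the mate outside with valid or
   invalid geometry; for the default 500 bp library a pair is concordant
   when its outer span lies within 300–800 bp in forward–reverse
   orientation), orphan-one-end (one end unmapped) and orphan. Unmapped
   ends with fewer than 10 bases under Q20 are realigned by Smith–Waterman
   against the set and its flanks and *rescued* when identity exceeds 0.92
   and the score exceeds 80% of a perfect match; rescued reads are promoted
   between classes (orphan to two-end, concordant- or discordant-one-end)
   according to where they land.
3. *Specificity scoring.* A discordant one-end read only carries
   information in proportion to how uniquely it is placed. For each such
   pair, both ends are queried against the whole genome for every placement
   within edit distance 6, and all paired placements are enumerated. If a
   concordant paired placement exists with total edit distance no worse
   than the best discordant one, the pair is discarded (a known concordant
   explanation is always preferred). Among the preferred discordant
   placements `D`, the read's placement `d` scores
   `s(d) = 2^-(e(d) - e_min(D)) / n_e(d)`,
   where `n_x` counts elements of `D` at edit distance `x`: exactly 1 for a
   unique best placement, geometrically less for ambiguous or poorly
   matching ones.
4. *Clustering and composition* (`cluster_ends`, `call_breakpoint`).
   External ends of supporting reads are single-linkage clustered with gap
   threshold equal to the insert size. At a true insertion all forward
   external reads lie upstream of the breakpoint and all reverse ones
   downstream; the breakpoint `b` is placed midway between the rightmost
   forward end and the leftmost reverse start (with a one-sided fallback of
   `I − L` past the innermost end). Reads violating the orientation
   pattern are *conflicting*: their specificity is subtracted from the sum
   of the supporters'. A cluster becomes a call when the resulting score
   reaches 2.0 — two unique, unambiguous discordant reads. A strict mode
   additionally drops any call with a single conflicting read.
5. *Zygosity* (`estimate_zygosity`). Concordant pairs spanning `b` are
   counted against the rate at flanking control positions under a Poisson
   model with rates `lambda` (no insertion), `lambda/2` (heterozygous) and
   approximately 0 (homozygous); a spanning rate indistinguishable from the
   background flags the call as suspect.

**Sequence reconstruction.** Each duplicon — every homolog and every
accepted breakpoint — is modelled by a profile HMM.

1. *Templates.* Homolog models start from the member's reference sequence.
   A breakpoint model starts from a subsequence of the longest homolog
   spanning the projections of its supporting reads' internal mates, padded
   by one read length: if only a fraction of the candidate region was
   duplicated, the template shrinks accordingly.
2. *Initial training.* Match emissions and transitions are initialised
   from a single observation of the template. Concordant one-end reads,
   anchored by their mates in the unique flank of a homolog, train that
   homolog's model; the internal mates of breakpoint-supporting discordant
   reads — plus orphan mates rescued around the breakpoint itself — train
   the breakpoint's model. All of this evidence sits near duplicon
   boundaries, so models are trained boundary-in; the *frontier* marks how
   far training has reached.
3. *Constrained updates.* With observation counts `O_v` of symbol `v`,
   background pseudo-counts `c_v`, and `O` total observations, emissions
   update as `E(v) = (O_v + w c_v) / (O + w sum(c))` with
   `w = w0 exp(-rho O)`, then are clamped to `[mu/3, 1 - mu]` and
   renormalised. `mu` is the sequencing error rate: no amount of evidence
   can drive a probability to 0 or 1, and with no evidence the background
   is preserved. Transitions update identically per state family.
4. *Recruiting.* Unassigned two-end pairs are decoded against every model
   hosting their anchors by *anchored Viterbi*: entry states are restricted
   to a window around the read's mapped offset, which makes decoding cheap
   without changing the optimum when the true start lies inside the window.
   A pair is assigned to the maximum-likelihood model only when (i) every
   hosting model has been trained near the pair so the comparison is fair,
   (ii) the best model leads the runner-up by a log-likelihood margin, and
   (iii) the joint likelihood clears a log-odds threshold against a uniform
   background. Everything else is deferred to later rounds. Retraining and
   recruiting alternate until all pairs are assigned or a round assigns
   nothing — the latter occurs when duplicons share an identical stretch
   longer than the insert size, leaving an unresolved core that is reported
   as such.
5. *Consensus.* Per column the maximum-emission base is emitted; columns
   whose delete usage outvotes match usage are dropped; insertion states
   used by a majority of spanning reads emit the majority inserted string;
   untrained columns fall back to the template base.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `insert_size` (I) | 500 bp | expected outer fragment span |
| `insert_lo`, `insert_hi` | 0.6 I, 1.6 I | concordance window (300–800 bp at default I) |
| `read_length` (L) | 100 bp | read length |
| `flank_width` | 1000 bp | flank used for retrieval and rescue |
| `min_similarity`, `min_score_fraction` | 0.92, 0.80 | rescue acceptance |
| `q_threshold`, `max_low_qual_bases` | Q20, 10 nt | base-quality filter |
| `max_edit` | 6 | mapper / match-set edit bound |
| `bp_score_threshold` | 2.0 | minimum breakpoint score |
| `bp_high_threshold` | 20.0 | highly-confident flag |
| `mu` | 0.01 | sequencing error rate; emission floor `mu/3`, cap `1-mu` |
| `rho` | 0.1 | training rate (prior decay per observation) |
| `min_depth` | 2 reads | column depth before it counts as trained |
| `recruit_threshold` | 2.0 nats | log-odds vs uniform background |
| `recruit_margin` | 2.0 nats | required lead over the runner-up model |
| `anchor_window` | `2 * max_edit` | Viterbi entry window |

The concordance window generalises the stated 300–800 bp instance for a
500 bp insert; `rho` has no published value and 0.1 makes the prior decay
to 5% of its weight by 30 observations; `recruit_margin` equals one
well-trained discriminating site's log-odds contribution (about 5.7 nats at
the clamp bounds) with room for noise, so a pair is only assigned when it
covers real evidence.

## The simulated world

`simulate_dataset()` regenerates the accuracy experiment end-to-end with no
downloads. One replicate is:

* a reference of five 50 kb chromosomes of i.i.d. sequence at GC 0.41,
  seeded with three interspersed repeat families — a young (1.5%
  divergence, 4% of the genome) and an old (12%, 5%) 300 bp SINE-like
  family and a young (1%, 3%) 4 kb LINE-like family. The young families
  are what make short-read placement ambiguous, as in real genomes; a
  breakpoint landing inside a young LINE copy is genuinely hard and is the
  dominant cause of missed breakpoints;
* a donor carrying 1–4 copies of a uniformly chosen 1–3 kb segment, each
  copy independently mutated (3% substitutions, 1–5 bp indels at 5x10^-4
  per bp, 10% chance of a terminal truncation of up to 20%) and inserted
  non-tandem, at least 5 kb from the source and from each other;
* a 40x, 100 x 2 bp, 500 bp-insert (sd 30) library at 0.5% base error,
  with a seeded 5% of reads carrying a Q2 tail so the quality filter has
  work to do; the published experiment pairs exactly this read geometry
  with a 40x dataset;
* mapping by the built-in seed-and-extend mapper (edit distance <= 6,
  co-optimal placements resolved deterministically to the lowest
  coordinate, MAPQ 0 for multimappers).

What the generator does **not** emulate: realistic quality ramps and
indel-rich homopolymer errors, chimeric fragments, GC-coverage bias,
diploidy (the donor is a single haplotype, so simulated insertions are
homozygous), nested or tandem duplication, and real repeat taxonomy beyond
the three families above. A green accuracy suite therefore establishes
that the method recovers planted, non-tandem duplications under idealised
but repeat-confounded mapping — not performance on real sequencing data.

## Numerical and design choices

* **Coordinates** are 0-based half-open internally; SAM/BED conversions
  live in the readers and writers only. A call's position is the leftmost
  base of the inserted sequence.
* **Specificity form.** `2^-(e - e_min)/n_e` is the simplest function that
  is 1 exactly at a unique minimum and decays geometrically with both extra
  edit distance and multiplicity; it is isolated in `specificity_score()`
  so an alternative can be substituted in one place.
* **Cluster thresholds.** Both the intra-cluster gap and the distal
  spacing use the insert size; under single-linkage these coincide, making
  a separate distal filter vacuous.
* **Mixed-composition clusters.** When the extreme-end midpoint for `b`
  would classify some cluster reads as conflicting, `b` is instead placed
  at the boundary maximising support minus conflict; for clean clusters
  the midpoint rule applies unchanged.
* **Shadow clusters.** Deterministic lowest-coordinate placement of
  co-optimal hits sends every ambiguous read near a junction-in-a-repeat
  to the same alternative repeat copy. The resulting pile is a one-sided
  cluster composed entirely of multi-mapped reads, and enough of them
  clear the score threshold (n reads at specificity 1/2 score n/2).
  A call whose support contains no uniquely placed read therefore also
  requires the full two-sided orientation composition; clusters with at
  least one unique supporting read are never affected. This is the one
  place where a composition deviation rejects rather than warns: such
  piles are pure mapping artefacts, with the one-sided shape the
  composition test is designed to recognise. A second arbitration pass
  handles two-sided shadows: a call with no unique support whose reads
  mostly have a co-optimal alternative placement inside another call that
  does have unique support is recognised as that call's shadow and
  dropped.
* **Junction tolerance.** The mapper aligns full reads, so a read crossing
  a junction by a few bases is stretched past it at mismatch cost;
  orientation classification allows `max_edit` bp of slack so such reads
  still support the call.
* **Emission clamps.** The floor `mu/3` spreads the error mass uniformly
  over the three alternative bases and makes the bounds exactly attainable
  (`(1-mu) + 3 * mu/3 = 1`); renormalisation distributes any residual mass
  proportionally to the remaining headroom, so the bounds are never
  violated.
* **Recruit precondition.** Requiring *both* ends of a pair to lie inside
  the trained frontier would freeze the frontier (an assigned pair could
  never add columns). One end must be near a trained column; the far end
  is what extends the frontier. In the same spirit, a pair is only
  assigned when every model hosting it could be scored, so no model claims
  reads merely because its frontier arrived first.
* **Insert emissions** stay uniform; inserted content is reconstructed
  from the majority inserted string per junction, which is robust for the
  short (1–5 bp) indels the generator plants.
* **Ties** defer rather than randomise, everywhere, keeping runs
  deterministic; co-optimal mapper hits take the lowest coordinate.
* **Homolog search** is forward-strand only; an inverted duplicon is
  handled by supplying the inverted sequence as the template.

## Known limitations

* Split-read (within-read) breakpoint evidence is not used, so breakpoint
  precision is bounded by fragment-sampling granularity (a few bp at 40x).
* Duplicons sharing an identical stretch longer than the insert size
  terminate with an unresolved central core; longer inserts or reads are
  the only remedy.
* Homologs below 95% identity are deliberately not recruited; such copies
  behave as novel insertions and need de novo assembly instead.
* The zygosity estimate assumes roughly uniform coverage around the
  breakpoint and returns UNKNOWN below 5 spanning pairs of local
  coverage.
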