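---
title: "Detecting nick-associated motifs from strand-specific long-read coverage"
author: "phagenick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nick-associated motifs from strand-specific long-read coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagenick)
```

## The problem

Some bacteriophages carry site-specific single-stranded breaks (nicks) in
their double-stranded DNA genomes. Because nanopore sequencing reads native
single strands, a nicked strand cannot be read across the break: molecules
terminate there, and the per-strand mapping depth collapses abruptly at the
nick while the opposite strand and a whole-genome-amplified (WGA) control —
which repairs/removes nicks by resynthesis — retain normal coverage. This
one-strand depth signature identifies nick positions without any dedicated
chemistry. Nick sites in such phages share a short degenerate sequence
motif (written in IUPAC codes, e.g. `WACTRTGAC`, W = A/T, R = A/G), and the
motif's strand bias, chance expectation, conservation across related
genomes, and position relative to genes are all informative about its
biology. `phagenick` implements that entire analysis as a reusable,
tested pipeline, together with a synthetic-data generator that provides
every input with known ground truth.

## Nick detection model

Let `d_s(x)` be the native read depth of strand `s` at base `x` and
`c_s(x)` the WGA-control depth. A position is flagged as part of a
candidate nick on strand `s` when all of the following hold:

1. **near-zero same-strand depth**: `d_s(x) <= max(tau_abs, tau_rel * median(d_s))`
   — the absolute ceiling (`tau_abs = 2` reads) tolerates rare read-through
   or chimeric molecules, and the relative term (`tau_rel = 0.05`) scales
   with sequencing effort;
2. **healthy opposite strand**: `d_s'(x) >= min_other_strand * median(d_s')`
   (default 0.5) — a genuine single-strand break leaves the other strand
   untouched, whereas deletions, mapping artefacts and low-complexity
   regions depress both strands;
3. **healthy control**: `c_s(x) >= min_control * median(c_s)` (default
   0.5) — the WGA sample is used strictly as presence-of-coverage
   evidence, not for signal-level comparison.

Flagged positions closer than `merge_gap = 5` bp are merged into
intervals. Intervals touching the first or last 200 bp are discarded:
physical termini of linear genomes produce genuine coverage cliffs that
are not nicks. Calling is refused outright (an explicit error, not an
empty result) when either strand's native median depth falls below
`min_callable_median = 10`, since absence of drops in an undersequenced
library is not evidence of absence of nicks. Both strands are tested
symmetrically and the depleted strand is reported, because assembly
orientation is arbitrary.

The nick point estimate is the interval midpoint. The exact broken base
within the motif is not identified — distances to motifs are reported
instead.

### Motif association

Drop intervals and motif hits are matched one-to-one greedily by
ascending midpoint distance (ties broken by coordinate), with a maximum
association distance `window = 50` bp and each hit used at most once.
Greedy matching is deterministic and, in the regime that matters (drops
centred inside motifs hundreds of bases apart), identical to optimal
matching.

## Degenerate motif statistics

`scan_genome()` reports every occurrence of an IUPAC pattern on both
strands of the linear sequence; overlapping occurrences all count, and a
window containing an ambiguous genome base (N) never matches —
conservative counting that cannot inflate strand asymmetry. The
per-strand chance expectation under an i.i.d. base model is

```
E = (L - k + 1) * prod_j ( sum_{b in code_j} p(b) )
```

with `p` the genome's own A/C/G/T composition (computed ignoring Ns) or
the uniform 1/4 model. For `WACTRTGAC` (k = 9, 4 concrete k-mers) on a
uniform 45,228 bp sequence this gives `45220 * 4 / 4^9 = 0.690` expected
occurrences per strand:

```{r expectation}
expected_count("WACTRTGAC", 45228)
```

Whether the window count (`L - k + 1`) or the plain length `L` enters the
formula is a matter of convention that changes the value by under 0.1%;
both are exposed via `length_convention`. The headline statistic for
cross-genome comparison is the **net strand difference**
`|n_fwd - n_rev|`; the absolute value makes it invariant to the arbitrary
strand each assembly happens to be deposited on.

### Consensus recovery

`consensus_from_sites()` is a small deterministic stand-in for a motif
discovery tool: fixed windows (`flank = 25` bp) around candidate sites
are aligned by their best-matching k-mer against the first window, and
per-column base sets are merged into IUPAC codes. A candidate is accepted
only if every column has at most two alternative bases **and** at most a
third of columns are degenerate; without the second rule any two
unrelated windows would produce a vacuous "consensus", since two
sequences can never exceed two alternatives per column. Longer motifs are
preferred, then fewer degenerate columns, then lexicographic order.
Failure is a `NULL` result, distinct from an error. This finder assumes
the motif is present once per window at a consistent offset after
alignment; it is not an EM/PWM discovery algorithm and does not model
gapped or two-part motifs.

## Proteome relatedness (wGRR)

Conservation of the motif is interpreted against genome relatedness,
computed as weighted gene repertoire relatedness:

```
wGRR(A, B) = sum_{(a,b) in BBH(A,B)} id(a, b) / min(|A|, |B|)
```

Bidirectional best hits (BBH) come from all-vs-all global protein
alignments (BLOSUM62, gap open 11, extend 1 — the classic protein-search
defaults); a pair is kept when each member is the other's best-scoring
partner and passes `min_identity = 0.35` and `min_coverage = 0.5`
(aligned span over the shorter sequence), common wGRR practice. Identity
is identical residue pairs over alignment columns including gaps; a
`shorter`-denominator variant is provided because the convention differs
between tools. wGRR is 1 for identical repertoires and 0 when nothing
aligns above threshold.

Genomes are clustered by average-linkage agglomeration on the distance
`1 - wGRR`, with flat clusters cut at a user-chosen wGRR threshold
(`cut = 0.5` default — inside a cluster, genomes share on average half
their weighted repertoire). The within-cluster versus outside-cluster
mean net motif count around a focal genome summarises motif enrichment in
the focal clade.

## Positional statistics

For cross-genome positional comparison every genome is reoriented to
start at its terminase large subunit (terL) gene — the most reliably
annotated phage gene — reverse-complementing first when terL lies on the
minus strand. Rotation treats coordinates as circular for bookkeeping; a
CDS spanning the new origin keeps `end > length` (unrolled), and the
sequence junction is explicit in the transform record. Motif positions
are then expressed two ways:

* `rel_genome`: hit midpoint over genome length, in [0, 1);
* `rel_cds`: position of the hit midpoint along the containing CDS in
  the CDS's own 5'→3' direction (0 = start codon), with the hit-to-CDS
  relation classified as coding-strand, template-strand or outside.

A hit "occurs within" a CDS if it overlaps it at all
(`overlap_mode = "any"`, the default, matching the natural reading of
"at least partly within"); `"midpoint"` requires the midpoint itself
inside and is the right choice when comparing against coding density,
since then the outside fraction of uniformly placed hits converges to
exactly `1 - coding_density`. Hits overlapping two CDS go to the one
containing more of the hit (ties to the smaller start). `rel_cds` is
clamped to [0, 1] for midpoints that hang over the edge of the assigned
CDS in `"any"` mode.

## What the synthetic data emulate — and what they do not

The generator produces every input the pipeline consumes, with recorded
ground truth:

* **Genome**: i.i.d. bases at a requested GC (defaults 45,228 bp, GC
  0.525, mirroring the study organism's scale); `n_nicks = 13` motif
  occurrences planted on one strand at jittered even spacing (≥ 500 bp
  apart, ≥ 500 bp from the ends), each containing one nick at the motif
  centre. Accidental background occurrences are re-scanned and recorded.
* **Reads**: randomly sheared linear molecules — truncated-normal
  lengths (4000 ± 2000 bp, minimum 200), uniform placement with
  clipping at the termini, so expected coverage is uniform edge to edge;
  strand assigned uniformly; default 50× per strand. Native reads on the
  nicked strand are split at every nick they span and lose
  `nick_end_trim = 5` bp on each side of the break (the end losses that
  make the drop visible — with a pure zero-width split both fragments
  together would still cover every base). Read-through probability and a
  uniform substitution error rate are configurable and default to 0,
  keeping coordinates exact: nick detection consumes only coordinates,
  so error modelling is cosmetic for this purpose.
* **Annotation**: CDS blocks of 600–1200 bp tiled with gaps sized to a
  target coding density (default 0.89, a typical bacterial value), the
  final block adjusted so the realised density matches the target to
  within a codon; the first CDS is labelled "terminase large subunit".
* **Family**: a focal clade (10 genomes) carrying 8–12 same-strand motif
  copies biased towards the second half of the terL-oriented genome, and
  an outgroup (10 genomes) with Poisson(0.7) chance-level occurrences on
  random strands. Proteomes descend from shared ancestors with per-site
  substitution rates calibrated analytically: each genome diverges from
  its group ancestor at rate `m` with `(1 - m)^2 = within_identity`, and
  the outgroup ancestor shares a fraction
  `between_identity / within_identity` of sites with the clade ancestor.
  Genomes are built in the terL-first frame and then hidden behind a
  random rotation (anchored in an intergenic gap, never splitting a CDS
  or planted motif) and an optional reverse-complement, so reorientation
  is genuinely exercised.

Deliberately absent: nanopore error and homopolymer models, chimeric
reads, indels in proteins (substitution-only evolution keeps identity
targets analytic), GC skew and oligonucleotide structure in the
background sequence, and raw-signal data. Passing tests therefore
demonstrate the pipeline's correctness and calibration under a clean
generative model, not robustness to every artefact of real libraries —
on real data the thresholds exist precisely to absorb such artefacts,
and may need adjustment for unusually noisy or low-depth runs.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; GFF3 crosses the
  boundary as 1-based inclusive, BED as 0-based half-open.
* Reads with mapping quality 0 are kept by default (small, non-repetitive
  phage genomes); `min_mapq` is exposed.
* Tie-breaks are all deterministic: scan order by position then strand;
  greedy association by distance then coordinate; BBH ties to the lower
  partner index; cluster labels numbered by first member; consensus ties
  by length, degeneracy, lexicographic order.
* Sequence-scale simulations in the test-suite use the full 45,228 bp
  genome for nick recovery (20 seeds) and Monte-Carlo motif counts
  (200 genomes), and 20-genome families with 8 proteins of 100 aa for
  clustering recovery (10 seeds) — sizes at which every property check
  completes in a couple of minutes on a single core while keeping
  standard errors small relative to the tested contrasts.
* Detection applies thresholds to integer depths; no smoothing is used
  for calling (the rolling-mean depth table is for visualisation only),
  so calls are invariant to uniform depth scaling.

## Known limitations

* The coverage-drop signature cannot distinguish a nick from any other
  strand-specific termination signal (e.g. tightly bound covalent
  adducts); orthogonal evidence is needed for chemistry.
* The exact broken base within the motif is not resolved.
* Origin-spanning motif occurrences are invisible on a linear scan, and
  reorientation drops hits that would span the rotation junction — both
  negligible for interior motifs but worth remembering for true circular
  genomes.
* wGRR at desk scale is O(n²) global alignments; for collections much
  beyond ~100 genomes × ~100 proteins, precomputed hit tables are the
  intended route.
* The BBH identity threshold makes wGRR exactly 0 between unrelated
  proteomes, so very distant relationships are compressed to zero rather
  than measured.
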