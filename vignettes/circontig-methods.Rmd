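---
title: "Detecting complete circular DNA elements in assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting complete circular DNA elements in assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circontig)
```

## The detection model

A circular molecule has no ends, but every assembler emits linear contigs.
circontig calls circularity *after* assembly from two independent
signatures, each matched to a sequencing geometry.

### Terminal redundancy (paired-end pipeline)

Mobilome preparations are usually multiple-displacement amplified (MDA) with
φ29 polymerase. Rolling-circle amplification converts each circle into
linear concatemers, so the assembler, walking around the circle and then
re-entering sequence it has already seen, terminates with a duplication of
the contig's own start — typically tens of nucleotides, up to ≈100 nt. Step
one of the paired-end pipeline finds the largest `k` with

```
prefix(seq, k) == suffix(seq, k),   min_terminal_overlap <= k <= 0.5 * L
```

and trims the suffix copy, leaving exactly one copy of the putative circle.
Three design choices matter:

* **The match is exact.** A gap or misassembly of even a few nucleotides
  inside the duplicated copy makes the comparison fail. This is
  deliberate: it produces false negatives (a known plasmid whose assembly
  has a 1 nt slip will be missed — our conservatism tests assert exactly
  this) but essentially no false positives, which is the right trade-off
  for a discovery pipeline whose positives go on to expensive downstream
  analysis.
* **The largest qualifying `k` wins**, capped at half the contig length so
  the trimmed core cannot degenerate; a duplication longer than one full
  circle copy is not meaningful in an assembly.
* **`min_terminal_overlap` defaults to 40 nt** (inclusive). Shorter exact
  repeats arise too easily by chance at contig ends.

Step two demands direct read evidence across the junction: at least one
pair whose `+`-strand mate lies entirely within the last `pe_end_window`
(500) nt and whose `-`-strand mate lies entirely within the first 500 nt of
the trimmed contig, each aligned over at least `pe_min_mate_aln` (90) nt.
This is the orientation a forward–reverse library produces when the
sequenced fragment wraps the linearization origin. We apply the strictest
reading of the window rule — the entire mate alignment must fit inside the
window — and require each *mate* (not the pair jointly) to reach 90 nt,
since each mate is a full read. Only gapless, unique-best alignments are
counted, whether they come from a SAM file or from the built-in test-scale
mapper. The minimum contig length of 1000 nt keeps the two 500 nt windows
from overlapping.

### Junction-spanning reads (single-end pipeline)

With long single-end reads (~400 nt) no mate orientation exists, so the
junction itself is interrogated. For each contig of length ≥ 2w we build the
window `suffix(w) + prefix(w)` with `w = se_end_window = 100`; its midpoint
is the circular junction. A contig is called circular when one read aligns
across the midpoint with

* ≥ `se_min_span_per_side` (99) nt of coverage on each side,
* no gaps (banded single-diagonal alignment; strand handled by also
  aligning the reverse complement), and
* identity ≥ 98 %, computed as matches / alignment columns × 100.

The "99 nt on both sides" reading is the strictest self-consistent
interpretation of requiring nearly full coverage of both window halves by
*one* read; two reads covering one side each are not accepted, because only
a single molecule spanning the junction demonstrates continuity. A read
must therefore be at least ~200 nt to qualify — 150 nt reads can never
pass, which the tests assert as a geometric impossibility.

Each passing window is screened against a reference replicon database: if
any single reference record contains the 200 nt window twice (either
strand), the call could be driven by a known repetitive element rather than
a true junction. The screen *flags* rather than discards, because it is a
global sanity check, not a per-element filter.

### Deduplication by canonical rotation

The same circle found twice is linearized at arbitrary origins and strands.
We identify circles by their **canonical rotation**: the lexicographically
smallest string among all rotations of the sequence and of its reverse
complement, computed with a linear-time least-rotation duel algorithm
validated against an enumerate-all-rotations oracle. Exact canonical
equality is the default clustering criterion. A `near` mode additionally
merges clusters whose lengths differ by ≤ 2 nt and whose rotation-aligned
global identity (one sequence aligned against the doubled other, so the
anchor rotation is found automatically) is ≥ 99.5 % — a single indel from a
homopolymer sequencing slip can otherwise split one real element in two.
Near mode is off by default to keep behaviour auditable. Representatives
default to the single-end copy of a twice-found element (long reads give
cleaner junctions); ties always break to the smallest id so results are
order-invariant. `N` bases participate in canonicalization as the literal
character, complementing to `N`: determinism is worth more here than IUPAC
generality.

### Replicon-domain classification

Plasmids are classified by their replication machinery. From external gene
predictions (only *complete* genes; partial genes at contig edges are
excluded) and a profile-HMM search of the predicted proteins against Pfam,
we keep each gene's best hit at E ≤ `hmm_evalue_cutoff` (1e-4) — smallest
E-value, ties to larger bit score, then accession — and tag an element as
replicon-positive when any best hit falls in a curated table of 14
replication-initiation families (Rep_1, Rep_2, Rep_3, RepL, TrfA, RepA_C,
Rep_trans, RHH_1, Rop, RP-C, RPA, RepA_N, RepC, Replicase). Version
suffixes on Pfam accessions are ignored. "Best hit" is per gene across all
families, not per family, which is what makes the instance arithmetic
meaningful: an element with n replicon genes contributes n domain instances
but one element, so total instances exceed positive-element counts.
Accessory traits (mobilisation, toxin/antitoxin, T4SS, capsid, integrase,
transposase) are tallied from an editable accession table;
the shipped defaults are a documented approximation, so trait counts should
be interpreted qualitatively.

### Virtual inverse PCR

Outward-facing primers located away from the linearization origin amplify
across the junction only if the template is circular (or was circularised
by MDA), so one product of the predicted size confirms both existence and
length: `product = (L − fwd5′) + rev5′ + 1`. The mispriming screen loads
every contig > `vpcr_min_template_len − 1` (200) nt **twice** (`seq+seq`)
— the doubling trick that makes junction-crossing binding sites visible to
a linear search — and accepts primer bindings with at most 1 mismatch AND
1 insertion AND 1 deletion, applied per category simultaneously. Two
numerical details:

* Binding feasibility is decided on **minimum-edit alignments**: a capped
  composition must attain the unconstrained minimum edit distance at that
  site. Without this, an insertion+deletion pair could impersonate a
  second mismatch and admit two-substitution sites that the caps are meant
  to exclude.
* Amplicons are deduplicated modulo the original length, and only products
  ≤ L are kept, so the doubled template reports exactly the amplicon set
  of the circle (verified against explicit rotation enumeration).

The screen passes when exactly one amplicon exists, on the pair's own
element, at the predicted length. No 3′-exactness rule is applied by
default because the edit-tolerance model does not single out the 3′ end;
real oligo selection (melting temperature, hairpins) is delegated to
external primer-design tools, for which we emit candidate regions
(≥ `junction_buffer` = 150 nt away from the origin) in BED.

## The synthetic-data generator

`simulate_metamobilome()` emulates the sequencing experiment the pipelines
target, with defaults chosen as the study conditions: circle lengths
uniform on 1,000–13,000 nt at GC 0.45; terminal duplications uniform on
40–100 nt; 100 nt paired-end reads from 450–550 nt inserts at 20×; ~400 nt
(sd 80, truncated at 50) single-end reads at 10×; substitution errors at
0.001/base, plus rare indels (2e-4/base) on the long reads only —
enough to exercise the identity and gap thresholds without modelling
platform chemistry in detail. Fragments are drawn uniformly on the circle
and wrap the origin, so the expected junction-spanning fraction is
`mean(insert) / L`, which the tests verify within three binomial standard
deviations. MDA copy-number skew can be emulated with a log-uniform
per-circle coverage multiplier (`mda_skew`); it is disabled by default
because uniform coverage is the cleanest regime for round-trip guarantees.

Negative controls are first-class: plain linear contigs, and
"repeat-confounded" contigs carrying two interior copies of a repeat longer
than a read (300 nt vs 100 nt) — the configuration in which de Bruijn
assemblers fail and which a circularity detector must not mistake for a
circle.

What the generator does **not** emulate: chimera formation during MDA,
quality-score structure, homopolymer-biased indels, real genomic repeat
families, and compositional bias beyond a global GC target. Passing
round-trip tests therefore demonstrate the correctness of the detection
logic under the stated geometry, not robustness to every artefact of real
libraries; on real data the conservative exact-match design means errors
surface as false negatives, not false positives.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; conversion to
  1-based happens only in file writers (SAM, GFF ingest are converted on
  the way in). A single convention prevents off-by-one junction errors.
* `find_terminal_overlap` scans candidate `k` downward with a cheap
  first/last-character prefilter; contigs shorter than
  `2 * min_terminal_overlap` are skipped with a logged reason, not an
  error.
* The window aligner scores every candidate diagonal by match count (ties:
  more columns, then smaller window start). At scale, candidate diagonals
  are nominated by exact 24-mer seeds placed every 25 nt across the window;
  with the default 98 % identity requirement a qualifying alignment always
  contains an exact 24-mer, so seeding loses nothing at the operating
  point.
* The internal mapper demands a unique best placement; reads placed equally
  well twice (e.g. inside an unresolved repeat) are discarded rather than
  guessed.
* Empty inputs (no reads mapped, empty reference database, zero-row
  alignment tables) flow through as empty results with complete funnel
  accounting, never as errors; malformed inputs (non-DNA characters,
  duplicate ids, dangling references, mates on different contigs) abort
  with named errors.

## Problem sizes

The shipped test-scale verification uses 200 simulated circles plus 200
linear contigs (~280k read pairs, ~70k long reads) for the round-trip
recovery checks; 1000 planted cases for the terminal-overlap oracle; 500
cases each for the window-aligner and primer-binding oracles; 100 circles ×
3 re-linearizations for dedup invariance; 50 elements for the virtual-PCR
self-consistency screen; and 50/100 contigs for the two negative controls.
These sizes give tight binomial expectations (e.g. ~35 junction-spanning
pairs per circle at 20×) while keeping a full run in minutes on one core.

## Known limitations

* Circles assembled across multiple contigs are out of scope: no scaffold
  joining or gap closing is attempted.
* The exact-match step one misses genuinely circular elements whose
  terminal copies differ by any edit; the published workflow accepted the
  same trade-off.
* The single-end test cannot detect circles shorter than the window
  (< 2w = 200 nt) nor with reads shorter than ~2 × 99 nt.
* Trait tables are approximations; replicon classification inherits
  whatever gene caller and HMM search the user ran upstream.
* `near`-mode dedup is pairwise and intended for handfuls of
  near-duplicates, not for clustering at lower identity (plasmid typing,
  gene-sharing networks).
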