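# circontig

Post-assembly detection of complete circular DNA elements — putative small
plasmids, phage genomes, circular transposon intermediates — among
metagenome/metamobilome contigs.

## The problem

Assemblers only emit linear contigs, even when the underlying molecule is a
circle. In plasmid-enriched (mobilome) sequencing the template is typically
multiple-displacement amplified (MDA) with φ29 polymerase before library
preparation. Rolling-circle amplification of a circle yields linear
concatemers, and the assembled contig of a circle then carries a diagnostic
signature: its first *k* bases are repeated identically at its end (terminal
redundancy, *k* up to ≈100 nt). circontig turns that signature, plus read
evidence across the junction, into circularity calls:

* **Paired-end pipeline** (short reads, e.g. 100 nt PE from 450–550 nt
  inserts): contigs ≥ 1000 nt are screened for identical ends of
  `k ≥ min_terminal_overlap` (default 40 nt); the duplication is trimmed so
  one exact copy of the circle remains; the call is confirmed only if at
  least one read pair maps with junction-spanning orientation — one mate on
  the `+` strand entirely within the last 500 nt, the other on the `-`
  strand within the first 500 nt, each aligned ≥ 90 nt. The end match is
  exact: a misassembly of even a few nucleotides inside the duplicated copy
  fails step one, a deliberately conservative design that trades false
  negatives for essentially zero false positives.
* **Single-end pipeline** (long reads, e.g. ~400 nt): a 200 nt junction
  window (last 100 + first 100 bases) is built per contig; the contig is
  circular if a single read covers ≥ 99 nt on *both* sides of the window
  midpoint, gaplessly, at ≥ 98 % identity. Each window is additionally
  screened against a reference replicon database for internal repeats
  (flagged, not discarded).

Downstream: elements found twice — by both pipelines, or linearized at
different origins/strands — are collapsed via the **canonical rotation**
(the lexicographically minimal string over all rotations of the sequence and
its reverse complement); elements are classified as putative plasmids when a
complete predicted gene carries a **plasmid replication-initiation (Rep)
Pfam domain** (best profile-HMM hit per gene at E ≤ 1e-4, from a curated
14-family table); and an **in-silico inverse PCR** screen verifies that an
outward-facing primer pair would amplify exactly one product of the
predicted length `(L − fwd5′) + rev5′ + 1`, screening for mispriming against
all contigs > 200 nt loaded twice (`seq+seq`) to mimic circularity, with at
most 1 mismatch, 1 insertion and 1 deletion per primer site.

## Worked example

Everything is tibble-in / tibble-out and chains with the pipe. The built-in
generator simulates a metamobilome with known truth:

```r
library(circontig)

sim <- simulate_metamobilome(sim_config(n_circles = 5, n_linear = 5,
                                        sub_rate = 0, seed = 42))
pe <- detect_circular_pe(sim$contigs, reads = sim$pe_reads)
glance(pe)
#>   input length_pass overlap_pass pe_confirmed platform
#> 1    10          10            5            5 paired_end
tidy(pe)[, c("id", "length", "overlap_trimmed", "n_supporting_pairs")]
#>   id         length overlap_trimmed n_supporting_pairs
#> 1 pe_circ001  11800              88                 33
#> 2 pe_circ002   3368              53                 32
#> 3 pe_circ003   6272              70                 34
#> 4 pe_circ004  10289              40                 25
#> 5 pe_circ005   2251              55                 32
```

All 5 planted circles pass both steps (their 40–88 nt terminal duplications
are found and trimmed; 25–34 read pairs span each junction) and none of the
5 linear contigs do. The single-end pipeline on the same circles confirms 4
of 5 (one junction happens to lack a long enough spanning read), and
cross-platform dedup collapses the two views of each circle:

```r
se <- detect_circular_se(sim$se_contigs, reads = sim$se_reads)
els  <- rbind(tidy(pe), tidy(se)[, names(tidy(pe))])
reps <- dedup_elements(els)
reps[, c("id", "length", "source_platform", "cluster_id", "cluster_size")]
#>   id         length source_platform cluster_id cluster_size
#> 1 se_circ004  10289 both            CL001                 2
#> 2 se_circ003   6272 both            CL002                 2
#> 3 se_circ001  11800 both            CL003                 2
#> 4 se_circ005   2251 both            CL004                 2
#> 5 pe_circ002   3368 paired_end      CL005                 1
```

(The default representative policy keeps the single-end copy of a
twice-found element.) Finally, virtual inverse PCR on a representative:

```r
pr  <- design_outward_primers(reps$seq[1], reps$id[1])
scr <- virtual_pcr_screen(pr, data.frame(id = reps$id[1], seq = reps$seq[1]))
scr$pass                      # TRUE
scr$amplicons$product_len     # 340  == predicted (L - fwd5') + rev5' + 1
```

One amplicon, on the element itself, of exactly the predicted 340 nt (two
150 nt junction buffers plus two 20 nt primers): the element behaves as a
discrete circle. `run_pipeline()` chains all stages and writes
FASTA/TSV reports; `plot_funnel()` and `autoplot()` visualise the filtering
cascade and element length distribution. `vignette("circontig-methods")`
documents the model, thresholds and simulation design.

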