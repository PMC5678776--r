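---
title: "Developing chloroplast markers: conserved-sea scanning and RAD-Seq sub-assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing chloroplast markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidmarkers)
```

## The problem

Chloroplast DNA markers for phylogenetic and population-genetic work are
traditionally developed from a short list of "universal" noncoding regions.
But variability hotspots are lineage-specific: the most informative regions
in one genus are often mediocre in another, and highly variable stretches
inside long coding genes (a classic example is *ycf1*) are invisible to a
noncoding-only search. This package implements two complementary
strategies for finding and exploiting the truly variable parts of a
chloroplast genome.

**Strategy 1 (alignment scanning)** starts from a multiple alignment of
three or more complete plastomes. Columns where all compared genomes carry
the identical non-gap residue are *conserved*. A **Con_Island** is a
maximal run of at least `min_island_len` (default 50) consecutive
conserved columns; the regions between adjacent islands are the
**Con_Seas** — the variable material from which primers can be designed,
flanked by conserved primer-annealing ground. Polymorphism of any region
is scored by **PIC** (potentially informative characters): the number of
substitution columns plus the number of indel *events* (each maximal
single-sided gap run counts once) between two genomes. With an ingroup of
three congeneric genomes and one outgroup, the *intrageneric* PIC of a
region is the mean over the three ingroup pairs and the *intergeneric* PIC
the mean over the three ingroup-versus-outgroup pairs.

**Strategy 2 (RAD-Seq sub-assembly)** skips Sanger markers entirely: it
reconstructs chloroplast fragments directly from paired-end RAD-Seq reads.
Read 1 of a RAD pair starts at a restriction cut (EcoRI `G^AATTC`; after
the cut every read 1 begins with the `AATTC` remnant), read 2 comes from
the sheared distal end of the fragment. Per cut site and side, read 1s are
clustered into a **tag-1** consensus; the matching read 2s are assembled
by greedy overlap-layout into a longer **tag-2**. The two tag-1s of one
site fuse positionally across the 4 bp cut remnant into a **paired tag
(pT)**; a tag-1 extending into its tag-2 through a qualifying overlap
gives an **overlap tag (oT)**; when both sides succeed the full span
tag-2/tag-1/tag-1/tag-2 is a **paired-overlap tag (poT)**. Tags of
neighbouring sites whose anchors overlap are chained into gap-free
**CpContigs**, and a reference-ordered scaffold (the **sub-super-marker**)
writes every unassembled position as `-`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_island_len` | 50 columns | minimum conserved run for an island |
| `window`, `step` | 100, 25 bp | sliding-window PIC geometry |
| `max_len` | 700 / 1500 bp | marker-length bound: effective span of one / two Sanger reactions once ~100 bp is reserved for primers |
| `q20_min`, `n_max` | 0.90, 0.05 | per-mate QC: Q20 base fraction and N fraction |
| `min_depth` | 3 reads | minimum read-1 support for a tag (stacks-style) |
| `max_mismatch` | 2 | read-1 distance to its cluster seed |
| `min_overlap`, `min_identity` | 20 bp, 0.95 | any suffix/prefix merge (CAP3-style) |
| `max_mismatch_frac` | 0.05 | cut-anchored read-1 matcher tolerance |

All merges break ties toward the lexicographically smaller sequence, so a
fixed input always yields byte-identical output.

## Design decisions

* **Circular adjacency for islands and seas.** A chloroplast genome is
  circular, so the island/sea partition is computed on the circle by
  default: a conserved run spanning the alignment origin is one island,
  and with two or more islands every non-empty inter-island gap is one
  sea, which is why island and sea counts coincide. Linear topology is
  available for partial alignments.
* **Conservation is strict.** A column where any compared row is gapped is
  not conserved, and `N` mismatches everything — including another `N` —
  both in conservation labeling and in PIC. The `n_matches` toggle relaxes
  the labeling rule if desired. Consequently a single non-conserved column
  between two islands is a legitimate one-bp sea.
* **Indel events at region boundaries** count once in every region they
  intersect: regions and windows are analysed independently, so totals
  across windows can exceed the whole-alignment count; per-region numbers
  stay individually interpretable.
* **Per-100-bp summaries** are by default the unweighted mean of each
  region's `100 * pic / length` (every sea counts equally); a
  length-weighted alternative (`weighted = TRUE` in `mean_pic_per100()`)
  divides total PIC by total length. Both are reported by `run_consea()`.
* **Joining short-island neighbours.** Adjacent seas separated only by a
  short island can be fused into one candidate marker
  (`join_adjacent_seas()`); this is off by default because it changes
  region identities.
* **Haploid tag clustering.** The organelle is effectively haploid, so
  when two sufficiently deep haplotype clusters survive at one cut-site
  side (heteroplasmy, a nuclear insertion of plastid DNA, or an assembly
  artefact), only the deeper cluster is emitted and the tag is flagged.
* **Greedy overlap-layout, not a string graph.** A tag-2 read set is
  tiny, single-locus and haploid; repeated best-overlap merging with
  depth-weighted consensus is adequate and fully auditable.
* **Inverted-repeat accounting.** Tags mapping ambiguously between the two
  inverted repeats cannot be resolved by a read-length anchor; coverage
  ratios can therefore be reported against a reduced reference length
  (`denominator_length`), the convention used when one IR copy is excluded.

## The synthetic-data generator

Real validation data for the full pipeline would require a sequencing
archive; instead the `simulate_*` family generates every input with a
recorded truth set, and all generators are seed-deterministic.

* `simulate_reference()` builds a circular genome (default 30 kb — a
  compact stand-in for a 150 kb plastome that keeps full-pipeline tests in
  seconds) carrying exactly `n_sites` (default 12) EcoRI motifs at
  circular spacing of at least `min_spacing`; chance motifs are removed.
* `mutate_genome()` / `simulate_divergent_genomes()` plant substitutions
  and 1–10 bp indels at given per-site rates. Events are kept away from
  restriction motifs and from each other (`min_separation`, default 12
  bp), and draws that create or destroy a motif are rejected. Because
  events of different genomes are mutually separated, the true alignment
  is known exactly and the pairwise PIC between two genomes equals the sum
  of their planted event counts — the package's strongest exactness check.
* `simulate_alignment()` materialises that true alignment from the edit
  scripts; no aligner is involved.
* `simulate_radseq()` digests in silico: per site and side, fragments
  extend outward from the cut with lengths uniform in `frag_range`, read 1
  covers the cut end, read 2 the distal end on the opposite strand, with
  optional per-base errors (qualities consistent with the error rate) and
  nuclear-decoy contamination. The default fragment window is 120–500 bp:
  a nominal 200–500 bp size selection plus the sub-nominal tail that real
  gel extraction leaves. That tail is deliberate — only fragments shorter
  than read length + overlap threshold let a tag-1 overlap its tag-2, and
  the high overlap-tag rates observed in real RAD libraries show such
  fragments exist; with the simulator's modest per-site depth (default 30)
  the compact window also keeps distal-read tiling dense enough for tag-2
  contigs to stay connected.
* `simulate_cohort()` assembles the standard test design: 2 populations
  × 3 individuals, each population sharing founder substitutions
  (rate 0.003) with private substitutions on top (rate 0.001) — sub-percent
  SNP densities of the kind seen in intraspecific chloroplast comparisons.
  The cohort uses substitution-only divergence so that recovered loci stay
  column-aligned by their reference anchors; indel handling is exercised
  on the alignment path instead.

What the simulator does **not** model: empirical quality-score profiles,
PCR duplicates, adapter read-through, inverted-repeat structure, and
alignment error (the alignment path is exact by construction). Passing
tests therefore demonstrate correctness of the algorithms under clean,
well-separated polymorphism — not robustness to misalignment or to
reference-scale repeat structure.

## Population-genetic statistics

From the per-individual tag sets, `select_conserved_loci()` keeps the loci
recovered in *all* individuals and trims each to the jointly covered
reference interval, giving a gap-free locus matrix aligned by anchor
coordinates (this assumes substitution-level divergence between
conspecific chloroplasts; indel-rich loci would need a realignment step
that is out of scope). On the concatenation:

* nucleotide diversity \(\pi\): mean per-site pairwise difference over all
  sequence pairs, with pairwise deletion of gap/`N` columns;
* Watterson's estimator \(\theta_W = S / (a_n \cdot \text{sites})\) with
  \(a_n = \sum_{i=1}^{n-1} 1/i\), where both \(S\) and the site count use
  the columns free of gaps and `N` — the same columns the segregating-site
  scan considers;
* differentiation: Hudson's \(F_{ST} = 1 - \bar\pi_\text{within} /
  \pi_\text{between}\) by default (it matches the "average nucleotide
  diversity between populations" reading most closely); Nei's \(G_{ST}\)
  is available via `fst_method = "nei"`.

## A small end-to-end run

```{r example, eval = FALSE}
## strategy 1 on a simulated four-genome alignment
sim <- simulate_reference(length = 30000, n_sites = 12, seed = 1)
dg  <- simulate_divergent_genomes(sim$genome, 4, snp_rate = 0.01,
                                  indel_rate = 0.002, seed = 2)
aln <- simulate_alignment(sim$genome, dg$truths)
res <- run_consea(aln, list(ingroup = c("g1", "g2", "g3"), outgroup = "g4"))
str(res$summary)

## strategy 2 on a simulated cohort, then population genetics
coh <- simulate_cohort(seed = 3)
sr  <- run_sacring(coh$individuals, coh$ref)
lm  <- select_conserved_loci(sr$results, coh$populations)
diversity(lm$concat, coh$populations)
```

The test suite runs the same computations at these problem sizes (30 kb
reference, 12 sites, depth 30, 2 × 3 individuals) and checks them against
independent brute-force oracles and the generators' truth sets; the
repository's `scripts/acceptance.R` recomputes the headline quantities
from scratch for any seed.

## Known limitations

* The package consumes alignments; it does not build them. Real plastome
  alignments need an external aligner (and usually manual correction
  around the inverted-repeat boundaries) before `read_alignment()`.
* Anchor-based locus alignment across individuals breaks down when
  conspecific chloroplasts differ by indels inside a locus.
* The cut-anchored extractor is not a general-purpose read mapper: reads
  whose first bases are corrupted beyond `max_mismatch_frac` are lost to
  the pipeline even if the rest of the read is fine.
* With two or more deep haplotype clusters at a site the minor cluster is
  discarded, which silently hides heteroplasmy; the `flagged` column is
  the only trace.
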