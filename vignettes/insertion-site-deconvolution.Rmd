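---
title: "Deconvoluting gene-trap insertion sites from nrLAM-PCR junction reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting gene-trap insertion sites from nrLAM-PCR junction reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A gene-trap transposon screen tags endogenous genes with a promoterless
splice-acceptor reporter cassette (here: the C-terminal half of split
GFP, "VC", used in a split-GFP PARylation biosensor screen in CAL51
cells). Each resistant clone carries the trap in one gene; after
selection of signal-positive cells, the trapped genes are identified by
sequencing the genomic DNA flanking each transposon insertion.

The sequencing chemistry is non-restrictive linear amplification PCR
(nrLAM-PCR): a primer anchored in the transposon's Tol2 end linearly
amplifies into the flanking genome, producing fragments that all share
one fixed end — the integration junction — and vary at the other. Every
original molecule therefore carries a distinct fragment length, while
PCR duplicates repeat a molecule's exact length. This is the basis of
the pipeline's two central devices:

* **unique-length deduplication** — the molecule count of a site is the
  cardinality of its set of flank lengths, per replicate reaction and
  pooled;
* **the pyramidal read stack** — authentic sites show reads stacked on a
  shared junction with per-base coverage non-increasing away from it,
  co-oriented with the host gene's transcription.

`trapscreen` implements the full deconvolution: tag trimming, flank
mapping, cross-sample master blocks, unique-length counting, the filter
ledger, and splice-acceptor reading-frame annotation — together with a
synthetic screen generator so that every stage is testable against
ground truth without external data.

## Pipeline model

1. **Trimming** (`trim_tag`). Reads must begin with the 23-nt Tol2
   junction tag `TTTGAGTACTTTTTACACCTCTG`, matched with at most 2
   substitutions (no indels; the Hamming contract keeps the operation
   exactly testable). The remainder is the genomic flank; flanks under
   25 nt are rejected as unalignable. A second exact tag occurrence
   inside the flank (transposon concatemer) truncates the flank there.
   The nrLAM primer carries two additional 5' bases (`GA`) ahead of this
   tag; whether they appear in reads depends on the library chemistry,
   so the tag is a parameter.

2. **Mapping** (`map_flank`). The built-in mapper is exact-seed (first
   20 nt of the flank) plus full-length Hamming extension with at most 2
   mismatches, on both strands. The best placement must be unique;
   ties are rejected as multimapped. The junction coordinate is the
   tag-adjacent flank end: interval start on `+`, last interval base on
   `-`. This mapper is intended for desk-scale references where it is
   provably equivalent to a brute-force scan (the test suite checks
   equivalence on 1000 random flanks); genome-scale data should be
   aligned externally (e.g. bwa) and imported via `import_alignments`
   (BED6 or SAM, primary mapped records only), which recomputes
   junctions from the same convention and uses the aligned reference
   span as the fragment length.

3. **Master blocks** (`build_master_blocks`). Alignments from *all*
   samples — both arms, all replicates — are pooled and single-linkage
   merged wherever intervals overlap (bookended intervals stay
   separate). Each maximal merged interval is a master block: the unit
   at which a candidate integration site is counted and compared
   between arms. Blocks are deterministic, ordered by (chromosome,
   start).

4. **Site calls** (`call_sites`). Per block and arm: the junction is
   the modal junction coordinate (ties toward the smaller coordinate),
   the strand the majority strand, and the counts come from
   unique-length deduplication per replicate (`A`, `B`, `C`) and pooled
   over replicates. `median_read_sample` is the median of the three
   replicate counts. `stack_ok` requires at least `min_stack = 3`
   distinct lengths sharing the modal junction within
   `junction_tolerance = ±2` bp, and non-increasing coverage away from
   the junction. Replicate concordance is reported as pairwise Spearman
   rank correlations of per-site counts.

5. **Filter ledger** (`apply_filter_ledger`). In reporting order:
   * *minimum unique reads* — sites with fewer than 3 pooled
     unique-length reads are discarded (boundary inclusive: 3 is kept);
   * *orientation / read stack* — sites failing `stack_ok`, and genic
     sites whose strand opposes the host gene's transcription, are
     discarded;
   * *control subtraction* — an experimental site is discarded when the
     same master block carries ≥ 1 pooled unique-length read in the
     negative-control arm (the control screen used a PAR-binding-dead
     sensor, so its sites are selection-independent false positives);
   * *genic / fusion viability* — sites outside known genes, inside
     exons, in 5' UTR introns, or otherwise unable to produce an
     in-frame reporter fusion are discarded.

   The four filters are independent predicates, so the survivor set is
   order-independent; only the per-filter discard trace depends on the
   order. Sites with pooled counts strictly above 30 are additionally
   tiered "high-depth". This tier is descriptive by default and not a
   discard rule, because the screen's discard ledger never names it as
   one even though its narrative applies the later filters to the
   high-depth stratum; `filter_ledger(hard_depth_filter = TRUE)`
   reproduces the narrative path.

6. **Hit table** (`aggregate_hits`). One record per surviving site with
   1-based positions, host gene, truncation length and protein length.
   Genes recovered through two or more distinct master blocks are
   tiered `high_confidence` (independent integration events in
   different cells). Distinct master blocks are also the operational
   definition of "independent" sites: no minimum junction separation
   beyond non-overlap is imposed.

## Reading-frame and truncation model

The trap cassette carries a splice acceptor followed 15 bp later by an
HA tag that lacks its own ATG, and exists in three variants with 0, 1
or 2 C bases padding the frame in front of the HA sequence. For an
insertion in intron *i* of a transcript, let `upstream_cds_nt` be the
coding nucleotides in exons 1..*i*. The intron phase is
`upstream_cds_nt mod 3`, and the variant complementing it is
`(3 − phase) mod 3`; exactly one variant per phase-defined intron
restores the reading frame across the splice.

A fusion is called viable only when the insertion is intronic, at least
one complete upstream codon exists (`upstream_cds_nt ≥ 3`), and the
cassette is co-directional with transcription. The retained N-terminal
fragment is `floor(upstream_cds_nt / 3)` residues: when the phase is
nonzero, the codon interrupted by the splice junction is completed by
cassette bases and encodes a chimeric residue, which we conservatively
do not count. (Published per-site tables of this screen round the
corresponding column inconsistently with their own running text — e.g.
one trapped gene is described as retaining residues 1–511 of 600 while
the table prints other values — so the convention cannot be recovered
from them; the floor rule is fixed and documented here instead.) The
test suite verifies the rule against an independent oracle that
explicitly concatenates the upstream coding exons, the cassette padding
and a reporter frame, translates the construct codon by codon, and
checks both the retained native prefix and that the reporter tag lands
in frame for exactly the matching variant.

Two further conventions: protein lengths exclude the stop codon
(`protein_length_aa = CDS/3 − 1`); and for genes with several
transcripts the fusion transcript is the one with the longest complete
CDS, overridable by transcript id. Transcripts whose CDS length is not
a multiple of 3 are flagged incomplete and excluded from fusion
prediction.

## What the generator emulates — and what it does not

`sim_config()` defaults define the reference conditions used by the
tests and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| genome | chr1 100 kb, chr2 50 kb | smallest size at which mapping is unambiguous and fast |
| genes | 12 multi-exon genes (4–8 exons, 150–450 aa), both strands | enough intron space for all planted events |
| true traps | 30 intronic, co-oriented, frame-matched | screen-like gene-level multiplicity |
| decoys | 5 anti-oriented, 5 intergenic | exercise the orientation and genic filters |
| control-shared sites | 10, present in both arms | exercise control subtraction |
| molecules per site | uniform 3–60 distinct flank lengths | produces a long-tailed depth distribution |
| flank length | geometric, mean 120 nt, range 25–250 nt | nrLAM-like length decay; 25 nt floor keeps flanks mappable |
| PCR duplication | mean 5× per molecule | duplicates repeat exact lengths |
| base errors | 0.005/nt substitutions | Ion-Torrent-scale error burden on the filters |
| replicates | A/B/C, each keeping 80% of molecules | triplicate reactions with realistic concordance |
| 3' bias | intron weight ∝ (index/n)² | selection against nonsense-mediated decay favours last introns |

Event junctions are kept mutually separated by more than twice the
maximum flank length so that each planted event maps to its own master
block; the simulator emulates the NMD-driven 3' insertion bias through
the intron weighting rather than mechanistically. Read layout follows
the convention that the nrLAM primer exits across one fixed Tol2 end,
so a productive trap yields flank reads on the host gene's strand
(`orientation_mode` in the ledger flips this for the mirrored
chemistry). Quality strings are constant; indel errors, selection
dynamics, clone growth, FACS efficiency and capture chemistry are out
of scope — the downstream filters operate on mapped coordinates and
fragment lengths only, which is what the generator reproduces.
Consequently, passing tests demonstrate the correctness of the
deconvolution logic under the stated read model, not robustness to
genome-scale repeat structure or Ion Torrent homopolymer indels; for
real data the mapping step should be delegated to a production aligner.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open; GTF input is converted on
  read and all reports print 1-based positions.
* Junction ties (two equally frequent junction coordinates in a block)
  resolve to the smaller coordinate; strand conflicts resolve to the
  majority with the minority fraction reported.
* An 8-bp target-site duplication of Tol2 is ignored for coordinates;
  the junction base is the first genomic base of the trimmed flank.
* Sites in genes overlapping on opposite strands are assigned to the
  gene whose strand matches the read orientation; antisense-only
  overlap counts as non-genic for fusion purposes.
* The "fewer than three unique reads" threshold is applied to the
  pooled count (union of replicate length sets); `median_read_sample`
  is the median over the three replicate reactions. Both
  interpretations are configurable but these are the defaults.
* Empty inputs (empty FASTA/GTF/FASTQ/BED, zero events) propagate to
  empty outputs rather than errors; a missing control arm skips
  subtraction with a prominent warning.
* All randomness in the generator derives from a single integer seed;
  structural draws (molecule counts, lengths, replicate subsampling)
  are consumed in a separate RNG pass from amplification/error draws,
  which makes unique-length counts provably invariant under the PCR
  duplication factor.

## Problem sizes in the test suite

The suite simulates complete screens at the default configuration
(≈20,000 reads per screen) across several seeds for end-to-end recovery
and concordance properties, checks the mapper against a brute-force
scan on 1000 random flanks over the 150 kb toy genome, the master
blocks against a pairwise overlap-closure oracle on 1000 random
intervals, and the truncation rule against fusion-construct translation
for all 40 viable planted insertions of a screen. The replicate
concordance property is computed from truth-assigned alignments
(generator → dedup → Spearman), since it concerns the subsampling and
deduplication structure rather than the mapper.

## Known limitations

* The built-in mapper requires an exact 20-nt seed; reads with an error
  in the seed region are dropped rather than rescued, which costs about
  10% of reads at the default error rate and is the main reason counts
  sit slightly below the planted molecule numbers.
* Fragment "length" for imported real alignments is the aligned
  reference span (soft clips excluded), which differs from read length
  in the presence of indels.
* Abundance normalisation between libraries, enrichment statistics
  across screens, and saturation estimation are out of scope; the
  screen this mirrors was explicitly under-saturating.
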