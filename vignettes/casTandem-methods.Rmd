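---
title: "Methods: dual-nuclease target design and amplicon-based editing analysis"
author: "casTandem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-nuclease target design and amplicon-based editing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casTandem)
```

# The problem

Cas9 and Cas12a recognize different protospacer-adjacent motifs (PAMs):
Cas9 needs a 3′ NGG next to a 20-nt protospacer and cuts bluntly three
nucleotides from the PAM; Cas12a needs a 5′ TTTV next to a (here) 23-nt
protospacer and makes a staggered cut distal from its PAM. Comparing
the two nucleases fairly requires loci where both can be programmed
against the *same* genomic sequence, so that chromatin context, GC
content, and flanking sequence are held constant. casTandem implements
the complete desk-side analysis for such a comparison: finding shared
(overlapping) target sites in coding sequences, enumerating candidate
off-target sites, quantifying editing outcomes from paired-end amplicon
sequencing, computing the downstream mutation statistics, designing
Golden-Gate spacer oligos, and simulating all inputs with known ground
truth.

# Overlap geometry

The only built-in geometry is the same-strand nested layout

```
5'-TTTV  N1 ... N20  NGG-3'
   |PAM12a| Cas9 spacer |PAM9|
   |  Cas12a spacer (23 nt)  |
```

A 27-nt locus provides a complete Cas12a site (TTTV + 23 nt) and a
complete Cas9 site (20 nt + NGG) on the same strand: the Cas9 PAM
supplies Cas12a spacer positions 21–23. With 23/20-nt spacers this is
the only layout in which both spacers share one locus, which is why it
is the default and only geometry; `overlap_pattern_spec()` leaves the
PAMs and lengths configurable but rejects inconsistent combinations
rather than silently admitting other geometries.

Scanning advances one position at a time, so mutually overlapping
matches are all reported. `N` in the genome matches nothing — not even
the `N` slots of a PAM — so masked sequence can never produce a site.
Site discovery is restricted to the CDS intervals of a user-supplied
gene list, and a site is only reported when its full 27-nt locus lies
inside a single CDS interval.

# Off-target search

`enumerate_offtargets()` is a Cas-OFFinder-style brute-force scan: every
window adjacent to an exact IUPAC PAM match, of length equal to the
spacer or one more/less, is compared against the spacer. Up to three
mismatches are allowed (PAM excluded from mismatch counting), plus at
most one single-nucleotide bulge: a DNA bulge is an extra genomic base,
an RNA bulge an unpaired guide base. For length-mismatched windows the
single best gap placement is chosen — minimal mismatches, ties broken
toward the most PAM-proximal gap — so results are deterministic and
testable against an exhaustive gap-enumeration oracle. Positions are
numbered with 1 at the PAM-proximal end for both enzymes, so the
Cas12a seed region is positions 1–14 under the same convention as the
Cas9 seed.

Two consequences of this enumeration style are worth knowing:

* every exact locus also appears as "satellite" bulge variants (its
  L±1 windows are valid 0-mismatch bulge hits); consumers that want
  one row per locus should group by position;
* brute force *is* the contract here — the package trades speed for
  exact oracle equivalence and does not build a genome index. Scans are
  intended for desk-scale genomes (up to ~100 kb comfortably).

`select_balanced_offtargets()` operationalizes "spread the mismatches
as evenly as possible over the spacer" as greedy maximum coverage of
distinct mismatch positions (ties: fewer mismatches, then genomic
order), capped at four sites per target. This is one deterministic
reading of what is otherwise a judgment call; it is not claimed to
reproduce any manual selection.

# The amplicon caller

The caller is a deliberately minimal re-implementation of the role an
amplicon-sequencing mutation caller (e.g. AmpliCan) plays in such
studies; it quantifies edited-read fractions and event tables and
nothing more (no HDR scoring, no base-editing statistics).

1. **Merging.** Read 2 is reverse-complemented and the best suffix–
   prefix overlap with read 1 is taken (minimum 20 nt, mismatch
   fraction ≤ 0.1; lowest mismatch fraction wins, ties to the longest
   overlap). Disagreements resolve toward the higher base quality,
   ties toward read 1. Pairs without an acceptable overlap are counted
   and dropped.
2. **Alignment.** Global Needleman–Wunsch with affine gaps
   (match +2, mismatch −4, gap open −6, gap extend −1; a gap of length
   k costs `open + (k−1)·extend`), implemented in C++ with a
   deterministic traceback (diagonal preferred, then gap in the
   reference row, then gap in the read row). Indel events are
   left-aligned on the reference, VCF-style, so event coordinates are
   reproducible.
3. **Calling.** A read is *edited* iff at least one indel overlaps the
   cut window: Cas9's window is protospacer position 18 (the blunt cut
   site between positions 17/18) ± 5 nt; Cas12a's is positions 18–23
   (the staggered cut region) ± 5 nt, both clipped to the amplicon.
   Deletions overlap by reference span, insertions by anchor position.
   Substitutions never mark a read edited — isolated base changes are
   treated as PCR/sequencing noise. Reads whose alignment identity
   (matches over all alignment columns, gaps included) falls below 60%
   are discarded; the all-column denominator matters because random
   sequence aligns "gappily" and would pass a non-gap identity filter.
4. **Quantification.** `mutation_frequency = 100 · edited / (edited +
   unedited)`; discarded reads never enter the denominator. Events are
   aggregated with read counts and percent frequencies.
5. **Control masking.** Any event whose frequency in a mock-transfected
   control reaches 0.5% is masked from the treated sample, and read
   status is re-evaluated without it. A control with fewer than 50
   usable reads, or whose per-position majority consensus disagrees
   with the reference, flags the amplicon as having no reliable
   control; adjudication must then disregard the site. Both thresholds
   are exposed as arguments.

# Downstream statistics

* `size_spectrum()` bins each mutated read once by its net indel
  (insertions positive, deletions negative; sizes beyond ±bounds pool
  into the boundary bins).
* `frameshift_summary()` reports the fraction of mutated reads whose
  net indel is not a multiple of three, and the sub-fraction explained
  by a single 1-bp insertion. "Fraction of mutations" is read as
  fraction of mutated reads, the read-level quantity the caller
  tabulates.
* `adjudicate_offtarget()` calls a site genuine iff (a) its
  control-normalized frequency is ≥ 0.1% — an exact step: 0.1 passes,
  0.099 does not — (b) a reliable control exists, and (c) the variant
  pattern is indel-dominated: among usable reads with any variant in
  the cut window, at least half carry an indel. The 0.5 dominance
  threshold operationalizes what is otherwise a visual inspection of
  mutation patterns; it is exposed as an argument.
* `relative_offtarget_frequency()` is the plain quotient off/on,
  undefined (NA, never 0) when the on-target frequency is zero.
* `per_target_comparison()` gives per-target means, SDs (absent, not
  zero, for single replicates) and replicate counts per nuclease plus
  the difference of means. Hypothesis testing is intentionally left to
  standard tools; the table carries everything they need.

# Golden-Gate oligo design

`design_oligos()` builds the forward oligo as `fwd_overhang + spacer`
and the reverse oligo as `rev_overhang + revcomp(spacer)`; annealing
leaves 4-nt 5′ single-stranded ends equal to the overhangs.
`validate_spacer()` rejects wrong lengths and internal recognition
sites of the cloning enzyme (BsaI GGTCTC(1/5) or BsmBI CGTCTC(1/5),
both strands) and warns on T≥4 homopolymers, which act as PolIII
terminators. `simulate_ligation()` digests a backbone in silico — the
two recognition sites must point outward from the stuffer so they are
excised with it — checks that the vector overhangs are distinct and
complementary to the oligo overhangs, and returns the assembled
sequence, which consequently carries no residual recognition site.
Because real cassette overhangs and direct repeats are
construct-specific, they are always supplied by the user's cassette
catalog; the defaults are labelled placeholders for testing.

# The synthetic-data generator

The generator exists so that every pipeline stage can be validated
against known ground truth at desk scale.

**Genomes.** `simulate_genome()` plants overlap sites inside generated
CDS intervals (one gene per site, random strand) on a random background
at 38% GC — a typical plant-genome composition — and realizes each
off-target configuration by mutating a copy of the corresponding
planted spacer (substitutions at the configured PAM-proximal positions,
optional 1-nt bulge) and placing it intergenically with a concrete PAM.
The background is then *screened*: any accidental overlap-pattern match
inside the scanned CDS, or accidental off-target hit of any planted
spacer, is regenerated until none remain, so the ground-truth tables
are exhaustive by construction. Bulge configurations additionally
require the affected base to differ from its neighbours so the planted
gap placement is unambiguous. Everything is deterministic given the
mandatory seed; identical seeds produce byte-identical files.

**Reads.** `simulate_reads()` produces 2×150 nt paired reads from an
amplicon, with exactly `⌊edit_fraction · n⌋` edited reads — an exact
count, not a binomial draw — so programmed frequencies are recovered
exactly on error-free input. Edited reads draw an outcome class,
event size and a position jitter (default ±2 nt) from an
`editing_profile()`; substitution errors are applied uniformly per
base afterwards. Qualities are a constant high value, optionally
lowered at simulated error positions (the merger's quality arbitration
is tested with constructed cases, not a realistic noise model).

**Profiles.** `preset_profiles()` encodes the two enzymes' published
on-target repair spectra: Cas9-like (insertions 17.4% of mutated
reads, 89% of them 1 bp; deletions 80.5%, truncated-geometric over
1–5 nt) and Cas12a-like (insertions 1.8%; deletions 94.1%,
discrete-triangular over 5–10 nt). Because the insertion and deletion
shares do not sum to 100%, each profile carries the residual mass
(2.1% / 4.1%) as a *mixed* class — one deletion plus a 1-nt insertion
in the same read — so both printed shares are realized simultaneously.
Only the class shares and the 1-bp insertion share are anchored to
published values; the size-distribution shapes and the default edit
fraction of 0.5 (a typical efficient protoplast pool) are this
package's choices.

A geometric subtlety drives the mixed-read design: a deletion and an
insertion at the *same* position are alignment-equivalent to a shorter
deletion plus a substitution, which no parsimony-based caller can
separate. Mixed reads therefore place the 1-nt insertion a few bases
left of the cut and the deletion right of it, with the inserted base
constrained to differ from its left neighbour so left-alignment cannot
move it out of the cut window.

**Amplicons.** `synthetic_amplicon()` rejects candidate references
until (a) every programmed deletion placement still overlaps the cut
window after left-alignment and (b) the region around the cut is free
of homopolymer runs ≥3 and period-2/3 repeats that could let an
insertion migrate out of the window. This screen is what makes the
caller-exactness property exact rather than approximate.

# What passing tests do and do not show

The simulator emulates read geometry, programmed editing outcomes and
uniform substitution error. It does **not** model PCR bias, chimeras,
indel-type sequencing errors, quality-score correlation, or real
genome repeat structure; passing its recovery tests shows the pipeline
is internally correct and calibrated, not that it reproduces any
particular wet-lab dataset. Known limitations:

* ~0.5% of mixed-class reads with large deletions collapse into
  deletion-plus-substitution when flanking context coincidentally
  matches the shifted frame; class shares inherit a corresponding
  small bias (deletion share high by ≲0.2 points at the preset mix).
* The off-target search is brute force; genome-scale inputs are out of
  scope by design.
* The greedy off-target panel selection and the 0.5 indel-dominance
  threshold are stated proxies for procedures that were judgment calls
  in practice.

# Numerical choices

Problem sizes used by the shipped validation suite: 6–8 kb screened
genomes (oracle equivalence and 20-seed closure), 250-read pools over
50 seeds for noise-tolerance checks, and 10,000-read pools per preset
profile for class-share recovery; the acceptance script
(`scripts/acceptance.R`) re-runs the 10,000-read simulations from
scratch at a user-supplied seed. Alignment scores are integers in
disguise (all parameters integral), so score comparisons are exact;
threshold comparisons on percentages use `>=` with a 1e-9 guard so the
0.1% rule behaves as an exact step at the printed precision.
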