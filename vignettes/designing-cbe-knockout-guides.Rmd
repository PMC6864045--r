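---
title: "Designing cytosine-base-editor knockout guides and analyzing multiplex panels"
author: "spliceCBE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing cytosine-base-editor knockout guides and analyzing multiplex panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceCBE)
```

## The problem

Cytosine base editors (CBEs) -- Cas9-nickase/deaminase fusions -- convert
C•G base pairs to T•A within a narrow window of the protospacer without a
double-strand break (DSB). For therapeutic multiplex engineering of primary
T cells (for instance knocking out *TRAC*, *B2M* and *PDCD1* simultaneously
to build allogeneic CAR-T cells), avoiding DSBs matters: simultaneous
nuclease cuts at $k$ loci admit $k(k-1)$ directed translocation junctions,
and those junctions are observed at appreciable frequency with active
nuclease but essentially vanish with base editing.

Two CBE knockout strategies exist:

* **Splice-site disruption.** A canonical intron starts with the donor
  dinucleotide `GT` and ends with the acceptor `AG`. The base paired with
  the invariant `G` on the antisense strand is a cytosine (donor
  `GT:CA`, acceptor `AG:TC`); converting that single *critical C* to any of
  T, A or G destroys the motif. Donor loss is predicted to retain the
  intron and route the transcript into nonsense-mediated decay; acceptor
  loss is predicted to skip the downstream exon.
* **Premature stop (pmSTOP) introduction.** A C-to-T edit can create a stop
  codon from `CAA` (→`TAA`), `CAG` (→`TAG`) or `CGA` (→`TGA`) on the sense
  strand, or from `TGG` by editing the antisense cytosines paired with
  either tryptophan G (→`TAG`/`TGA`/`TAA`).

The splice route has a structural advantage this package makes testable:
because *any* conversion of the critical C (including the editor's
nontarget C→A and C→G products) removes the invariant G, every edited
outcome is knockout-causing. For pmSTOP targets only the C→T product makes
a stop; nontarget edits give missense changes instead.

## Guide discovery

`findSpliceGuides()` extracts, for every canonical splice site of a
transcript model, a sense-strand window of `2*flank + 2` nt centered on the
junction dinucleotide, and matches the pattern N~20~-PAM against the
*antisense* strand of that window. A candidate is emitted when its editing
window (protospacer positions `windowStart`..`windowEnd`, position 1 =
PAM-distal) covers the critical C. `findPmstopGuides()` scans CDS codons
for the four editable codon types, placing sense-strand protospacers over
`CAA`/`CAG`/`CGA` (codon position 1 C in window) and antisense protospacers
over `TGG` (either or both paired Cs in window); the terminal stop codon is
excluded and untranslated sequence is never scanned.

Key parameters, all carried by `baseEditorProfile()` / `runConfig()`:

| parameter | default | meaning |
|---|---|---|
| `pam` | `NGG` | IUPAC PAM, matched 3' of the protospacer on its strand |
| `windowStart`,`windowEnd` | 4, 8 | efficient deamination window of BE3/BE4-class editors, protospacer coordinates |
| `flank` | 30 nt | splice-window half-width; 20 is the minimum that fits any protospacer+PAM whose window can cover the critical C |

Candidates whose protospacer or PAM overlaps an `N` are dropped, and
non-`GT`/`AG` junctions are excluded from design unless
`includeNoncanonical = TRUE`.

## Scoring

The original splice-design tooling describes its ranking only as "position
of the target motif within the editing window" plus "position within the
transcript"; the arithmetic here is this package's own concretization, and
the weights are exposed rather than fixed:

$$\mathrm{window} = \max\!\left(0,\; 1 - \frac{|p - p_{mid}|}{w_{span}}\right),
\qquad
\mathrm{transcript} = 1 - d/L,$$

with $p$ the critical protospacer position (mean if several), $p_{mid}$ the
window midpoint (6 for window 4--8), $w_{span} = \mathrm{windowEnd} -
\mathrm{windowStart}$ (4 for window 4--8), $d$ the 0-based spliced-transcript
offset of the targeted junction or codon, and $L$ the spliced length. The
combined score defaults to $0.7\,\mathrm{window} + 0.3\,\mathrm{transcript}$,
clamped to $[0,1]$. Targeting earlier in the transcript is rewarded because
upstream disruption truncates more of the product. Ties in `rankGuides()`
break by higher window score, then smaller transcript offset, then
lexicographic protospacer -- the ordering is a pure function of the
candidate set.

A worked example on the bundled toy locus:

```{r toy}
toy <- toyDonorLocus()
g <- scoreGuides(findSpliceGuides(toy$tm, toy$genome), toy$tm)
mcols(g)[, c("protospacer", "pam", "critical_pos",
             "window_score", "transcript_score", "combined_score")]
```

## Outcome enumeration and classification

Editors do not produce strict C→T edits, so for a candidate with $m$ window
cytosines `enumerateOutcomes()` generates all $4^m$ joint assignments of
{unchanged, T, A, G} (an error above $m = 8$ guards the combinatorial
blow-up). `classifyOutcomes()` reconstructs the sense-strand sequence and
calls the consequence:

* splice classes: site lost iff the junction no longer reads `GT`/`AG`;
  the prediction is categorical -- no splice-strength model (e.g. maximum
  entropy scoring) is applied, because losing the invariant dinucleotide is
  treated as loss of the site;
* pmSTOP class: every CDS codon touched by an edit is translated; a new
  stop is `pmstop` (truncation), an amino-acid change `missense`, a
  synonymous change `silent`. Edits falling outside the CDS change no
  protein.

Acceptor candidates into the terminal exon or a noncoding exon are *kept
but flagged* (`noncoding_or_terminal_exon`): efficient editing of such a
site need not reduce protein, so the flag marks knockout as unassured
rather than silently dropping the design. Skipped exons whose length is a
multiple of 3 add `in_frame_skip`, since an in-frame deletion may leave a
functional protein. Outcomes produced purely by nontarget chemistry carry
`nontarget_only`. Insertion/deletion byproducts are not enumerated: they
are an empirical low-rate side channel of nickase editors, not a modeled
conversion, and enter only through assay tables.

`summarizeCandidate()` reports, over the outcomes in which a critical
position is edited at all, the fractions classified knockout-causing,
missense and silent -- 1.0 knockout for every splice-class candidate, 1/3
stop for a single-C `CAA` target.

Outcomes are enumerated *unweighted*: per-base conversion proportions are
measured quantities that vary by editor and locus, so probability weighting
is left to the simulation layer rather than baked into predictions.

## Multiplex panel mathematics

`enumerateTranslocations()` counts each directed junction separately
(partner A joined to partner B is a different molecule -- and a different
ddPCR assay -- than B joined to A), giving $k(k-1)$ outcomes: 12 for the
four-site panel of three targets plus one off-target site, 90 for a
ten-locus strategy. Inversions and large deletions are deliberately out of
scope of this count.

`koCombinationFractions()` decomposes per-cell boolean knockout calls
(pre-gated flow phenotypes) into the $2^g$ combination categories and the
grouped fractions by number of genes lost;
`expectedCombinationFractions()` provides the independence benchmark
$\prod_i p_i^{x_i}(1-p_i)^{1-x_i}$ against which an observed composition
can be compared.

## Assay quantification

**ddPCR.** Droplet occupancy is Poisson, so a channel with $k$ of $n$
droplets positive has concentration $\lambda = -\ln(1-k/n)$ copies/droplet.
With a duplexed internal reference (HEX) present at two copies per diploid
genome, the junction frequency is reported as
$100 \cdot 2\lambda_{FAM}/\lambda_{HEX}$ percent. The source material names
only "fractional abundance adjusted for two-copies of reference"; the
factor-of-two placement is therefore config-exposed, with the
QuantaSoft-style alternative
$100 \cdot 2\lambda_{FAM}/(\lambda_{FAM}+\lambda_{HEX})$ selectable
(`variant = "fractional_abundance"`). A reference channel with zero or
saturated counts is an error, not a number. The assay's practical
detection limit (0.01% in the motivating experiments) is a reporting
threshold parameter, never a hard-coded truth.

**PD-1 flow normalization.** Stimulation does not uniformly upregulate
PD-1, so observed fractions are rescaled with the control-sample ratio
$r_{PD1}$ of PD-1^+^ to PD-1^-^ subpopulations:
$F'_{pos} = F^\circ_{pos} + F^\circ_{pos}(1 - r_{PD1})$ and
$F'_{neg} = F^\circ_{neg} - F^\circ_{pos}(1 - r_{PD1})$. The implementation
computes $F'_{neg}$ as (total $-$ $F'_{pos}$) so the conservation identity
holds to the last bit; results outside $[0,100]$ warn and are clamped only
on request.

**RNA off-target ranking.** Candidate transcripts for sgRNA-independent
RNA editing follow-up are scored by percent-maximal expression,
$(R^i_{CD4} \cdot R^i_{CD8}) / \max_j (R^j_{CD4} \cdot R^j_{CD8})$, the
maximum taken over the per-gene products (a per-compartment-maxima variant
was considered and rejected as the less direct reading), filtered to genes
with previously observed editing, ties broken by gene id.

## The synthetic-locus generator

`makeSyntheticLocus()` is first-class, tested code, not a throwaway
fixture. From a seed it draws exon/intron lengths, writes canonical
`GT`..`AG` introns, builds an `ATG`..stop CDS from codons that exclude the
four editable types and stops, and plants requested guide targets with
window-compatible PAM anchors (critical C at window position 6, the
midpoint). Because random spacer sequence could create extra PAM contexts,
the locus is then *repaired to a fixpoint*: the finders are re-run and each
unplanned candidate has one free PAM base rewritten (choices that would
create a new `CC`/`GG` dinucleotide, a forbidden codon, or touch planted
bases are rejected; for pmSTOP candidates the target codon itself is the
fallback). The result is a locus whose designable guide set *equals* the
planted truth table, which makes generator/analyzer closure a testable
property. Repair failure raises an explicit "infeasible spec" error rather
than emitting a locus with an inexact truth table.

What the generator emulates: canonical splice geometry, codon structure,
strand symmetry (a minus-strand rendering reverse-complements the contig
and flips the annotation, leaving designable protospacers identical), `N`
runs, and GTF/GFF3/FASTA round-trips. What it does not emulate: real human
sequence composition (GC content, repeats), alternative isoforms,
chromatin or editing-efficiency heterogeneity, and indel byproducts.
Passing tests on these loci therefore demonstrate the *combinatorial and
geometric* correctness of the design logic, not wet-lab editing rates.

`simulateKoCalls()` and `simulateDdpcr()` draw from exactly the generative
models the analysis functions invert (independent Bernoulli knockout;
binomial droplet occupancy at $1 - e^{-\lambda}$), so estimator-recovery
tests are calibrated end to end. All simulation seeds run through a fixed
Mersenne-Twister configuration for cross-machine reproducibility.

## Numerical and design choices

* **Coordinates.** In-memory containers are `GRanges`/`IRanges` (1-based
  inclusive, the Bioconductor convention). All exported TSV/BED tables use
  0-based half-open `start0`/`end0` columns; GTF and GFF3 follow their own
  1-based standards. Conversions happen only at I/O boundaries.
* **Transcript addressing.** Overlapping transcripts are processed
  independently per transcript id; no gene-level merging.
* **Degenerate inputs.** Single-exon transcripts yield no splice sites
  (empty result, not an error); a transcript without CDS or with a frame
  not divisible by 3 is an error for pmSTOP design; splice windows
  truncated by a contig end raise an error naming the site; a candidate
  with zero window Cs enumerates to the single unchanged outcome and
  summarizes to an explicit empty record with a warning.
* **Determinism.** Identical seeds and configurations produce
  byte-identical FASTA/GTF/GFF3/TSV/BED outputs; writers emit LF
  line endings through binary connections to keep this platform-stable.
* **Problem sizes.** The shipped test suite checks finder/oracle
  set-equality on 100 seeded loci (~0.8 kb each, both strands, mixed
  plantings), outcome-completeness on 10 loci, ddPCR estimator recovery on
  100 simulation seeds at truths between 0.01% and 2% with 20,000 droplets,
  and composition recovery on 100,000 simulated cells. These sizes give
  binomial/Poisson standard errors comfortably below the asserted 3-sigma
  bands while keeping the full suite around two minutes.

## Limitations

Consequence prediction is rule-based at the annotated junction or codon:
no splice-strength rescoring, no NMD-escape modeling, no readthrough
penalty for pmSTOP targets (stop-codon readthrough is a documented concern
and is surfaced as class metadata only). Off-target search, editor
chemistry variants beyond a parameterized PAM/window, and translocation
*frequency* prediction from DSB rates are out of scope; only the outcome
*combinatorics* and the measurement math are implemented.
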