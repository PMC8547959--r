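---
title: "Detecting endogenous virophages and Ngaro retrotransposons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting endogenous virophages and Ngaro retrotransposons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emalescan)
```

## The problem

Marine heterotrophic flagellates such as *Cafeteria burkhardae* carry dozens
of endogenous mavirus-like elements (EMALEs) — integrated virophage genomes
of 5.5–21.5 kb — in nuclear genomes whose background GC content is around
70%, while the elements themselves sit at 30–53% GC. The elements are
flanked by terminal inverted repeats (TIRs, 0.2–2.3 kb) and, being
integrase-generated insertions, by short target site duplications (TSDs,
mostly 1–9 bp). A second layer of mobile DNA — Ngaro retrotransposons of the
DIRS order, ~6 kb, GC-rich, with split direct repeats
A1–[ORF1 ORF2 ORF3]–B1 A2 B2 — preferentially inserts into the virophage
elements themselves.

`emalescan` turns the discovery workflow for this system into a tested,
reusable pipeline: GC-anomaly screening, homology confirmation, precise
delimitation, dot-plot typing, retrotransposon resolution, and nucleotide
bookkeeping — plus a synthetic genome generator whose planted ground truth
makes every stage verifiable at desk scale.

## Detection model

Write $g_i$ for the GC indicator of base $i$. The primary screen slides a
window of $w = 500$ bp at step 100 and computes
$\mathrm{GC}_k = \sum_{i \in W_k} g_i / (w - N_k)$, with ambiguous bases
excluded from numerator and denominator. Candidate segments are maximal runs
of windows at or below $b - \delta$, where $b$ is the genome-wide median
window GC (robust because elements make up only a few percent of the
assembly) and $\delta = 15$ percentage points. Runs are merged across gaps
up to 1 kb, retained from 500 bp (pre-join) and 2 kb (final), and their
edges are refined to the maximum-likelihood binomial changepoint at
single-base resolution:

$$\hat c = \arg\max_c \; n_L H(\hat p_L) + n_R H(\hat p_R), \qquad
H(p) = p\log p + (1-p)\log(1-p),$$

re-centred iteratively when the optimum lands at the search-window edge. The
likelihood form matters: a plain mean-contrast criterion degenerates for
tiny candidate splits.

A GC-rich retrotransposon insertion splits its host element into two low-GC
segments. Adjacent segments are therefore re-joined when the gap between
them is at most 12 kb and its GC lies at least 3 points below the host
baseline — true host gaps sit *at* the baseline and are never joined.

A candidate becomes an element only if it also passes the homology screen:
at least one stop-to-stop ORF (six frames, minimum 50 aa — permissive, as
virophage genes are short and not reliably ATG-anchored) with a local
alignment of at least 50 bits against the reference virophage proteome.
Local protein alignment uses BLOSUM62 (X scored 0) with affine gaps
(open 11, extend 1) and bitscores $(\lambda S - \ln K)/\ln 2$ with the
gapped BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$. The two screens
are deliberately redundant; their intersection is the call set.

## Delimitation

Within 3 kb windows at either end of a candidate (plus 200 bp of outer
slack), the 5' arm is locally aligned against the reverse complement of the
3' arm; a hit of at least 100 bp at 90% identity is a TIR pair and the
element boundaries snap to its outer ends. These thresholds bracket the
observed 0.2–2.3 kb arm range with margin. An element is **complete** when
a TIR pair is present and host DNA flanks it on both sides; otherwise it is
**partial** (an assembly artifact, not biology).

The TSD is the longest $L \le 15$ for which the upstream-flank suffix
equals the downstream-flank prefix exactly; exact matching means every
reported TSD is re-verifiable by string equality, and the cap of 15
(observed TSDs reach only 9 bp) exposes out-of-range anomalies. A 1 bp TSD
is indistinguishable from a chance single-base match; the caller reports
$L$ and leaves significance to the user. On real data an additional ±1 bp
ambiguity arises when the junction bases happen to be reverse-complementary
(the TIR alignment then absorbs one TSD base per side); the synthetic
generator excludes this configuration so that planted truth is unambiguous.

Contig-end partials have no TIR pair. Their inner junction is refined, after
typing, by aligning the assigned type's reference TIR arm across the
junction region — the boundary is the arm's outer end. This mirrors
practice: partial element boundaries are determined from GC content *or*
similarity to already-annotated TIRs, and is why elements of one type share
TIR sequence in the generator.

## Typing

Complete elements are compared all-versus-all with exact word matches of
length 10, forward and reverse-complement. The similarity statistic is the
fraction of the shorter sequence covered by shared words lying on *dense
dot-plot diagonals* (at least 3 matches within a 20 bp diagonal band).
Chaining by diagonal is what makes the statistic a faithful proxy for
visual block patterns: between long sequences of similar skewed base
composition, isolated chance 10-mer collisions alone would cover 30–50% of
an AT-rich sequence, but they scatter across diagonals and are discarded.

Single-linkage clustering at a coverage threshold of 0.30 partitions the
elements into types; the threshold was calibrated once on the bundled
template panel so that the eight types separate while copies diverged up to
~10% merge. Clusters are numbered by ascending median GC (ties by size), so
low-GC types come first, and the longest member of each cluster is the type
species. Elements below 43% GC — the midpoint of the empty interval between
the low-GC group (up to 38.5%) and the mid-GC group (from 47.2%) — are
labeled "low", the rest "mid". Partial elements are typed by cumulative
bitscore: each ORF contributes its single best bitscore against each type's
protein set (best-per-ORF avoids double-counting paralogous hits), scores
are summed per type, and a maximum below 100 is "inconclusive"; exact ties
resolve to the lower type id and are flagged.

## Retrotransposons

Inside elements, insertions are called as windowed-GC runs at least 10
points above the element's own background (its lower-quartile window GC,
robust even when the insertion spans most of a short element), 2–12 kb
long — bracketing the typical ~6 kb. Sub-600 bp dips inside a run are
noise and are bridged; longer gaps merge only if they are themselves
GC-elevated, so element DNA separating two genuinely adjacent insertions is
never bridged. Host-integrated copies have near-host GC and are invisible
to this screen; they are found by exact 12-mer seeding against the bundled
templates (dense seed runs mark a copy).

Candidates are snapped to their split-direct-repeat structure: the 5' arm
(A1) is located by same-strand self-alignment of the prefix window against
the interior (arm ≥ 50 bp at ≥ 90% identity), and the B copies are required
to bracket the located A2 contiguously (≤ 100 bp tolerance), yielding
A1–…–B1A2B2 with exact outer boundaries. A detached A+B pair recognised
against reference arms with no intervening ORFs is a solo repeat, the
analogue of a solo LTR. Types are assigned by word-10 block coverage
against the four templates; the variant is `orf1_truncated` when no ORF
hits the assigned type's ORF1 (Gag-like) protein at 50 bits — this is
robust to the ~2 kb 5' deletions sliding ORF2 into the window an
ORF-position rule would test.

Integration-site preference is tested with a 2×2 table: insertions landing
in intergenic versus genic-or-TIR element DNA against the per-class base
totals from the same annotations, evaluated two-sided by exact
hypergeometric enumeration (all tables with the observed margins whose
probability does not exceed the observed one, with the customary
$1+10^{-7}$ tolerance); a binomial upper tail is reported as a cross-check.
"Genic" counts reference-labeled ORFs plus unlabeled ORFs of at least 150
aa, which keeps spurious short stop-to-stop frames from absorbing the
intergenic class.

## Quantification

Assembly-side fractions are exact bookkeeping over disjoint class ranges;
nested retrotransposon bases count as retrotransposon, not element. The
read-side estimator attributes every aligned base to the class of its
reference position, CIGAR-aware: M/=/X consume both sequences, I consumes
the read and inherits the enclosing reference class, D is not counted;
unmapped, secondary and supplementary records are skipped. Codon usage is
counted over each element's ORFs and summarised as GC3 and per-amino-acid
synonymous fractions; the GC3-versus-element-GC trend is reported as a
Spearman correlation, since the observed shift is monotone rather than
linear. Gene-length comparisons between retrotransposon-carrying and
retrotransposon-free elements use per-label medians, IQRs and a Wilcoxon
rank-sum statistic.

## The synthetic generator

The generator is first-class, tested code, and its defaults are the
validation conditions: five 1 Mb contigs at 70% GC; 15 elements covering
all eight types (GC 31–53%, TIRs 0.2–2.3 kb, TSDs 1–9 bp, three truncated
at contig ends, kept fraction 0.55–0.75 so at least one intact gene
survives); six Ngaro insertions (all four types, two ORF1-truncated in host
DNA, four full-length inside elements, at least 500 bp from element ends);
2% per-base substitution on planted copies (TIR arms stay identical within
an instance, as real arms nearly do); top-level features at least 20 kb
apart; and 10,000 error-free 8 kb reads.

The element templates are synthetic gene mosaics, not copies of any real
virophage: a shared core proteome (primase/helicase, rve-integrase, pPolB,
MV14, ATPase, PRO, PEN, MCP, tyrosine recombinase, accessory genes) is
diverged ~35% per type at the protein level and reverse-translated with
GC-steered synonymous codon choice (third-position GC compensates the
~0.47 GC pinned at codon positions 1–2 by amino-acid composition). The 35%
divergence is what lets types separate at the nucleotide word level even
under the nearly deterministic AT-rich codon choice of low-GC genomes,
while protein homology to the shared reference set stays strong. Low-GC
types 1–4 carry pPolB and a 5'-proximal integrase; mid-GC types 5–8 carry
a tyrosine recombinase and a 3'-proximal integrase; MV14 always immediately
precedes the ATPase and PEN the MCP, with the full morphogenesis order
restricted to types 4–7; type 8 is short and lacks the morphogenesis
module. A hook accepts user-supplied real template sequences.

Reads are sampled with **balanced coverage** by default: systematic start
positions with a random phase per contig, so every base has equal expected
depth — emulating the even genome-wide coverage of an aligned long-read
data set, and making the read-based fraction estimator agree with the
assembly-based one to well under 0.1 percentage points. An i.i.d.
uniform-position mode (`sampling = "uniform"`) exists for binomial sampling
checks; under it the estimator's seed-to-seed spread at 10,000 reads is
~0.12 percentage points. Reads are error-free by default; an optional
substitution rate adds mismatches without indels, which is sufficient for
coverage accounting.

What the generator does *not* emulate — and hence what green tests do not
demonstrate about real data: host repeat families and low-complexity DNA
(the i.i.d. background makes detection scoring unambiguous but is easier
than real flanking context), heterozygous or allelic insertions and the
assembly collapse they cause, realistic long-read error models (chimeras,
homopolymer indels), biological truncation with TIR regeneration, and
sequencing bias against AT-rich DNA.

## Numerical choices and degenerate inputs

Coordinates are 1-based closed throughout, the native convention of every
container the package is built on (IRanges/GRanges, Biostrings, GFF3);
conversion happens only at external interfaces that demand otherwise.
All randomness is consumed through per-stage seeds derived from the
configuration seed, so identical configurations give byte-identical
artifacts; the bundled templates come from fixed internal seeds and are
cached per session. Empty inputs degrade gracefully (empty profiles,
empty call sets, host-fraction-one reports); candidates shorter than twice
the minimum TIR arm are returned without TIR and a warning; flanks shorter
than the TSD cap bound the search and are flagged. Tie-breaks are
deterministic: lower type id on cumulative-bitscore ties, first-in-order
on equal cluster sizes, smallest adjustment on equal-likelihood
changepoints (`which.max` on the profile).

## Validation scale

The test suite validates module behaviour on small genomes (hundreds of
kb) and the full pipeline on the default panel across 20 replicate seeds;
`scripts/acceptance.R` re-runs the panel end-to-end (10 replicates by
default) and writes aggregate recall, precision, boundary-error, TSD,
typing, retrotransposon and quantification metrics as JSON. These sizes
keep a complete validation run on a single CPU in the tens of minutes
while exercising every code path, including nested insertions and
contig-end partials.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
sim <- simulate_genome(cfg)
res <- run_pipeline(sim$assembly)
res$summary          # per-type complete/partial counts
res$fractions        # host / element / ngaro nucleotide bookkeeping
head(res$elements)   # delimited elements with TIR, TSD, type, GC group
res$ngaros           # retrotransposon insertions with container and variant
```

## Known limitations

Beyond the generator gaps above: the 0.30 linkage threshold and the
block-coverage statistic stand in for a visual dot-plot reading and have
no published numeric counterpart; elements at host-like GC or without
recognisable protein similarity are invisible to both screens by
construction; cross-strain locus orthology assumes flanks are unique
enough for seed-and-extend matching; and the Fisher table construction
(per-base class sizes as the comparison row) is one defensible choice
among several — the table itself is always reported alongside the p-value.
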