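---
title: "Models and methods behind mtrecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mtrecomb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtrecomb)
```

## The recombination model

A genome is a set of molecules, each an ordered list of oriented
segments. Repeat pairs are modelled at the segment level: both copies of
a pair reference one shared segment, so a pair is "present" wherever that
segment occurs twice across a configuration. This representation makes
the three recombination reactions purely combinatorial:

* **Inversion** (inverted pair, one molecule): the segments strictly
  between the two copies are reversed and strand-flipped. The copies
  themselves are untouched — the crossover happens *within* the aligned
  repeat, so the pair stays inverted while everything the arc contains
  (including one copy of any *other* pair) changes relative orientation.
  That is exactly why, on a circle carrying two inverted pairs in
  alternating order, inverting across either pair renders the *other*
  pair direct.
* **Excision** (direct pair, one circle): the circle resolves into two
  circles, each carrying one copy of the pair.
* **Integration** (pair split across two circles): the inverse of
  excision; the merged circle carries the copies in direct orientation.

Double-stranded DNA circles have no intrinsic orientation or start, so
molecules are compared up to rotation *and* strand flip: the canonical
form is the lexicographically least token string over all rotations of
the layout and of its reversed, orientation-flipped image. This quotient
is what collapses the two excision routes of the alternating two-pair
circle (across the now-direct first pair after inverting the second, or
vice versa) into a single separated state, giving the characteristic
count of three joint configurations plus one separated state.

`enumerate_states()` is a breadth-first closure over all applicable
single moves, storing each state once by canonical key and sorting the
output by key, so the result is independent of move application order.
Simultaneous double crossovers are not modelled; every edge in the state
graph is one recombination event. Linear molecules support inversion but
not excision or integration — circular recombination products are the
documented case, and extending excision to linears would require choices
(which end becomes which) that nothing in the data constrains.

Two practical dials: repeat pairs recombine only at sequence identity
≥ 0.94 by default — short repeat pairs at lower similarity are observed
not to produce recombinants, and pairs can also be disabled individually —
and the closure refuses (rather than truncates) beyond `max_states`
(default 10 000), because a silent partial closure would corrupt every
downstream count.

### Transcriptional context

Promoters (and optional terminators) are explicit annotated features; no
motif prediction is attempted. Within a configuration, gene parts that
abut on the same strand — a repeat-borne 5′ part followed by its 3′
continuation — are merged into one gene copy, wrapping the origin on
circles. A transcription unit is a promoter plus the ordered same-strand
features downstream of it up to the next promoter or terminator (the
scan wraps on circles). A gene copy's context is the promoter whose unit
contains it; on a linear molecule with no upstream promoter the copy is
reported as `no-promoter`, which is a result, not an error.

## The toy genome

`build_toy_genome()` constructs one circular molecule
`[A+, X+, C+, Y+, A−, Z+, C−, W+]`: `A` is a 636-bp repeat derived from
*atp6*, `C` a 491-bp repeat (454 bp of *cob* 5′ coding sequence plus the
37 bp immediately upstream), and `X`, `Y`, `Z`, `W` are unique spacers.
The *cob* promoter sits at the end of `X` abutting `C+`; the *cob* 3′
continuation opens `Y`, so `C+` begins the full gene in the initial
state; the chimeric gene *bobt* and its promoter sit in `W` on the minus
strand pointing into `C−`; the *atp6* continuation closes `Y` on the
minus strand, abutting `A−`. Repeat lengths are the documented values;
spacer lengths are free parameters chosen once (2.2–2.6 kb each) to give
a ~12-kb molecule on which enumeration and digestion are instantaneous.
Spacer sequences are random with GC fraction 0.45, the mid-range of
plant mitochondrial chromosomes.

This geometry reproduces, by construction plus enumeration, three facts
the analysis turns on: 3 joint + 1 separated state; the full *cob* copy
driven by its own promoter in exactly 2 of 3 joint states (and by the
*bobt* promoter on the separated circle, i.e. co-transcription); the
partial *cob* copy downstream of *bobt* in exactly 2 of 3 joint states.

## RNA editing

Editing extent is `T / (C + T)` over reads oriented to the strand of
interest; reads of other bases carry no information about C-to-U editing
and are ignored by the statistic. Ingestion re-orients minus-strand
sites (a genomic G>A on the reference plus strand is C>T on the coding
strand) so all downstream logic sees C→T only. A site is *called* when
the oriented reference is C, extent ≥ 0.10 **and** ≥ 10 edited reads —
both thresholds are inclusive and both must hold. Sites with oriented
C+T depth below 10 are retained but flagged `low_depth` and left out of
summaries. Positions inside rRNA/tRNA annotations are excluded from
calling by default because library preparation (rRNA depletion, small-RNA
loss) biases their coverage. Codon effects are annotated under the
standard genetic code — the code plant mitochondria use — by applying the
C→T change at the site's codon position in the spliced CDS; assembling
the spliced CDS (trans-splicing included) is the caller's
responsibility, and a CDS whose length is not a multiple of 3 is an
error naming the feature.

Context labels follow the precedence CDS > intron > UTR > ORF > island >
intergenic, strand-aware except for islands, which are unstranded.

## Editome comparison

Homologous-site mapping is an input table; the package deliberately
bundles no whole-genome aligner. Each mapped pair of (reference base,
recorded rate) is classified by the first matching rule:

1. `loss_substitution` — one haplotype has genomic T where the other has
   an edited C. The DNA-level change dominates: whatever the RNA shows,
   the site no longer exists as an editable C.
2. `loss_activity` — both references C, one rate ≥ 0.8, the other
   *measured* at ≤ 0.1 % edited reads. Both flavours of loss are exposed
   because a lost edit can disappear by substitution or by silencing of
   the editing activity at a retained C, and the two have different
   evolutionary meaning.
3. `highly_differential` — both rates recorded, the larger > 0.8 and the
   smaller < 0.3, strict inequalities.
4. `new_editing` — called edited in one haplotype, no recorded editing
   (or essentially zero) in the other.
5. Otherwise `conserved_edited`, `conserved_unedited`, or
   `minor_difference`.

A missing rate means the haplotype's editome has no record at that site;
a recorded near-zero rate is evidence of measured silence. The
distinction matters in rule 3 versus rule 4: a site recorded at, say,
0.09 in one haplotype and 0.87 in the other is a *highly differential*
site (both editomes know it), not a new edit — which is why the
highly-differential test precedes the new-editing test and requires
recorded rates rather than called ones. Classification is total: every
mapped row gets exactly one class, and swapping the two haplotypes maps
losses and gains symmetrically while leaving the symmetric classes
fixed (direction is recorded separately).

Loss counts are reported both overall and restricted to intact
protein-coding genes, because a loss inside a chimeric-ORF partial gene
copy is a different biological statement from a loss in a functioning
gene; the packaged twelve-site KRA/KOV table contains one such chimeric
row, and the restricted count is 3.

Rate correlation between haplotypes uses rank correlation as the primary
statistic (editing rates are bounded and heteroscedastic) with linear
correlation reported alongside, over sites where both references are C.

## Coverage, islands, fold changes

TPM is computed per sample as length-normalised rate scaled to one
million; the column-sum invariant is exact by construction and tested.
"Sliding" 100-bp windows are implemented as non-overlapping tiles
(step = window) — a read-count threshold per window is only meaningful
when windows partition the sequence — with an overlapping mode available
via the `step` parameter. The island threshold (12 000 reads per window,
merged across samples) is tied to sequencing depth, so a rescaling
option (`threshold × total_depth / reference_depth`) is provided as
configuration rather than an inferred constant. Windows overlapping
annotated genes/ORFs are masked *before* thresholding, since islands are
by definition intergenic; qualifying windows merge when adjacent, and
names follow `chromosome.start(length)` with a 1-based start, exactly
invertible by `parse_island_name()`.

Unique-region coverage masks positions shared with any annotated repeat
copy before averaging depth, so chimeric features are not credited with
reads from the homologous parts of their donor genes; a fully masked
feature yields a flag, not a number. The gender fold change is the ratio
of arithmetic mean TPM in F over H samples, with a 0.5-TPM pseudo-count
added to both means when the H mean is zero. No differential-expression
test is bundled — with three samples per gender the honest product is
the ratio itself, and hypothesis testing on the qPCR side is out of
scope.

## Synthetic data: what it emulates, and what it does not

The generators emulate the *statistical structure* the methods assume:
binomial sampling of edited reads at known true rates, negative-binomial
counts (variance μ + αμ², α = 0.05 by default) with a planted
female/hermaphrodite effect, and a known true alignment for the
identity metric. The default expression panel plants a 3-fold effect on
a *bobt*-like feature against ~29 background genes spanning two orders
of magnitude, so the planted feature is a small share of the library —
with a tiny panel, TPM's compositional constraint would visibly shrink
the recovered ratio below the planted value. They do not emulate
alignment artefacts, mapping bias, splice-junction discovery, coverage
autocorrelation, or editing-site linkage; passing the recovery tests
therefore shows the estimators are correct on clean draws from the
assumed models, not that the thresholds are optimal for any particular
real library.

Problem sizes used throughout the test-suite and acceptance script —
1 000 simulated sites at depths 50–1 000, 200 fold-change replicates at
3 + 3 samples, 500 random recombination instances, a ~12-kb toy genome —
were chosen as the smallest sizes at which the law-of-large-numbers
margins in the checks are comfortable; all complete in seconds.

## Numerical and convention choices

* Internal coordinates are 0-based half-open; GFF3 on disk is 1-based
  inclusive; report files and island names use 1-based positions.
* Percent identity excludes alignment columns with a gap in either
  sequence from numerator and denominator; `N` occupies a column but
  never matches. Reported identities round half-up to 2 decimals (and
  genome fractions to 1), avoiding banker's rounding surprises at the
  .005 boundary.
* GC content excludes `N` from the denominator.
* Circular digestion linearises at the first cut site; an uncut circle
  returns its full length flagged `uncut` rather than erroring, because
  a probe that fails to cut is an informative outcome.
* Features may wrap the circular origin only where the representation
  makes that explicit (merged gene copies wrap; plain features do not).
* Ties in context classification (overlapping same-precedence features)
  resolve to the first feature by (start, id), with a warning.
* The GFF3 writer emits a fixed field and attribute order so that
  read → write round trips are byte-identical; parsing is delegated to
  `rtracklayer`, FASTA to `Biostrings`.

## Known limitations

Recombination kinetics and configuration stoichiometry are out of scope:
the model enumerates *reachable* states, it does not predict their
frequencies. Repeat copies are treated as interchangeable even when
stored identity is below 1, so gene conversion within repeats is
invisible. Editing comparison requires an externally supplied homology
map and addresses C-to-U editing only (no U-to-C). Island detection
assigns whole windows, so island boundaries are quantised to the window
grid. The pipeline validates inputs eagerly and aborts on the first
failing stage by design; partial results are never written silently.
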