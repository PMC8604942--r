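---
title: "Detecting template switching between inverted-repeat arms in coding genes"
author: "irswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting template switching between inverted-repeat arms in coding genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irswitch)
```

## The problem

A short inverted repeat (IR) is a pair of DNA segments in reverse-complement
orientation -- two *arms* -- separated by a *spacer*. During replication, DNA
polymerase can switch templates between the arms: the nascent strand anneals
to the other arm (on the same molecule via a hairpin, or on the sister
chromatid), copies a stretch, and switches back. One template switch
*homogenizes* the arms, converting an imperfect IR into a perfect one; an
intermolecular switch initiated while the first arm is replicated *inverts
the spacer*, replacing it by its reverse complement. Either way the result is
a multinucleotide mutation (MNM): two or more substitutions appearing at
adjacent sites in a single generation.

In coding DNA such MNMs matter for inference. Codon models used to detect
positive selection assume substitutions accumulate independently; a
mechanism that writes several adjacent substitutions at once mimics the
signature of repeated adaptive replacement, and the same locus can mutate
recurrently (the inversion is even reversible), mimicking parallel adaptive
evolution. `irswitch` implements a phylogenetic pipeline that identifies
such events in closely related strains from per-gene codon alignments and a
rooted species tree, scores their enrichment against a simulation-based
null, classifies the mechanism, and annotates the protein-level
consequences.

## Pipeline overview

For each gene the pipeline runs, in order:

1. **Prefilter** (`prefilter_orthoset()`): sequences with more than 20 `N`s
   are dropped; sets with fewer than 4 remaining strains are rejected.
2. **IR detection** (`find_perfect_irs()`): all maximal perfect IRs with arm
   length at least 7 bp and spacer at most 70 bp, found on each strain's
   ungapped sequence. Arms must match the reverse-complement identity
   exactly; positions holding `N` never pair; "maximal" means the arms can
   extend neither outward into the flanks nor inward into the spacer.
   Footprints are mapped back to alignment columns through the retained gap
   map.
3. **Binning** (`bin_and_deduplicate()`): each IR belongs to the bin of its
   maximal arm length and every bin is analyzed separately. Within a bin
   and strain, IRs with overlapping footprints are all discarded unless one
   is fully nested in the other, in which case both are kept.
4. **Model fit and ancestral reconstruction** (`fit_parameters()`,
   `reconstruct_ancestors()`): a GY94-type codon model with
   gamma-distributed omega (M5, below) is fitted and the marginal posterior
   codon distribution is computed for every internal node; the argmax state
   is used downstream. No posterior-confidence threshold is applied, but
   the per-site maxima are carried through for reporting.
5. **MNM calling** (`call_mnms()`): on terminal branches only, maximal runs
   of two or more strictly contiguous alignment columns in which the leaf
   differs from its reconstructed parent. Columns containing a gap or `N`
   in either sequence break runs; indels are never substitutions.
   Restricting to terminal branches keeps the calls close to the data and
   away from deeper reconstruction uncertainty.
6. **Association** (`associate_mnms()`): an MNM is arm-associated with an
   IR of the same strain when at least one of its columns intersects either
   arm, spacer-associated when it intersects the spacer; both labels are
   possible.
7. **Quality control** (`qc_filter()`): an associated IR is discarded when
   (i) the strain's terminal branch exceeds 0.2 expected substitutions per
   codon site (mutation saturation), (ii) the footprint contains an indel
   between strain and parent, or (iii) the IR region plus a 50-bp 3' tail,
   globally aligned between the strain and its nearest leaf by patristic
   distance (match 1, mismatch -1, gap 0), scores more than 15 points
   differently when aligned per nucleotide versus with codons as
   indivisible units -- the signature of a frameshifted, untrustworthy
   codon alignment. A hook accepts optional per-column confidence scores
   (cutoff 0.95) from external alignment-assessment tools.
8. **Controls** (`match_controls()`): each IR receives a control interval
   of the same length as its arm, placed in the nearest gap-free window of
   the same strain that intersects no detected IR footprint; ties break
   toward the 5' side, and IRs with identical footprints shared by several
   strains share one control position. Control intervals are tested for
   MNM overlap with the same terminal-branch rule.
9. **IR score and significance** (`compute_ir_score()`,
   `empirical_significance()`, `ir_score_test()`): see below.
10. **Event classification and protein effects** (`classify_event()`,
    `aa_consequences()`, `ts_tv_tally()`): see below.

`run_pipeline()` composes the stages with per-gene error isolation and a
master seed that fans out to per-gene, per-bin simulation seeds.

## The IR score and its empirical null

With `a` IRs whose arms overlap an MNM, `b` IRs without, and `c`/`d` the
same counts over the matched controls, the score is

$$\mathrm{IR\ score} = \frac{a + 1}{b + 1} \Big/ \frac{c + 1}{d + 1},$$

with a pseudo-count of 1 on every element to prevent division by zero. The
control ratio removes whatever MNM background the gene would show anywhere;
the score asks specifically whether MNMs concentrate on IR arms.
Spacer-only overlaps are deliberately not counted in `a`: they are handled
by the inversion pathway.

Significance is assessed against 100 simulated alignments per gene and bin.
Each replicate evolves a root sequence drawn from the stationary codon
distribution along the gene's tree under the fitted M5 parameters, with the
root length set to 4.5 times the outgroup's sequence length (configurable
in [4, 5]) so the longer simulated gene offers enough IRs; replicates are
accepted only if they contain at least as many distinct IRs of the tested
arm-length bin as the real alignment, and the whole analysis -- detection,
binning, association, QC, controls, scoring -- is repeated on every
accepted replicate. The empirical p-value is the add-one upper tail,
`p = (#{null >= real} + 1) / (n_null + 1)`, with ties counted against the
real gene; a gene is called significant at `p <= 0.05`. When a bin cannot
produce enough qualifying replicates within the attempt budget (long arms
are vanishingly rare in simulation), the test refuses with an error naming
the bin rather than degrading silently; no statistical call is made there.

Two accounting choices deserve a note. First, the replicate-acceptance
condition counts *distinct IR footprints*, not per-strain instances: an IR
locus conserved across all strains is one IR offered to the analysis, and
an instance count (one per strain) would make bins with long, conserved
arms impossible to satisfy in simulation even though the analysis of such
bins is routine. The score itself stays instance-based -- each strain's IR
has its own control in that strain. Second, null replicates are scored
against their *own true simulated ancestral sequences* rather than
re-reconstructed ones. This keeps the null computation to one pass per
replicate; the real gene is scored with reconstructed ancestors. At the
short branch lengths where the pipeline operates (saturated branches are
excluded at 0.2), reconstruction is nearly exact, and the no-event
calibration experiment below checks empirically that the asymmetry does
not distort the test's size.

No multiple-testing correction is applied across genes; raw empirical
p-values are reported and downstream users should treat genome-wide counts
accordingly.

## Classifying the mechanism

For every QC-passing association, the footprint of the IR is compared
between the strain and its reconstructed parent (`classify_event()`):

* **spacer inversion** -- the child spacer equals the reverse complement of
  the parent spacer and differs from it (a self-reverse-complement spacer
  makes the inversion unobservable, and no event is called);
* **arm homogenization** -- the parent arms are imperfect as a pair while
  the child arms are perfect;
* **combined** -- both at once.

Whether the parent arms were already perfect is recorded on the event (pure
inversions typically arise on previously perfect arms) but is not a
requirement. Classification is strand-symmetric: reverse-complementing both
regions yields the same class and counts. `count_parallel_events()` tallies
independent recurrences of the same footprint and derived form across
terminal branches -- repeated template switching at one locus is a
hallmark of the mechanism, not of adaptation.

Protein-level annotation (`aa_consequences()`) translates parent and child
in the anchored frame and reports per-codon replacements with Grantham
physicochemical distances (the embedded 1974 matrix spans 5--215 with mean
about 100; replacements above 120 are flagged as high-distance), the span
class (one codon, two neighboring codons, or more), synonymous-only events,
and the transition/transversion tally of the substitutions
(`ts_tv_tally()`).

## The codon model

The substitution process is a GY94-type codon model over the 61 sense
codons: rates are zero between codons differing at more than one
nucleotide, and otherwise proportional to the target codon's frequency,
multiplied by `kappa` for transitions and by `omega` for nonsynonymous
changes. Site-to-site variation in selective pressure follows M5: omega is
Gamma(shape, rate)-distributed across sites, discretized into
equal-probability categories represented by their bin means (default 8;
the calibration experiments use 4, which changes fitted likelihoods only
marginally at these divergences). Codon frequencies default to F3x4
estimates from the alignment (with a +1 nucleotide pseudo-count so no sense
codon gets probability zero); simulation without data uses uniform
frequencies unless told otherwise.

Likelihoods are computed by Felsenstein pruning with per-column rescaling;
transition matrices come from an eigendecomposition of the symmetrized
reversible generator (the similarity transform by the square-root
stationary frequencies), with tiny negative entries clamped to zero and
rows renormalized. Rate scaling is applied across the omega mixture --
the mean substitution rate at stationarity, averaged over categories,
equals one -- so branch lengths are expected substitutions per codon site
under the full model, the unit in which the 0.2 saturation cutoff is
interpreted. (The standalone `build_rate_matrix()` scales a single matrix
to mean rate one, the natural contract for a one-omega generator.) Gaps,
`N`-containing codons and stop codons are treated as missing data (partial
likelihood one over all codons); columns that are gaps in every leaf are
reported as gaps in the ancestors. Parameters are estimated by Nelder-Mead
on the log scale; branch-length optimization is available but the pipeline
defaults to the branch lengths of the supplied species tree.

Marginal ancestral reconstruction combines the standard downward partials
with an upward pass; per-site posteriors are mixed over omega categories
with their posterior category weights, and the reported state is the
per-site argmax. On four-taxon instances the implementation agrees with
exhaustive enumeration over all 61^3 ancestral assignments to 1e-8 (this is
a unit test), and on synthetic data at branch lengths at or below 0.1 it
recovers over 99% of ancestral codons.

## The synthetic universe generator

`generate_universe()` builds the test bed the validation suite runs on: a
pure-birth tree of `n_taxa` ingroup strains, rescaled so the mean terminal
branch is 0.06 expected substitutions per codon site with log-normal
(sd 0.3) per-branch rate noise to break the clock, plus an outgroup on a
0.35 branch attached above a 0.05 stem -- a caricature of a dense
population of conspecific strains with a congeneric outgroup. Genes are
gap-free in-frame codon alignments evolved under M5 defaults of kappa 3 and
omega ~ Gamma(0.6, 3) (mean 0.2, strongly purifying with a permissive
tail), uniform codon frequencies, 200 codons unless asked otherwise.

Events are planted after the neutral simulation, and the ancestral form is
written into every row *and every true ancestral sequence* while the
derived form goes only to the chosen leaf or leaves -- so the event maps
exactly to those terminal branches, mirroring the real signature. The
planted construct carries one fixed non-pairing base on each flank so the
IR is maximal at exactly the requested arm length in every row; candidate
arms and spacers are rejected if splicing them would create a stop codon
in any row, if the spacer is its own reverse complement, or -- for
inversions -- if the inverted spacer lacks two adjacent differences, since
such an inversion produces no MNM and is invisible to any MNM-based
detector (every documented real inversion has a fully substituted spacer).
The truth ledger records, per event, the branch, coordinates, both region
sequences and the changed columns; tests re-derive each event by diffing
the stored regions.

What the generator does **not** emulate: indels and alignment error (real
ortholog sets need the codon-MSA QC stage far more than these clean
alignments do), base-composition and codon-usage bias, rate variation
beyond M5, recombination, and selection on the planted events themselves.
Passing the suite therefore demonstrates the machinery is correct and
calibrated under the stated model, not that real yeast data are free of
the artifacts those stages guard against.

## Validation experiments and problem sizes

The suite's two capstone experiments run at desk scale, chosen as
down-scaled analogues of a genome-wide screen:

* **Null calibration**: 200 event-free genes (10 strains, 200 codons,
  n_null = 100, 4 omega categories, analysis at the generating kappa and
  omega). The fraction of genes called significant at the arm-7 bin must
  lie in [0.01, 0.10], the binomial band around the nominal 0.05.
* **Recovery**: 50 genes, each with one planted arm-homogenization MNM
  (arm 10, 3-base mismatch run, terminal branches at or below 0.1). With
  the true ancestors supplied, 100% of events must be called as MNMs and
  arm-associated; with reconstructed ancestors, at least 90%.

## Known limitations

* Internal-branch events are out of scope by design; the event census is a
  lower bound.
* The codon-unit QC score assumes rows gap in codon multiples, the defining
  property of a codon alignment; alignments violating it will tend to fail
  the score check, which is the intended direction of error.
* Empirical p-values are granular (1/101 steps) and reported uncorrected.
* When the focal strain's sister is a clade, the QC comparison uses the
  nearest leaf by patristic distance as its representative.
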