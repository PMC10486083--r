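---
title: "retromir: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{retromir: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own methods: what each
stage assumes, which parameters matter and why their defaults are what
they are, what the synthetic-data generator does and does not emulate,
and where the design was genuinely open and a choice had to be made.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The biological setting

A retrocopy is created when a spliced mRNA is reverse-transcribed and
reinserted into the genome: it carries the parent's exonic sequence,
concatenated across former exon junctions, and then diverges under its
own mutational history. Three routes can put a miRNA inside such a copy:

* **R (retroposed)** — the parent already carried an exonic miRNA and the
  copy inherited it;
* **EJ (exon-junction)** — two sequence halves that are separated by an
  intron in the parent become adjacent in the copy and only there fold
  into a hairpin; the parent cannot carry the annotation;
* **N (novel)** — post-insertion point mutations create a hairpin that has
  no counterpart in the parent.

The package discovers candidate retro-miRs, verifies folding, assigns one
of these classes, and then characterizes conservation, selection,
expression, targets, and prognostic association.

## Coordinates and I/O

All internal coordinates are 0-based half-open; GTF/GFF3 (1-based
inclusive) and BED (0-based half-open) are converted at the I/O boundary.
This single convention is deliberate: silently mixing browser conventions
is the classic failure mode of annotation pipelines. Overlap is
strand-aware by default — retrocopy and hosted miRNA co-orientation is
the biological expectation — with `ignore_strand` available because the
strandedness of the original interval intersection is not something we
can verify; it is exposed as a flag rather than guessed. A `.` strand is
permitted only for repeat/cCRE-style inputs and matches either strand.
Files are pre-validated line by line so malformed input fails with the
file name and 1-based line number before parsing.

## Hairpin assessment

The folding engine maximizes the number of nested Watson-Crick plus G:U
pairs (minimum hairpin loop 3 nt, the structural convention) with a
deterministic traceback. This is not a thermodynamic model: there are no
stacking energies, no ensemble, no ΔG. It was chosen because it is exact,
dependency-free, fast in compiled code, and — at the 40–200 nt scale of
miRNA precursors — separates planted stem-loops from background sequence,
which is all the discovery stage requires of it.

"A secondary structure is formed" is made concrete by three thresholds:

* `min_stem = 18` pairs in one extended helix, where consecutive pairs may
  be separated by interior loops of up to 6 unpaired nt. Canonical
  pre-miRNA stems are ~22 ± a few pairs; 18 leaves margin for wobble
  without admitting random 80-mers.
* `max_loop = 40` nt terminal loop — generous; real loops are ~3–20 nt.
* `min_paired_frac = 0.4` of bases paired.

Measured behaviour (recomputed by the test suite): random 80-mers pass in
fewer than 20% of draws; the generator's planted hairpins (24-bp stem,
8-nt loop) always pass. Shuffling a planted hairpin destroys the call in
roughly 70–80% of shuffles — not more, because the shuffled sequence
keeps a self-complementary base composition and re-pairs by chance; the
test asserts the majority behaviour rather than a knife-edge rate.

One property worth recording: with G:U pairs enabled, the maximum pair
count is *not* invariant under reverse complement (a G:U pair maps to
A:C). The invariance holds exactly in Watson-Crick-only mode, and that is
how the property is tested.

## Classification

The precursor (taken strand-aware from the retrocopy locus) is aligned
locally to the spliced parental mRNA (Needleman–Wunsch/Smith–Waterman
with affine gaps, via Biostrings); placements under 60% identity or
covering less than half the precursor are reported "unplaceable" rather
than forced into a class. The decision order is EJ → R → N because
junction evidence is structural and unambiguous, while the R/N rules
depend on mismatch counting, which is meaningful only after placement:

* EJ requires ≥ 2 genomic blocks separated by at least `min_intron = 30`
  bp — long enough to exclude alignment artifacts, far shorter than any
  real intron.
* R tolerates ≤ 1 mature mismatch. "Exact copy" is relaxed by one base
  because inherited copies can drift slightly in the mature region while
  remaining unmistakably the parental miRNA.
* N requires ≥ 2 mature mismatches *and* a non-folding parental region —
  both halves of the de novo argument.

Candidates that fit none of these remain `unclassified`, a first-class
output; silently dropping them would bias the class tally.

## Conservation and age

Identity is computed from a global alignment with terminal gap columns
excluded, so a truncated ortholog is not penalized for missing sequence.
Conservation is *strictly* greater than 0.80 — an identity of exactly
0.80 is not conserved — and the age is the most distal conserved species
along the ordered panel, with "human-specific" when none is conserved and
"all primates" when the most distal one is. Conservation is assessed on
the precursor; a mature-only assessment would be noisier at these lengths
(22 nt leaves ~4 informative mismatches at the 80% line).

## Selection (dN/dS)

The longest ATG-to-stop ORF (forward frames; the retrocopy's orientation
is known from its strand) is codon-aligned to the parent's ORF through a
BLOSUM62 protein alignment, and dN/dS follows Nei–Gojobori (1986):
per-codon synonymous-site fractions (changes to stop codons count as
nonsynonymous, so S + N = 3 for every sense codon), pathway-averaged
difference counts that skip stop-codon intermediates, and Jukes–Cantor
correction `d = -3/4 log(1 - 4p/3)` with saturation (`p ≥ 3/4`) reported
as `NA`.

Departure from neutrality is tested by resampling codon columns
(default 1000 bootstrap replicates; 200 in the pipeline's default
configuration, where 12 loci are tested on one CPU) and doubling the
smaller tail fraction of `dN − dS` about zero. The sign of `dN − dS` is
used as the bootstrap statistic rather than `omega` itself so that
resamples with `dS = 0` do not produce undefined ratios. Maximum-
likelihood codon models would be the heavyweight alternative; the
counting estimator is fully specified, exactly testable against a
brute-force pathway enumeration, and recovers simulated regimes
(`omega_true = 0.1` called purifying, `omega_true = 1` called neutral, in
well over 90% of replicates — recomputed by the acceptance suite).
`omega` is `NA` whenever `dS = 0`; identical sequences are reported as
"not evaluable", never as neutral.

## Expression

TPM is the default unit (`RPM` available); "expressed" means TPM > 0.
Breadth is the number of tissues whose median TPM is positive. The TSS
search looks strictly upstream (strand-aware) of the precursor's 5' end
within 4000 bp; cCRE proximity uses a 20-kb window — the source
convention's "20,000 kb" is read as a typo for 20 kb, and the window is a
parameter, not a hard-coded guess. Tumor-vs-normal testing is a
two-sided Mann–Whitney with exact p-values when both groups have ≤ 8
samples and no ties, and the normal approximation with continuity and tie
correction otherwise; stars follow the conventional bands. Matures with
identical sequences cannot be attributed to a specific precursor by
counting alone; they are summed into one flagged feature rather than
apportioned by an invented rule.

A compositional caveat the tests document explicitly: TPM columns are
constrained to sum to 10^6, so when planted overexpressed features make
up a large share of a small feature panel, unchanged features shift
downward in tumors. That is a property of the unit, not a bug; null
calibration is therefore checked on fold-1 data, where it holds at the
nominal rate.

## Targets and enrichment

The seed is mature positions 2–8; its reverse complement is searched in
each UTR (DNA/RNA normalized internally). A core match followed by an
`A` in the UTR is an 8mer-1a, otherwise a 7mer-m8; each core position is
reported once with the stronger type. Gene-level target calls are the
union of predicted sites and externally validated interactions — a
validated gene with zero predicted sites is kept. Enrichment is the
upper-tail hypergeometric with BH correction across sets; the universe
defaults to all genes with an annotated UTR in the input, the only
universe the input files define.

## Survival signature

The fitting core is a ridge-penalized Cox partial likelihood (Breslow
ties, Newton–Raphson with step halving, relative tolerance 1e-8,
`lambda = 0.1` on z-scored log1p expression). The signature procedure
resamples patients (default 100 resamples, each fit on a full-size
bootstrap), then keeps features that (i) hold one coefficient sign in at
least 80% of resamples and (ii) pass a bootstrap z-test
(mean/sd over resamples) at Bonferroni-corrected 5% across the candidate
features. The second condition exists because the sign rule alone does
not calibrate: bootstrap resamples of one dataset share its sampling
noise, so a null feature whose in-sample coefficient happens to be
moderately nonzero keeps its sign in most resamples (measured ~40%
per-feature inclusion without the z-test; with it, all-null panels return
an empty signature in ~90% of runs while a planted log-2 hazard feature
is selected essentially always — both recomputed in the tests).
Coefficients are bootstrap means; patients are scored by
`sum(beta_i * z_i)`, split at the in-sample median with ties to the low
group, and compared by Kaplan–Meier curves and a log-rank test. Candidate
features are restricted to expressed retro-miR matures, mirroring how the
stage is meant to be used.

## The synthetic-data generator

The generator builds each gene as an mRNA — 5'UTR, intact CDS (90–130
codons), 3'UTR — then splits it into 3–5 exons with 80–200 bp introns, so
every gene has a real ORF for the selection stage and well-defined
junctions for EJ planting. Hairpins (24-bp stem, 8-nt loop, 22-nt mature
in the 5' arm) are planted in the 3'UTR: intact within an exon (R, with
the parental miRNA annotated), straddling a junction placed inside the
mature (EJ), or pairing-broken at 7 spread positions (N — broken in the
parent, reverted in the copy, so the copy's mature differs at ≥ 2
positions and the parental region cannot fold). Twelve retro-miRs (4 per
class) are planted by default, plus one mobile-element decoy that the
repeat screen must flag. Copies land on random strands; background point
mutations default to rate 0 so R/EJ plants are exact copies and the truth
ledger is exact.

Ortholog panels assign each retro-miR a conservation depth (cycling
through human-specific to all-primates) and substitute sites at 2–10%
per species — all below the 20% identity budget, so "present" and
"conserved" coincide and absence encodes the age. Expression is negative
binomial (dispersion 0.3) with a lognormal-jittered 4-fold tumor effect
on half the real matures over 30+30 cohort samples; survival times are
exponential with hazard `h0·exp(beta·z)`, `beta = log 2` on two planted
matures, with independent exponential censoring at ~30%; UTR backgrounds
are rejection-sampled to be free of accidental seed cores (≤ 1000
attempts, then error) before sites are written at recorded positions, so
scanned counts equal the ledger exactly.

What the generator does not emulate: chromosome-scale genomes, L1
insertion mechanics (target-site duplications, poly-A tails), indels
(excluded by default so truth coordinates stay exact; an indel mode would
change bookkeeping, not the methods), sequencing reads, batch effects,
or realistic miRNome-scale feature panels. Passing on synthetic data
therefore demonstrates algorithmic correctness against known truth — not
performance on real genomes, where repeat structure, paralogy, and
annotation error dominate.

## Pipeline mechanics

`run_all` executes discover → fold → classify → conserve → select →
express → targets/enrich → survive, writing every stage table as TSV plus
a deterministic plain-text report. Every stochastic stage derives its
seed from the single config seed, so a rerun with the same configuration
is byte-identical (the acceptance suite checks file hashes). Stages are
recomputed rather than cached: at the package's intended scale every
stage runs in seconds, and cache state is a source of stale-results bugs
with no offsetting benefit here. The report embeds an MD5 hash of the
seed and parameters (not the output path), so reports are comparable
across locations.

Default problem sizes — 12 genes, ~30 kb genome, 200 patients, 50 UTRs,
200-codon selection simulations, 100–1000 bootstrap replicates — were
chosen so that the full pipeline and its validation complete in minutes
on one CPU while keeping every statistical check comfortably powered.

## Known limitations

* Base-pair maximization over-pairs relative to thermodynamic folding;
  the thresholds compensate at precursor scale but the dot-brackets are
  not MFE structures and should not be interpreted as such.
* The duplication screen is an exhaustive translated search over genome
  windows — correct and exact at toy scale, not a BLAST replacement.
* NG86 assumes equal base frequencies and no transition/transversion
  bias; with strong bias it under-corrects relative to ML codon models.
* Multi-parental retrocopies are taken at their recorded parent; paralog
  resolution is out of scope.
* The survival module models a single signature with L2 penalties and
  Breslow ties; clinical covariate adjustment and competing risks are
  out of scope.
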