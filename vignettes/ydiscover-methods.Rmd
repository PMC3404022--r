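---
title: "Methods: anchor-based Y-chromosome subclade discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-based Y-chromosome subclade discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The non-recombining portion of the human Y chromosome is inherited as a
single haploid block, so every man's Y fits on one genealogical tree, and
every SNP that has mutated exactly once marks one branch of it
(haplogroups). Given haploid genotype calls for a cohort — in practice
low-coverage (2–4×) whole-genome calls, where a third of sites may be
missing in any one sample and sequencing error produces calls that look
heterozygous on a chromosome that cannot be — the task is:

1. split samples into **cases** (derived at an anchor SNP defining the
   haplogroup of interest) and **controls** (ancestral there);
2. nominate candidate variants that subdivide the case cohort;
3. filter out artefacts;
4. assemble the survivors into a rooted **perfect phylogeny** of subclades,
   labelling each branch with its phylogenetically equivalent markers;
5. reconcile the result against a prior scaffold of named markers and place
   each sample at its most derived node.

`ydiscover` implements this pipeline together with a simulator of the
calling regime, so every stage is testable against known ground truth
without any external download.

## The filter cascade

Candidate variants pass four stages in a fixed order, and a failing variant
is attributed to the **first** stage it fails — the source criteria are a
set, not a sequence, so the order is this package's convention, chosen to
make reports reproducible and to run the cheap cohort-level checks before
the pairwise one:

* **F1 control-ancestral** — fail if any control has an *observed* derived
  call. Controls that are missing or ambiguous are uninformative: a
  universally quantified condition can only be tested on observed data,
  and rejecting on unobserved calls would be unsound. A variant with no
  informative controls passes vacuously and is annotated
  `"no informative controls"`. Sites where every observed sample is
  derived (reference artefacts) can never be rejected by F1 and are
  annotated as such.
* **F2 non-singleton** — fail if fewer than two case samples carry an
  observed derived call. Singletons carry no clade information; ambiguous
  calls never count toward the threshold.
* **F3 no heterozygous-looking calls** — fail if the number of AMBIGUOUS
  calls among cases and controls exceeds `max_ambiguous` (default 0, the
  strict literal rule: a haploid chromosome should never yield a
  heterozygous call, so any such call indicates a duplicated or paralogous
  region).
* **F4 phylogenetic consistency** — the rooted compatibility test: with
  the ancestral state known, two variants fit on one tree iff their
  derived-carrier sets, restricted to jointly observed case samples, are
  nested or disjoint; equivalently the pair is incompatible iff all three
  patterns (1,0), (0,1), (1,1) occur. The pairwise incompatibility graph
  is resolved by greedily removing the variant of highest conflict degree
  (ties: fewer observed derived cases, then higher position) until
  conflict-free. Greedy removal rather than exact minimum vertex cover is
  deliberate: it is deterministic, near-optimal for the sparse conflict
  structure duplicated-region artefacts produce (a recurrent pseudo-variant
  conflicts with several genuine variants, which conflict with nothing
  else, so its degree dominates), and exact on the simulator's artefact
  construction. Compatibility is evaluated on cases only: survivors of F1
  are ancestral in every observed control, so controls cannot create
  conflicts.

Novelty is an annotation, not a filter: a variant is *known* iff its
(contig, position, derived allele) key appears in a user-supplied local
known-variant list, in which role a public Y-SNP catalogue would be used.

Orientation of ancestral vs derived is explicit. By default it is taken
from the VCF (`INFO/ANC`, falling back to REF); with
`orientation = "control-majority"` it is re-derived per site as the
majority observed allele among controls, with ties flagged `UNUSABLE` —
the mode to use when the reference orientation cannot be trusted.

## Equivalent blocks and tree construction

Retained variants with *identical* observed derived case sets collapse into
one **marker block**; the block label joins the member names in
alphanumeric order (the convention used when equivalent markers are listed
on one branch). Identity, not mere non-contradiction, is required —
grouping by partial match is non-transitive and would chain unrelated
variants. Blocks separated only by missing data are instead flagged
`"possibly equivalent (missing data)"`.

Blocks are inserted in decreasing carrier-count order under the deepest
node whose set contains them. With complete data the retained blocks form a
laminar family (every pair nested or disjoint — the set-system form of a
rooted tree), and insertion is exact. With missing data the *observed* sets
of pairwise-compatible blocks need not be strictly laminar (a sample
missing at a parent block but derived at its child breaks raw-set nesting),
so nesting decisions use joint observations: a block descends under a
candidate only when they overlap and no observed call contradicts the
nesting. The hard post-build assertion is correspondingly *generalized*
laminarity — every node pair must pass the rooted compatibility test on
observed calls — which reduces to strict laminarity in the noiseless case.
A violation aborts with an internal-consistency error, because it means the
F4 contract was broken upstream.

A block whose carriers are the entire case cohort (the anchor, and anything
equivalent to it) labels the root rather than becoming a child — the root
*is* the anchor clade.

Samples attach to their most derived containing node: the deepest node at
whose block the sample is observed derived. A sample missing at a parent
block but derived below it still descends — passage through the
undetermined node is implied by laminarity and surfaced by
`place_samples()` as an `"undetermined at <block> (passage inferred)"`
diagnostic, never imputed into the matrix. When noise makes two
incomparable nodes claim a sample, the node with more member-variant
support wins (ties by label) and the conflict is reported.

Everything is canonically ordered (blocks, siblings and labels
alphanumerically; tie-breaks fully specified), so outputs are diffable and
invariant under permutation of the input rows and columns.

## Scaffold reconciliation

The scaffold is a parent–child table of named markers rooted at the anchor
(the role a curated haplogroup tree plays). For each scaffold marker found
in the data: **CONFIRMED** when its tree parent's block (or its own block,
for markers equivalent to their scaffold parent) contains the scaffold
parent or any scaffold ancestor of it — so a marker that lands under its
grandparent because the intermediate was unobserved still confirms;
otherwise **REPOSITIONED**, keeping the data-derived placement and
reporting both parents ("data wins" — a richer variant set legitimately
relocates known markers below newly discovered ones); **UNPLACED** when
never observed. The adjudication rule is this package's explicit
convention; the source analysis reported repositionings without stating a
general rule.

## The simulator: a stated world

The generator emulates the discovery regime, with defaults fixed a priori:

* a rooted clade tree (`n_clades` = 8 below the anchor root). The first
  two clades attach to the root and the third below clade 1, the rest
  uniformly at random. This guarantees a branch with a non-root parent
  plus a branch disjoint from that parent's subtree — the configuration a
  recurrent artefact needs to be *detectable*: a pseudo-variant spanning
  two disjoint root-child subtrees is nested-or-disjoint with every
  genuine variant and no compatibility test can catch it, so placing
  artefacts there would silently test nothing.
* cohort of 30 cases / 20 controls; each clade node receives two
  guaranteed directly-attached case samples (hence
  `n_case_samples >= 2 * n_clades`), the rest uniform over root and
  clades. Without the guarantee, exact recovery would not be well-posed: a
  clade with fewer than two private cases is either invisible (its
  variants are singletons) or indistinguishable from its only child.
* 3 branch-private variants per branch under infinite sites (a fixed
  count, so noiseless block sizes are exactly testable), 5 singletons, 2
  recurrent artefacts; positions drawn without replacement from
  1..60,000,000 on `chrY` (the scale of the chromosome; the exact range is
  arbitrary).
* calling: per-cell read depth ~ Poisson(`mean_coverage` = 3, the 2–4×
  regime); each read errs with `per_read_error` = 0.02; a site is dropped
  outright with `missing_rate` = 0.05. A call is MISSING at depth 0 or
  when dropped; AMBIGUOUS when both alleles have ≥ 2 supporting reads
  (`ambiguity_threshold_reads`), *or* when support is exactly tied — the
  observed artefact class is "heterozygous-looking calls", for which no
  threshold was stated, so a mechanical read-support rule reproduces it;
  otherwise the majority allele. Per-allele depths are emitted as VCF `AD`
  so readers can recompute ambiguity with the same rule, which is what
  makes write→read the identity on all four states.
* population labels drawn i.i.d. (defaults GBR 0.35, CEU 0.30, IBS 0.20,
  TSI 0.15 — a European-weighted mix of the kind of cohorts such studies
  draw on); labels affect reporting only, never inference.
* one RNG stream per stage, derived from the run seed by fixed offsets, so
  adding a stage never perturbs earlier stages and every output is
  byte-reproducible from the seed.

The exact-recovery test regime additionally sets `per_read_error = 0`,
`missing_rate = 0` and `mean_coverage = 30`: the noiseless limit needs deep
enough coverage that Poisson depth-0 cells are negligible, and that choice
was fixed before any outcome was measured.

What the simulator does **not** emulate: reads and alignment (no BAM/FASTQ;
mapping artefacts enter only as the stylized recurrent class), linked
recombining regions, reference bias, indels or multi-allelic sites, STR
loci, and population structure in the tree shape. A green recovery test
therefore establishes that the pipeline's logic is correct on its stated
model of the data, not that real low-coverage calling has these error
rates.

## Numerical and interface choices

* Coordinates are 1-based inclusive (VCF convention) everywhere.
* Multi-allelic and indel records are excluded with a counted warning
  (only biallelic SNPs are analysed).
* Reported percentages use one decimal, rounding half away from zero.
* Config files are DCF (`key: value`) read with base `read.dcf` — the
  R-native flat key-value format; no YAML dependency.
* VCF parsing is delegated to Bioconductor's `VariantAnnotation`; writing
  is a plain-text writer in this package so equal inputs give
  byte-identical files.
* Tree comparison uses the symmetric difference of rooted clade
  sample-sets, which for rooted trees on a shared cohort equals the
  Robinson–Foulds distance; `ape` serves as the independent Newick
  round-trip oracle in the tests.
* The CLI exposes `simulate`, `filter`, `build`, `report` and `run`; each
  subcommand takes its inputs explicitly and later subcommands re-run the
  earlier stages in memory (they are cheap), rather than deserializing a
  partial pipeline state.
* Degradation under noise is *measured, not assumed*: the truth-evaluation
  helper reports the fraction of retained branch variants whose observed
  block equals their branch's true carrier set, and control-contamination
  counts; the tests pin only exact reproducibility under fixed seeds, not
  a threshold.

## Known limitations

Greedy F4 is not guaranteed minimal on adversarial conflict graphs (it is
exact on the artefact structure the domain produces). Placement accuracy
under heavy noise is scored strictly (a sample is correct only if its
reconstructed subtree set matches the truth exactly), which makes the
reported noisy-regime numbers conservative. Scaffold markers are resolved
by name only, and the reconciliation rule is a convention, not an inferred
quantity. Sites where all samples are derived are retained but can never
pass F1 and are only annotated.
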