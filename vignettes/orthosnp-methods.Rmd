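---
title: "Methods: cross-species CDS conservation and disease SNP mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species CDS conservation and disease SNP mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosnp)
```

## Overview

`orthosnp` compares the human coding sequences (CDSs) against five mammalian
model species and maps human disease-associated SNPs onto each species'
genome through six-way alignments. This vignette documents the model behind
each stage, the parameters that matter, the simulator used for validation,
and the numerical and design choices a maintainer should know about.

## Conservation filtering

Each non-human CDS is compared against the full human CDS set by local
alignment with affine gaps: a gap of length $L$ costs
$g_{open} + L\,g_{ext}$. The default scoring (match $+1$, mismatch $-2$,
$g_{open} = -5$, $g_{ext} = -2$) approximates a nucleotide BLAST run; the
downstream analysis is driven by the identity and coverage *filters*, not by
raw scores, so modest changes to the scoring matrix leave the conserved set
essentially unchanged. Exactly one highest-scoring alignment is kept per
subject and one best subject per query, with a deterministic tie-break
(higher score, then higher percent identity, then lexicographically smallest
subject id). Percent identity is computed over alignment columns including
gap columns; coverage is the aligned span on the *human* CDS divided by the
full human CDS length, because the conservation definition is
human-referenced.

A hit passes the conservation filter iff identity $\ge 50\%$ **and**
coverage $\ge 0.5$; both bounds are inclusive ("at least 50%"). A human CDS
is *conserved* when it passes in all five species comparisons. No
reciprocal-best-hit requirement is imposed: the search is one-directional
(each model species queried against human), which matches the way the
conserved set is defined.

For speed, `best_hits(max_candidates = k)` can restrict the alignment to the
$k$ subjects sharing the most 8-mers with the query. This is a word-hash
prescreen in the spirit of BLAST seeding; the tests require it to agree with
the exhaustive search on ortholog-like data, and the default in
`best_hits()` itself is the exhaustive search (`Inf`). The pipeline default
is $k = 10$, which is generous when each query has a single true ortholog.

Identity distributions are compared with a classical one-way ANOVA plus all
pairwise Welch $t$-tests, Bonferroni-corrected by multiplying each raw $p$
by the number of pairs (capped at 1). The fully degenerate case (zero
variance everywhere, equal means) is reported as $F = 0$, $p = 1$ rather
than `NaN`.

## Alignment and SNP projection

Conserved groups are aligned by tree-guided progressive alignment: leaves
are merged in the guide tree's postorder, each merge being a global
affine-gap (Gotoh) alignment of two profiles, scoring a column pair by the
mean pairwise substitution score (residue pairs involving a gap score 0).
Ties in the dynamic program are resolved deterministically
(diagonal, then vertical, then horizontal). A pre-computed alignment can be
supplied instead (`align_group(prealigned = ...)`); its rows are validated
to de-gap exactly to the inputs. Every block is validated the same way, so
"removing gaps from the human row reproduces the human CDS" holds by
construction.

Human coordinates are the analysis frame throughout:

* a *variant column* has a non-gap human base and at least one differing
  non-human row (a gap counts as a difference for detection);
* columns gapped in the human row are skipped entirely;
* the human CDS position of a column is the count of non-gap human
  characters up to and including it;
* genomic positions come from a 1-based inclusive exon walk, descending on
  the genome for minus-strand CDSs.

A catalog SNP is located by (chromosome, position) within the conserved
CDSs and *identified in* species $S$ iff $S$'s residue at the SNP's column
equals the catalog **major** allele. Two conservative rules deserve note.
First, a gap never matches: an unalignable or deleted site cannot support a
major-allele match. Second, if the human reference base at a catalog
position disagrees with the catalog's declared major allele, the SNP is
excluded and reported, never silently matched — with real catalogs this
flags assembly/catalog version mismatches. Catalog SNPs are mapped whether
or not their column is variant across species (a site at which all six
species agree is still an identified SNP in all five models); multi-allelic
records are allowed, but matching is strictly against the major allele.
Whether sites matching a human *minor* allele should also count is left out
deliberately: the match criterion here is the major allele only.

## Disease profiling

Association tables are joined by rsID; association rows whose rsID is not
among the mapped SNPs are ignored with a reported count. Disease identity is
the case-folded disease-name string, and a disease counts once per species
no matter how many SNPs or genes support it. *Conserved* diseases are those
identified in all five species; *species-specific* diseases in exactly one.
Category percentages are computed over unique diseases
($100 \cdot n_{cat} / n_{total}$ per species over 24 categories) and sum to
100 by construction; an empty species yields an all-zero profile with a
warning rather than an error, since a sparse input is a legitimate state.
The 24-category vocabulary is treated as opaque labels supplied with the
association table; the generator ships a DisGeNET-style default
(`disease_categories()`). Per-chromosome top genes use a deterministic
tie-break: higher unique-disease count, then alphabetical gene symbol.

## Phylogeny and synteny

Block alignments are concatenated in human chromosome order (1–22, X, Y),
then by genomic start. Distances use *pairwise deletion* — only the columns
gapped (or `N`) in either of the two rows are dropped for that pair — which
keeps more signal at desk scale than complete deletion. The Jukes–Cantor
transform $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ is undefined at
$p \ge 0.75$ and errors there explicitly.

Tree building is canonical neighbor joining (Studier–Keppler $Q$ criterion,
standard branch-length formulas), with ties on $Q$ broken by the
lexicographically smallest representative-taxon pair and negative branch
lengths clamped to zero with a message. NJ with JC distances stands in for
approximate-ML GTR inference deliberately: the reported output of this
analysis is the *topology* and relative distances, NJ on an additive matrix
is exactly recoverable (and tested to be), and the whole path stays
self-contained and oracle-checkable. Bootstrap support is out of scope.
Robinson–Foulds distance is the size of the symmetric difference of
non-trivial bipartition sets; both NJ and RF are cross-checked in the test
suite against independent implementations (`ape::nj`, `phangorn::RF.dist`).

Synteny maps count conserved orthologs per (human chromosome, species
chromosome) cell; source chromosomes are listed in descending count order
with ties broken by label order (numeric, then X, then Y), and a cell is
*intact* when one source chromosome carries all of that human chromosome's
conserved orthologs.

## The synthetic-data generator

The generator is the package's validation instrument, not a fixture: it
evolves `n_cds` ancestral CDSs independently down a six-taxon guide tree
under Jukes–Cantor substitution — on a branch of length $d$ each site
changes with probability $\tfrac{3}{4}(1 - e^{-4d/3})$, uniformly to one of
the three other bases — with optional indels at `indel_rate` events per site
per unit branch length, frame-preserving (lengths a multiple of 3) by
default and frame-breaking behind a flag. Site lineages are tracked through
indels, so the truth tables (which species carries the human major allele at
each planted SNP's orthologous site) remain exact even for gapped groups; a
deletion that would empty a CDS is redrawn and reported. Human CDSs get 1–5
exons on a toy coordinate system with both strands represented; rsIDs are
`"rs"` + sequential integer; the major allele is defined as the human
reference base (how ambiguous dbSNP records designate major alleles is not
modelled). Identical configurations and seeds give byte-identical outputs.

Default study conditions: 100 CDS groups of 300–900 nt (multiples of 3),
`indel_rate = 0`, 500 planted SNPs with minor-allele frequencies in
[0.05, 0.5], 100 diseases over 24 categories. The default guide tree's
branch lengths are calibrated so the human-to-species path divergences,
passed through Jukes–Cantor, give mean CDS identities around 96.8%
(macaque), 94.7% (marmoset), 89.4% (pig), 86.7% (mouse), and 86.5% (rat) —
the identity regime typical of CDS-level comparisons between human and
these species — with the macaque as human's nearest leaf by path length.
The phylogeny-recovery checks in the test suite additionally rescale this
tree to a total depth of 0.3 substitutions/site across 20 seeds.

What the simulator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: codon structure and selection (sites are
i.i.d.; real CDSs have codon-position rate structure), rate variation across
sites and lineages, GC/composition bias (real blastn identity distributions
are skewed, not binomial), gene duplication and paralogy (each query has
exactly one true ortholog, so best-hit assignment is easier than in real
genomes), alignment ambiguity at high divergence, population structure
beyond a major/minor allele dichotomy, and the noisy, versioned nature of
real SNP and disease annotations. Full-scale headline numbers from real
assemblies (e.g. a five-figure conserved-CDS count) require the pinned
genome downloads and live annotation databases and are outside the package's
desk-scale validation.

## Problem sizes and numerical notes

The test suite and the acceptance script run at desk scale by choice: 100
CDS groups for the planted-SNP recovery and end-to-end runs, 20 seeds for
topology recovery, 50-element fixtures for the set-algebra oracles, and
oracle alignments up to a few hundred nt (the exhaustive Smith–Waterman
oracle is quadratic in pure R). Alignment kernels are exact dynamic
programs in C++ (no heuristic banding); score ties in every DP and every
ranking have a documented deterministic resolution, which is what makes the
bit-identity determinism guarantee of `run_pipeline()` possible. Floating
point enters only through alignment scores (small integers in the default
scoring, exactly representable) and the distance/ANOVA computations, where
tests use tolerances of $10^{-6}$ or tighter.

## Known limitations

* Progressive MSA is not iteratively refined and is not codon-aware; at
  high divergence with many indels its columns can differ from a
  refinement-based aligner's.
* One best subject per query means recent duplications can shadow the true
  ortholog in real genomes.
* Disease identity by name string is only as clean as the annotation
  source; the case-folding helps but does not resolve synonyms.
* NJ provides no support values; the package reports a point topology.
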