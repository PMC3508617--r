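---
title: "Methods: confidence-scored homology transfer and transporter classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confidence-scored homology transfer and transporter classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metannot` re-annotates the protein-coding genes of a genome with metabolic
functions — Enzyme Commission (EC) numbers, gene products, and Transporter
Classification (TC) numbers — from *pre-computed* homology searches and
offline evidence tables. Nothing in the package touches the network; every
input is a file, which makes every stage reproducible and testable. This
vignette describes the models and procedures, the parameters that matter,
the numerical choices, and what the synthetic test bed does and does not
demonstrate.

## The confidence score

For each gene, a homology search against a protein database yields a list
of hits, each carrying an e-value, a bit score, the subject organism's
taxonomic lineage, and the subject's annotation (EC numbers and a product
name). After filtering (e-value at most `evalue_ceiling`, default 1e-30;
at most `max_hits`, default 100, in ascending e-value order with bit-score
and accession tie-breaks), every distinct EC number and product string
among the retained hits becomes a *candidate function*, scored by the
convex combination

$$
\mathrm{score}_{\mathrm{annotation}}
  = \alpha\,\mathrm{score}_{\mathrm{frequency}}
  + (1-\alpha)\,\mathrm{score}_{\mathrm{taxonomy}},
\qquad \alpha \in [0,1].
$$

Both component scores are normalized to $[0,1]$ so the combination is a
true convex mixture:

* **Frequency** — the fraction of retained hits whose annotation carries
  the candidate label.
* **Taxonomy** — the mean, over the hits carrying the label, of the
  shared-prefix fraction between the query organism's lineage and the
  hit's lineage: the length of the longest common root-to-leaf prefix
  divided by the longer of the two lineages. A hit with unknown lineage
  contributes 0.

The frequency and taxonomy formulas are this package's concrete
instantiation: upstream descriptions of the approach leave both terms
informal, and a non-uniform weighting of taxonomic ranks would be an
equally defensible choice; the shared-prefix mean is the simplest
normalized form and is what the test oracles pin down. With the default
$\alpha = 0.2$, taxonomy outweighs frequency 4:1, so a function reported
by a minority of taxonomically close homologues (e.g. budding yeasts, for
a yeast query) beats a majority reported only in distant organisms — the
property the dual-project design depends on. At $\alpha = 1$ the ranking
degenerates to frequency-only, at $\alpha = 0$ to taxonomy-only; both
limits are asserted exactly in the test suite.

Ties on the combined score are broken deterministically: complete EC
numbers before partial ones, then more supporting hits, then
lexicographic label. The ranking is a total order, so identical inputs
give byte-identical output.

The selected automatic annotation is the top-scoring EC number together
with the top-scoring product among the hits supporting that EC. A locus
whose selection carries at least one EC number is an *enzyme encoding
gene candidate* (EEGC). No minimum score is imposed: rejection is the
curation engine's job, which sees strictly more evidence.

## Two projects and the four-set comparison

The genome is annotated twice — against a broad database (`nr`) and a
yeast-restricted one (`yeast`) — and the EEGC sets are partitioned into
*matches* (equal selected EC sets after normalization), *distinct* (both
selected, sets differ), *nr_only* and *yeast_only*. The partition is
decided on EC sets only; product-string disagreements are logged, not
partitioned, because product spelling varies too freely across databases
to be a reliable discriminator. Partial-versus-complete pairs (such as
`3.2.2.-` against `3.2.2.27`) are classified distinct but flagged
*revisable*, since registry verification may later reconcile them.

## The curation decision tree

Each EEGC then passes a deterministic decision tree over its *evidence
bundle*, a set of offline tables emulating curated-database lookups:

1. **L** — a literature override (author knowledge, one row per gene) wins
   outright; a contradicting reviewed record is flagged rather than
   silently dropped. Ordering literature first is a deliberate choice:
   the override encodes organism-specific knowledge that a generic
   reviewed record cannot trump, and the flag preserves the conflict for
   review.
2. **A** — a reviewed database record for the locus itself is accepted.
3. **B1** — otherwise the best *S. cerevisiae* homologue among the
   retained hits (minimum e-value at or below 1e-30; ties by bit score)
   is taken, and the UniProt and SGD entries for its systematic
   Y-identifier are reconciled. Identical EC sets pass; on disagreement
   the organism-specific SGD entry is favoured.
4. **B2** — failing that, a reviewed-restricted similarity search under a
   lowered ceiling (e-value strictly below 1e-10) is consulted (best
   hit), then an organism-unrestricted one (first hit). With no
   qualifying hit the gene is **discarded** as non-metabolic.
5. **C** — accepted EC sets are verified against an EC registry:
   deprecated numbers are replaced by all their transfer targets (a
   terminal deletion removes the number); a partial number is upgraded to
   a complete one only when *exactly one* active complete entry both
   refines the prefix and lists the product among its accepted names.
   The upgrade is attempted whether or not the partial number is itself a
   registry row — the rule is a search over complete entries, not a
   property of the partial. Transfer targets absent from the registry are
   flagged unknown, so every emitted EC is either an active registry
   entry or explicitly flagged.
6. **D** — the decision is emitted with a provenance code
   `<origin>-<sources>`: origin `M`/`D`/`N`/`Y`/`T` for the comparison
   set (or transporter-only), and the sorted subset of `U` (UniProt),
   `S` (SGD), `B` (registry revision applied), `H` (non-cerevisiae
   homologue), `L` (literature) actually consulted. The scheme
   round-trips losslessly and is this package's own.

The tree is monotone in evidence: adding a reviewed record to a
previously discarded gene's bundle can only turn it annotated, never
perturb another gene — a property the suite asserts.

## Transporter classification

Genes with at least one predicted transmembrane helix (from a TMHMM-style
summary) are transporter candidates (TPGC). Each is aligned against every
entry of a TC-numbered reference database with an in-house affine-gap
Smith–Waterman aligner (Gotoh three-state recursion with full traceback,
compiled; a gap of length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$,
defaults 10 and 0.5; BLOSUM62, switching to PAM30 for queries shorter
than 35 residues — PAM30 suits short, highly conserved segments, and 35
is this package's concrete cut for "short").

An alignment's *similarity fraction* is positives per alignment column
(positives = aligned pairs with positive substitution score; gap columns
count in the denominator); identities per column is available as a
configurable alternative for sensitivity analysis. Reference entries at
or above the *effective threshold*

$$
\mathrm{thr}(h) = \max\!\left(\frac{\mathrm{base}}{h}, \mathrm{floor}\right),
\qquad \mathrm{base} = 0.10,\; \mathrm{floor} = 0.02,
$$

for a query with $h$ helices are kept: the more transmembrane helices a
protein has, the more structurally constrained it is, so weaker sequence
similarity to a reference transporter remains informative. "Inversely
proportional" is taken literally; the floor prevents the threshold from
vanishing for many-helix proteins. The exact published heuristic behind
this scaling was never disclosed, so this instantiation is declared,
configurable, and tested — but not claimed identical to any other tool's.

The kept entries' four-component TC *family* prefixes and substrate lists
are then scored with the same convex-combination machinery used for EC
numbers, with one difference: reference databases of transporters span
too few organisms for a meaningful taxonomy term, so the taxonomy score
of a TC label is set equal to its frequency score (making $\alpha$
irrelevant there). The winning family is rolled up to its three-component
superfamily (TCS) number — family-level assignment from a small reference
is considered over-precise — and the top-scoring substrates are retained.
A candidate with no kept entry is discarded. Genes with both an EC and a
TC(S) assignment are kept as dual annotations and merged downstream.

## Reporting

Merged annotations are classified by category (monofunctional /
multifunctional / multiclass / with-TC, the last taking precedence),
completeness (partial iff any EC carries a `-` placeholder), and enzyme
class from the *first-annotated* EC number, treated as the main function.
The reporting module produces the completeness-by-category-by-class
cross-tabulation with conserved marginals, provenance and TC-class
percentage shares, and a comparison against an external annotation in
which TC payloads are ignored and each locus falls in exactly one of
*match*, *superset* (ours strictly extends or completes the external
set), *subset*, *conflict*, *new-in-ours* (further bucketed by payload),
*ruled-out* (externally metabolic, discarded here) or *absent-in-ours*.
Superset/subset use EC refinement: a complete number satisfies an
external partial it extends. All percentages are computed from the count
cells with round-half-up to two decimals (base R's `round()` rounds half
to even, which cannot reproduce conventionally rounded published shares).

## The synthetic test bed

The `fixtures` module generates every input file with planted ground
truth, under a fixed seed (byte-identical across runs):

* **Homology tables** place the planted EC on close-lineage homologues
  (6 of 7 shared ranks) and a distractor EC on distant-lineage ones, so
  the taxonomy-weighted default $\alpha$ selects the planted function even
  when the distractor is more frequent — exercising precisely the
  property the score exists for.
* **Evidence bundles** realize one planted curation path per gene (L, A,
  B1 with agreeing or disagreeing entries, restricted or unrestricted
  fallback); planted false-positive EEGCs get confident hits and *no*
  evidence, so the tree must discard exactly them.
* **The toy TC database** draws each family's sequences from a residue
  group whose BLOSUM62 cross-scores against every other family's group
  are non-positive (e.g. hydrophobic `LIVM` versus charged `DEKR` versus
  aromatic `FYW`). Cross-family local alignments therefore score exactly
  zero while within-family mutated copies score near one, making planted
  transporter calls exact at any helix-scaled threshold. This is a
  testing device, not sequence evolution: for *real* protein pairs the
  optimal local alignment's positive fraction is high (often 0.5–1.0)
  even between unrelated sequences, because the aligner is free to report
  a short, dense segment. On real data the positives-per-column
  similarity is therefore a weak discriminator on its own, and threshold
  choice (or the identities-per-column alternative, or score-based
  normalization) deserves a sensitivity analysis that the configurable
  parameters support. Passing the planted-recovery tests demonstrates the
  pipeline's wiring and determinism, not alignment-based discrimination
  power on natural sequences.
* **Noise knobs**: a per-hit EC-corruption probability (half erasures,
  half distractor swaps) degrades automatic-selection accuracy, and a
  per-locus evidence-dropout probability costs recall; both degradations
  are asserted (in expectation over seeds) by the suite.

Two named scenarios fix the study conditions. `tiny` (30 loci, seconds)
flattens the curation-path mix so every branch runs. `paper-shaped`
(5085 loci, tens of seconds) plants a genome-scale funnel: 2000 revised
candidates splitting into 1699 EEGCs (of which 241 planted false
positives) and 301 exclusively transporter genes, yielding 1759 metabolic
genes (1410 enzymatic-only, 301 transporter-only, 48 dual); curation
paths weighted so roughly 81% of metabolic genes resolve through
*S. cerevisiae* homologues, about 2.5% through other organisms, and a
handful through literature; transporter families weighted so about 70% of
transporter loci are class-2 porters. These mirror the shape of a
published yeast re-annotation and are the package's fixed reference
conditions; the acceptance script reruns them from scratch and reports
the recovered counts. Problem sizes throughout (100-hit cap, 12 planted
hits per gene, 150-residue reference sequences, 15-entry toy TC database)
were chosen so the full genome-scale run completes in well under a minute
on one CPU.

## Known limitations

* Everything upstream of the hit tables — running BLAST or TMHMM,
  retrieving live database records — is out of scope by design; garbage
  hit tables yield garbage annotations.
* The taxonomy score treats all lineage ranks uniformly; rank-weighted
  variants are plausible and unexplored here.
* The similarity threshold heuristic is one defensible instantiation of
  an undisclosed rule (see above); its constants are configurable rather
  than authoritative.
* The GenBank writer emits the LOCUS/CDS subset of the format (with
  `/EC_number` per INSDC convention and TC payloads in `/note`, which has
  no standard qualifier); it does not attempt nucleotide sequence or
  non-CDS features.
* EC "class 7" (translocases) postdates the six-class scheme this
  toolkit's classification tables assume; a leading digit outside 1–6 is
  carried but not classified.
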