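---
title: "Modeling cancer variants, disease overlays and therapeutics in pathvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cancer variants, disease overlays and therapeutics in pathvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathvar)
```

## The model

`pathvar` treats a pathway as a set of reactions ("events") that convert
input physical entities into outputs, optionally catalyzed, with events
grouped into pathways that may nest. A disease variant of a protein is an
*entity with an accessioned sequence*: a reference accession, the retained
coordinate range, and an ordered list of typed modifications. All
coordinates are 1-based and ranges are inclusive at both ends, the
convention of protein sequence databases; a deletion of residues 463..466
therefore removes exactly `466 - 463 + 1 = 4` residues.

Five modification kinds cover the recurring classes of cancer mutation:

| kind                 | models            | length effect              |
|----------------------|-------------------|----------------------------|
| replaced residue     | missense          | none                       |
| fragment deletion    | in-frame deletion | − (end − start + 1)        |
| fragment insertion   | insertion; fusion fragment | + payload length  |
| truncation           | nonsense          | trims to `new_end`         |
| frameshift           | frameshift        | trims to `position − 1`, + tail |

A nonsense mutation written `R130*` is modeled as truncation with
`new_end = 129`: the stop replaces residue 130, so the product retains
residues 1..129. A frameshift `795fs*139STOP` keeps residues 1..794 and
appends 139 novel residues; their identities are unknown (only their count
is recorded), so sequence construction emits `X` for each. A fusion protein
is a truncated host plus a single insertion anchored at
`host_range$end + 1` whose payload is a range of the partner's reference
sequence; `build_fusion()` constructs both the entity and the residue
string, and such entities classify as `Translocation`.

## Coordinate anchoring and application order

Every modification is anchored in *reference* coordinates. Published variant
names state positions on the wild-type sequence; renumbering after an
upstream deletion is never implied, and the naming of compound variants
(e.g. `E746_A750del; T790M`, where 790 is a wild-type coordinate) only makes
sense under reference anchoring. `apply_modifications()` therefore edits a
positional map of the reference rather than a running product string:
deletions and truncations mark reference positions dropped, insertions
attach their payload immediately before a reference position, replacements
rewrite a position, and the product is read off at the end. This makes the
result independent of the order in which modifications are listed.

Degenerate inputs are rejected rather than resolved silently: overlapping
deletion ranges and a replacement inside a deleted range are conflicts,
and any stated wild-type residue (the `L` of `L858R`, deletion and insertion
flanks, the residue replaced by a stop) is checked against the reference,
with mismatches reported by coordinate, expected and found residue. These
checks are the main safety net when variants from a catalogue are applied to
sequences from elsewhere: a silent off-by-one would otherwise corrupt every
downstream residue.

## The nomenclature and its canonical form

The token grammar (`GENE descriptor[;descriptor...]`) covers missense,
range/single deletion, deletion-insertion (`delins`), insertion between
adjacent residues, nonsense, frameshift (with or without the leading
amino acid), fusions (`GENE1-GENE2`), and registry aliases. Three choices
deserve explanation:

* **delins** is represented as a deletion plus an insertion anchored at the
  deletion start, with the insertion flagged as the insert half of a delins
  so that mutation-type classification reports only `Deletion` — the
  convention the variant catalogue itself uses for its delins rows.
* **Compound spelling**: tokens written `"...del; T790M"` and
  `"...del;T790M"` both occur in the wild. The parser accepts both; the
  formatter emits the no-space form as canonical. String round-trips are
  therefore exact for every corpus token except the single row printed with
  the space, which round-trips to its canonical spelling.
* **Isoforms and aliases**: a trailing single lowercase letter on the gene
  token (`FGFR2b`) is an isoform designator mapped to its own reference
  accession, since splice forms differ in the very regions some variants
  fall in. Named aliases such as `EGFRvIII` carry no coordinates in the
  name; the bundled registry supplies curator-provided coordinates
  (a deletion of residues 6..273 for EGFRvIII) and is the single place such
  knowledge lives.

`parse_variant_token(format_variant(p))` reproduces `p` exactly for every
parseable variant, and parsing is whitespace-insensitive and deterministic.

## Disease annotation and propagation

Disease terms are Disease Ontology identifiers with a label and an optional
NCIt cross-reference; they are opaque — no ontology file is parsed and no
reasoning is done, which keeps the package self-contained and makes the
annotation robust to ontology revisions. A term attached to a physical
entity is propagated to every event whose inputs, outputs or catalysts
include it, to every pathway containing such an event, and transitively up
the containment tree (the containment relation is validated acyclic at
construction). Propagation only ever adds terms, so it is monotone and
idempotent; both properties are exercised on randomized graphs in the test
suite. Disease-centric queries over the variant corpus match free text
case-insensitively as substrings of the `";"`-normalized disease list —
free-text disease names differ in granularity ("glioblastoma" vs. "adult
glioblastoma multiforme"), and substring matching tolerates that without a
curated synonym table.

## Wild-type and disease views of a shared diagram

A single diagram is shared between a wild-type pathway and its disease
counterpart; `compute_view()` returns one render state per diagram node:

* wild-type mode: disease-tagged events are `hidden`, along with entities
  appearing *only* in disease-tagged events; everything else is `visible`;
* disease mode: disease-tagged events and entities are
  `disease_highlighted` (the red outline of the diseased diagram) and all
  untagged nodes are `faded` (gray shading of the normal events).

Two interpretation points are worth flagging. First, the treatment of
*entities* in the wild-type view is not forced by the event rule; the rule
here — an entity shared between normal and disease events stays visible,
only disease-exclusive entities hide — follows from the premise that the
diagram is shared, so removing a shared node would break the wild-type
picture. An entity participating in no event keeps its default
(visible/faded) state. Second, render states attach to entities and events
only: pathway groupings organize the event hierarchy but are not drawn as
diagram nodes. In each mode the states partition the node set, and the
wild-type view's visible and hidden sets together cover it exactly; both are
property-tested.

## Therapeutics

Therapeutics are small molecules or recombinant antibodies with an ordered
target-specificity list, a binding mode, and a pathway. Small-molecule
TKIs classify along spectrum × reversibility: *specific* when the
specificity list is exactly the anchor receptor, *broad* otherwise
(the "receptor-plus" spectrum); *reversible* for non-covalent binders,
*irreversible* for covalent ones. Mutant sensitivity sets map onto this:
mutants sensitive to reversible TKIs are inhibited by non-covalent drugs;
mutants resistant to them are inhibited by covalent drugs — which at the
required concentrations also inhibit the wild-type receptor, so a covalent
TKI never reports `not_inhibited`; wild-type-overexpressing tumors are the
antibody's indication. Combinations outside these rules return `unknown`
rather than a guess.

Specificity cells in the transcribed corpus mix individual targets
(`EGFR`), family designators (`Pan-ERBB`, `Pan-FGFR`, `PI3K Class I`) and
isoform-level targets (`FGFR2b`, `FGFR3`). `target_covers()` interprets
these with a small family table (ERBB = EGFR/ERBB2/ERBB3/ERBB4,
FGFR = FGFR1–4, PI3K = PIK3CA/CB/CD/CG): a query matches a token if it
equals it, appears as a word within it, lies in a family the token
designates, or — when the query names a family — the token is a member
(isoform suffix ignored). Word-level matching also absorbs the two
typographic irregularities preserved verbatim from the source table
(`"VEGFR. KIT"`, `"FGFR VEGFR"`). Matching is deliberately not substring
matching: `EGFR` must not match `VEGFR`.

The corpus's `binding_mode` column is a curator-supplied annotation (the
published table lists only name, identifier, specificity and pathway):
gefitinib, erlotinib, lapatinib and vandetanib bind EGFR non-covalently;
afatinib, canertinib, HKI-272, pelitinib and WZ4002 covalently; wortmannin
and PX-866 are covalent PI3K inhibitors; the remaining small molecules are
annotated non-covalent and antibodies `not_applicable`.

## Synthetic reference sequences

The bundled corpus names coordinates on real proteins, but the package
never downloads sequences. `generate_fixture_references()` emits, for every
gene (+ isoform) in a variant table, a deterministic pseudo-random sequence
that (i) covers the gene's maximum variant coordinate plus a 10-residue
margin, and (ii) carries the stated wild-type residue at every stated
coordinate — `L` at EGFR 858, `Y`/`L` at PIK3R1 463/466, and so on,
collected from every parsed token. Conflicting demands at one coordinate
abort generation with the conflict listed, which doubles as an internal
consistency check of the corpus. Genes contributing no coordinates (fusion
hosts and partners) receive 600-residue sequences, a typical receptor-
fragment scale. The same seed yields byte-identical FASTA.

These synthetic references emulate exactly what the sequence operations
need — lengths and constrained residues — and nothing else: they have no
domain structure, no realistic composition, and no homology to the real
proteins. Tests passing on them demonstrate correct coordinate arithmetic,
residue validation and edit semantics; they say nothing about biological
properties of the real sequences, which is the intended division of labor
since every operation is a pure function of the residue string.

## Problem sizes and numerical choices

The test suite works at desk scale by design: the full 151-row variant
corpus and 41-row therapeutic corpus are exercised directly (every token
parsed, every non-fusion variant applied to its synthetic reference);
randomized property tests use sequences of length 50 with up to 5
modifications (60 + 40 instances), and 20 + 10 random pathway graphs of
4–8 entities and 2–5 events. The independent oracle for sequence edits is
plain right-to-left substring surgery, kept deliberately separate from the
positional-map implementation. There is no floating-point arithmetic
anywhere; all comparisons are exact.

## Limitations

* Nucleotide-level events (the translocations themselves, exon
  coordinates, genome-coordinate nomenclature) are out of scope; the model
  starts at the protein.
* Fusions are limited to one partner fragment appended to a truncated
  host — the only pattern in the corpus; multi-segment fusions would need
  an extended representation.
* Disease terms are opaque: overlapping or near-synonymous terms are kept
  as annotated, and no normalization across ontologies is attempted.
* Three-letter amino-acid spellings and full HGVS are not parsed.
* Rendering is abstract: view states serialize to JSON, and producing
  actual diagrams (SBGN or otherwise) is left to downstream tools.
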