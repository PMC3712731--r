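# pathvar

Protein-level annotation of cancer-perturbed signaling pathways, for
curators and computational biologists working with reaction-centric pathway
models (pathways as chains of reactions converting input physical entities
into outputs).

Cancer variants perturb these pathways in a handful of recurring ways:
missense substitutions (EGFR L858R), in-frame deletions (PIK3R1
Y463_L466del), insertions (EGFR D770_N771insNPG), nonsense truncations
(PTEN R130\*), frameshifts (FGFR3 795fs\*139STOP), and translocation-derived
fusion proteins (BCR-FGFR1). `pathvar` models each as a typed modification
of a reference protein sequence — a *replaced residue* at coordinate *c*
(from → to), a *fragment deletion* of the inclusive range *[s, e]* (removing
*e − s + 1* residues), a *fragment insertion* whose payload is a peptide or
a fragment of another reference sequence, a truncation to a new end
coordinate, or a frameshift yielding a tail of unknown residues — so a
mutant protein is just a reference accession, a retained coordinate range
and an ordered modification list. A fusion protein is a truncated host
(residues 1..*k*) plus an insertion anchored at *k + 1* pointing into the
partner sequence.

On top of the sequence model the package provides:

* **Nomenclature** — a parser/formatter for the variant-token dialect above,
  with mutation-type classification (`Missense`, `Deletion`, `Insertion`,
  `Nonsense`, `Frameshift`, `Translocation`, and `"; "`-joined compounds).
* **Disease annotation** — Disease Ontology terms attached to pathway
  entities and propagated to every reaction they participate in and
  transitively up the pathway-containment tree, plus disease-centric queries
  and opaque COSMIC/DO/ChEBI cross-references.
* **Pathway overlay** — render states for a diagram shared between a
  wild-type pathway and its disease counterpart: the wild-type view hides
  disease events (and disease-exclusive entities); the disease view
  highlights tagged nodes and fades the rest.
* **Therapeutics** — a model of tyrosine kinase inhibitors and recombinant
  antibodies classified by target spectrum (receptor-specific vs. broad)
  × binding reversibility (non-covalent vs. covalent), with mutant-set
  sensitivity rules (mutants resistant to reversible TKIs are inhibited by
  irreversible ones; antibodies act on wild-type-overexpressing tumors).
* **Corpora** — transcriptions of a published catalogue of 151 cancer
  variants and 41 anti-cancer therapeutics, and a generator of synthetic
  reference sequences consistent with every variant coordinate in the
  corpus, so nothing is fetched from the network.

## Worked example

```r
library(pathvar)

p <- parse_variant_token("EGFR L858R")
classify_mutation_type(p)
#> [1] "Missense"

variants <- read_variant_table()
nrow(variants)
#> [1] 151
query_by_disease(variants, "glioblastoma")
#> [1] "EGFR"   "FGFR1"  "IDH1"   "PIK3CA" "PIK3R1" "PTEN"

refs <- generate_fixture_references(variants, seed = 42)
rec  <- variants[variants$display_name == "PIK3R1 Y463_L466del mutant", ]
ent  <- variant_record_to_entity(rec, refs = refs)
nchar(refs$SYN_PIK3R1$residues) - nchar(apply_modifications(refs$SYN_PIK3R1, ent))
#> [1] 4        # the deletion removes four residues

host   <- refs$SYN_BCR                        # synthetic stand-ins
insert <- reference_sequence("SYN_FGFR1_LONG", "FGFR1",
                             strrep("G", 832))
fus <- build_fusion(host, sequence_range(1, 584),
                    insert, sequence_range(429, 822))
fus$entity$modifications[[1]]$position
#> [1] 585      # partner fragment inserted at host position 585
nchar(fus$residues)
#> [1] 978      # 584 retained host residues + 394 partner residues

drugs <- read_therapeutic_table()
length(filter_therapeutics(drugs, pathway = "Signaling by EGFR in Cancer",
                           kind = "small_molecule",
                           target_includes = "EGFR"))
#> [1] 9        # the anti-EGFR tyrosine kinase inhibitors
```

A thin command-line wrapper is installed as `exec/pathvar`
(subcommands `parse`, `mutate`, `fuse`, `query-disease`, `view`, `drugs`,
`gen-refs`, `validate`).

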