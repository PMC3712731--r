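Package: pathvar
Title: Disease Variant and Therapeutic Annotation for Cancer Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for annotating cancer-perturbed signaling pathways at the
    protein level. Parses the protein-variant nomenclature used for missense,
    deletion, insertion, nonsense, frameshift and fusion mutants into typed
    modification records; constructs mutant and fusion protein sequences from
    reference sequences; tags pathway entities with Disease Ontology terms and
    propagates them to reactions and parent pathways; computes wild-type versus
    disease render states for shared pathway diagrams; and models anti-cancer
    therapeutics (tyrosine kinase inhibitors and recombinant antibodies) with
    target-specificity and binding-mode classification plus mutant-set
    sensitivity rules. Ships transcribed corpora of published cancer variants
    and therapeutics together with a generator for synthetic reference
    sequences consistent with every variant coordinate.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
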