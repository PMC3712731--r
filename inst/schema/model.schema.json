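{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "pathvar model document",
  "type": "object",
  "required": ["format", "version", "entities", "graphs", "therapeutics"],
  "properties": {
    "format": {"const": "pathvar-model"},
    "version": {"type": "integer"},
    "entities": {"type": "array", "items": {"$ref": "#/definitions/variant_entity"}},
    "graphs": {"type": "array", "items": {"$ref": "#/definitions/pathway_graph"}},
    "therapeutics": {"type": "array", "items": {"$ref": "#/definitions/therapeutic"}}
  },
  "definitions": {
    "sequence_range": {
      "type": "object",
      "required": ["start", "end"],
      "properties": {
        "start": {"type": "integer", "minimum": 1},
        "end": {"type": "integer", "minimum": 1}
      }
    },
    "modification_spec": {
      "type": "object",
      "required": ["type"],
      "properties": {
        "type": {"enum": ["replaced_residue", "fragment_deletion",
                           "fragment_insertion", "truncation", "frameshift"]},
        "coordinate": {"type": "integer", "minimum": 1},
        "from_aa": {"type": "string", "pattern": "^[A-Z]$"},
        "to_aa": {"type": "string", "pattern": "^[A-Z]$"},
        "range": {"$ref": "#/definitions/sequence_range"},
        "position": {"type": "integer", "minimum": 1},
        "peptide": {"type": "string", "pattern": "^[A-Z]+$"},
        "source_accession": {"type": "string"},
        "source_range": {"$ref": "#/definitions/sequence_range"},
        "from_delins": {"type": "boolean"},
        "new_end": {"type": "integer", "minimum": 1},
        "stop_residue": {"type": ["string", "null"]},
        "tail_length": {"type": "integer", "minimum": 0},
        "ref_residue": {"type": ["string", "null"]}
      }
    },
    "disease_term": {
      "type": "object",
      "required": ["do_id", "name"],
      "properties": {
        "do_id": {"type": "integer", "exclusiveMinimum": 0},
        "name": {"type": "string", "minLength": 1},
        "ncit_xref": {"type": ["string", "null"]}
      }
    },
    "variant_entity": {
      "type": "object",
      "required": ["gene", "reference_accession", "ref_range",
                    "modifications", "display_name"],
      "properties": {
        "gene": {"type": "string"},
        "isoform": {"type": ["string", "null"]},
        "reference_accession": {"type": "string"},
        "ref_range": {"$ref": "#/definitions/sequence_range"},
        "modifications": {"type": "array",
                           "items": {"$ref": "#/definitions/modification_spec"}},
        "display_name": {"type": "string"},
        "diseases": {"type": "array",
                      "items": {"$ref": "#/definitions/disease_term"}},
        "cosmic_ids": {"type": "array", "items": {"type": "string"}},
        "pathway_name": {"type": "string"}
      }
    },
    "therapeutic": {
      "type": "object",
      "required": ["name", "kind", "reference_id", "specificity",
                    "binding_mode"],
      "properties": {
        "name": {"type": "string"},
        "kind": {"enum": ["small_molecule", "recombinant_antibody"]},
        "reference_id": {"type": "string"},
        "specificity": {"type": "array", "minItems": 1,
                         "items": {"type": "string"}},
        "binding_mode": {"enum": ["covalent", "non_covalent",
                                    "not_applicable"]},
        "pathway_name": {"type": "string"}
      }
    },
    "pathway_graph": {
      "type": "object",
      "required": ["entities", "events", "pathways"],
      "properties": {
        "entities": {"type": "array", "items": {
          "type": "object", "required": ["id", "name"],
          "properties": {
            "id": {"type": "string"}, "name": {"type": "string"},
            "diseases": {"type": "array",
                          "items": {"$ref": "#/definitions/disease_term"}}
          }}},
        "events": {"type": "array", "items": {
          "type": "object", "required": ["id", "name"],
          "properties": {
            "id": {"type": "string"}, "name": {"type": "string"},
            "inputs": {"type": "array", "items": {"type": "string"}},
            "outputs": {"type": "array", "items": {"type": "string"}},
            "catalysts": {"type": "array", "items": {"type": "string"}},
            "diseases": {"type": "array",
                          "items": {"$ref": "#/definitions/disease_term"}}
          }}},
        "pathways": {"type": "array", "items": {
          "type": "object", "required": ["id", "name", "events"],
          "properties": {
            "id": {"type": "string"}, "name": {"type": "string"},
            "events": {"type": "array", "items": {"type": "string"}},
            "parent": {"type": ["string", "null"]}
          }}}
      }
    }
  }
}
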