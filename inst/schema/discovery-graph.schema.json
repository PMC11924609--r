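{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Discovery graph interchange document",
  "description": "One document per discovery graph: entities, pairwise statements, hyperedges, reified handles and nested entities. Ids are strings; entity ids are normalized labels.",
  "type": "object",
  "required": ["entities", "statements", "hyperedges", "handles", "nested"],
  "properties": {
    "pmid": {"type": ["string", "null"]},
    "statement_text": {"type": ["string", "null"]},
    "entities": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "kind"],
        "properties": {
          "id": {"type": "string", "minLength": 1},
          "label": {"type": "string"},
          "kind": {"enum": ["SIMPLE", "NESTED", "HANDLE"]},
          "role_tags": {
            "type": "array",
            "items": {"enum": ["FINDING", "CONTEXT", "EXPERIMENTAL_MODEL",
                               "METHOD", "MODIFIER", "GENERAL_CONCEPT",
                               "PROCESS", "PLAIN"]}
          },
          "pmid": {"type": ["string", "null"]}
        }
      }
    },
    "statements": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "subject", "predicate", "object", "directed"],
        "properties": {
          "id": {"type": "string"},
          "subject": {"type": "string"},
          "predicate": {"type": "string"},
          "object": {"type": "string"},
          "directed": {"type": "boolean"}
        }
      }
    },
    "hyperedges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "members"],
        "properties": {
          "id": {"type": "string"},
          "members": {
            "type": "array",
            "minItems": 2,
            "items": {"type": "string"}
          },
          "label": {"type": ["string", "null"]}
        }
      }
    },
    "handles": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["handle", "hyperedge"],
        "properties": {
          "handle": {"type": "string"},
          "hyperedge": {"type": "string"}
        }
      }
    },
    "nested": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["owner", "body_statements", "body_entities"],
        "properties": {
          "owner": {"type": "string"},
          "body_statements": {"type": "array", "minItems": 1,
                              "items": {"type": "string"}},
          "body_entities": {"type": "array", "minItems": 1,
                            "items": {"type": "string"}}
        }
      }
    }
  }
}
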