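{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "pddikit annotation document",
  "description": "Open-Annotation-inspired interchange for drug and PDDI mentions: each annotation has a target (section id plus position selector with exact quoted text) and a typed body. Character offsets are 0-based, half-open; sentence indices refer to the corpus's canonical segmentation.",
  "type": "object",
  "required": ["format", "source", "annotations"],
  "properties": {
    "format": { "const": "pddikit-annotation/v1" },
    "source": {
      "type": "object",
      "required": ["id", "kind"],
      "properties": {
        "id": { "type": "string" },
        "kind": { "enum": ["reference", "nlp", "human"] }
      }
    },
    "annotations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "target", "body"],
        "properties": {
          "id": { "type": "string" },
          "target": {
            "type": "object",
            "required": ["section"],
            "properties": {
              "section": { "type": "string" },
              "sentences": {
                "type": "array",
                "items": { "type": "integer", "minimum": 0 }
              },
              "selector": { "$ref": "#/definitions/textPositionSelector" }
            }
          },
          "body": {
            "oneOf": [
              { "$ref": "#/definitions/drugMentionBody" },
              { "$ref": "#/definitions/pddiMentionBody" }
            ]
          }
        }
      }
    }
  },
  "definitions": {
    "textPositionSelector": {
      "type": "object",
      "required": ["type", "start", "end", "exact"],
      "properties": {
        "type": { "const": "TextPositionSelector" },
        "start": { "type": "integer", "minimum": 0 },
        "end": { "type": "integer", "minimum": 1 },
        "exact": { "type": "string" }
      }
    },
    "drugReference": {
      "type": "object",
      "required": ["id", "entity_type"],
      "properties": {
        "id": { "type": "string" },
        "entity_type": { "enum": ["active_ingredient", "metabolite", "drug_product"] }
      }
    },
    "drugMentionBody": {
      "type": "object",
      "required": ["type", "entity_type", "concept_id"],
      "properties": {
        "type": { "const": "DrugMention" },
        "entity_type": { "enum": ["active_ingredient", "metabolite", "drug_product"] },
        "concept_id": { "type": "string" },
        "normalized_ingredient_id": { "type": "string" },
        "unmapped_product": { "type": "boolean" }
      },
      "additionalProperties": true
    },
    "pddiMentionBody": {
      "type": "object",
      "required": ["type", "precipitant", "object", "statement", "modality"],
      "properties": {
        "type": { "const": "PDDIMention" },
        "precipitant": { "$ref": "#/definitions/drugReference" },
        "object": { "$ref": "#/definitions/drugReference" },
        "statement": { "enum": ["quantitative", "qualitative"] },
        "modality": { "enum": ["positive", "negative"] },
        "uid": { "type": "string" }
      },
      "additionalProperties": true
    }
  }
}
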