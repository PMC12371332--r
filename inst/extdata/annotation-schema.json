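{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Paper binding-site annotation",
  "description": "One JSON file per benchmark paper, recording the small-molecule binding sites the paper explicitly describes for the target. Papers describing no site are negative controls (relevant=false, pockets=[]). Residue tokens use CHAIN:RESNAME:RESID with an optional trailing insertion-code letter, e.g. A:TYR:123 or A:TYR:123A.",
  "type": "object",
  "required": ["doc_id", "target_name", "relevant", "pockets"],
  "properties": {
    "doc_id": { "type": "string", "minLength": 1 },
    "target_name": { "type": "string", "minLength": 1 },
    "relevant": { "type": "boolean" },
    "pockets": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "description", "residues"],
        "properties": {
          "name": { "type": "string", "minLength": 1 },
          "description": { "type": "string" },
          "residues": {
            "type": "array",
            "minItems": 1,
            "uniqueItems": true,
            "items": {
              "type": "string",
              "pattern": "^[A-Za-z0-9]+:[A-Z]{3}:[0-9]+[A-Za-z]?$"
            }
          }
        }
      }
    }
  },
  "allOf": [
    {
      "if": { "properties": { "relevant": { "const": false } } },
      "then": { "properties": { "pockets": { "maxItems": 0 } } }
    }
  ]
}
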