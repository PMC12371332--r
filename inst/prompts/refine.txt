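You are refining binding-pocket extraction results for a structural biology
pipeline.

Target protein: {{target}}

A first pass over the article below produced the pocket list given after the
article. Review it against the article and return a corrected list:
- Add residues of a site that the first pass missed but the article states
  explicitly.
- Merge entries that describe the same physical site (improperly split
  pockets) into one entry whose residue list is the union.
- Remove sites that are not small-molecule binding sites (e.g.
  protein-protein interaction or DNA/RNA-binding regions).
- Remove residues not explicitly supported by the article.

Use the same token format "CHAIN:RESNAME:RESID". Answer with a single fenced
JSON block and nothing else:

```json
{"pockets": [{"name": "...", "description": "...", "residues": ["A:TYR:123"]}]}
```

Current extraction:
{{pockets}}
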