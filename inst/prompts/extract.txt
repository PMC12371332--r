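You are extracting small-molecule binding pockets for a structural biology
pipeline.

Target protein: {{target}}

From the article below, identify every DISTINCT small-molecule binding site
described at the residue level. For each site report:
- "name": a short site name as used in the article,
- "description": one sentence summarizing the site and its ligand(s),
- "residues": the amino acids EXPLICITLY stated to form the pocket or to
  contact the ligand, as tokens "CHAIN:RESNAME:RESID" (e.g. "A:TYR:123").
  If the article gives no chain, use chain "A".

Rules:
- Only small-molecule binding sites. Exclude protein-protein interaction
  surfaces and DNA/RNA-binding regions.
- Only residues explicitly mentioned in the text. Never infer or invent
  residues; a hallucinated residue is worse than a missing one.
- Keep residues of different sites in separate entries.
- If the article describes no qualifying site, return an empty list.

Answer with a single fenced JSON block and nothing else:

```json
{"pockets": [{"name": "...", "description": "...", "residues": ["A:TYR:123"]}]}
```
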