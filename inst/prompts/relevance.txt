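You are screening research articles for a structural biology pipeline.

Target protein: {{target}}

Decide whether the article below is relevant for binding-pocket extraction.
An article is relevant only if BOTH hold:
1. It describes the target protein named above (not merely a homolog in passing).
2. It contains a residue-level description of at least one small-molecule
   binding site (explicit residue identifiers such as Tyr123 or A:TYR:123).

Sites that only involve protein-protein interaction surfaces or DNA/RNA
binding do NOT count. Do not guess: if no residues are explicitly listed,
the article is not relevant.

Answer with a single fenced JSON block and nothing else:

```json
{"relevant": true, "reasons": "<one short sentence>"}
```
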