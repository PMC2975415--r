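# Bundled curated histone data

`histones_human_curated.fasta` / `histones_human_curated_sites.tsv` and the
`arabidopsis` pair are a small curated stand-in for the human and
*Arabidopsis thaliana* histone training inventories, provided so that
full-inventory runs of the predictor need no network access.

Provenance and caveats:

* Sequences are mature core-histone sequences (initiator methionine
  removed).  Human H3.1 and H4 are canonical; the Arabidopsis H3 and H4
  entries reproduce the documented species differences (H3: positions 31,
  87 and 90, giving 97.8% identity and a 14th lysine; H4: positions 60 and
  72, 98.0% identity).
* The H2B and H2A variant entries are partly **synthetic constructions**:
  the Arabidopsis H2B N-terminal tails and the H2A.4 C-terminal extension
  (carrying K144) are built to have the documented qualitative features
  (tail-localized acetylation, variant count, approximate identity), not
  transcribed from database records.
* Site labels follow widely reported histone acetylation sites (`P`) with
  every remaining lysine labeled `N` (not observed acetylable), matching
  the semi-supervised labeling convention of the predictor.  They are an
  approximate reconstruction, not the original experimental tables.

Format: FASTA headers carry `species=`, `family=`, `variant=` tags; the
annotation tables are tab-separated with columns `id`, `position`,
`label`.  Load with `curated_histones("human")` /
`curated_histones("arabidopsis")`.
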