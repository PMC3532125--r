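# extdata

- `synthetic_compendium.tsv` — a **synthetic** stand-in for a curated
  drug–gene chemosensitivity compendium, constructed to have the canonical
  summary structure of such a resource: 150 distinct drug–gene pairs over
  64 drugs and 94 genes, with cell-line, PMID and description columns.
  Three rows are deliberate duplicates so the loader's pair-level
  deduplication is exercised. The drug and gene names are a mix of real
  oncology vocabulary and clearly synthetic fillers (`NSC…`, `SYGN…`);
  none of the records is a literature claim.
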