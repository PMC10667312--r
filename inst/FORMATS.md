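# File formats

All files are plain text, tab-separated unless noted.

## Segment map (`segment_map.tsv`)

BED-convention intervals (0-based half-open), one row per loxPsym-delimited
segment, ordered left telomere to right telomere and tiling the chromosome
without gaps or overlaps.

| column | type | meaning |
|---|---|---|
| chrom | string | chromosome name |
| start | int | 0-based start |
| end | int | exclusive end |
| id | string | unique segment id |
| centromere | 0/1 | exactly one row flagged 1 |
| marker | string | selection-marker label or `.` |
| arm | string | `left`, `right` or `centromeric` |
| genes | string | semicolon-separated gene labels or `.` |

## Structure words (`structures.tsv`)

One strain per line:
`<strain id>\ttopology:<linear|circular>\t<word>` where the word is a
comma-separated list of signed segment ids (`S05,-S07,S08`; a leading `-`
marks an inverted occurrence).  Word positions are 1-based.  A JSON
serialization (`structureToJson`) carries the same two fields.

## Evidence (`<base>.segments.tsv`, `<base>.junctions.tsv`, `<base>.header.json`)

* segments: `id`, `depth` (synthetic-specific read depth per reference
  segment).
* junctions: `end_a`, `end_b` (oriented segment ends, `<id>.l` / `<id>.r`,
  pair sorted), `support` (read count, >= 1).
* header JSON: `baseline` (single-copy linear depth), `wt_reads`,
  `syn_reads`, `wt_syn_ratio`, `topology_hint`.

## Association scan (`association_scan.tsv`)

One row per segment: `segment`, `meanDeleted`, `meanRetained`,
`statistic` (Welch t), `p`, `pBonferroni`, `pass` (family-wise flag),
`nDeleted`, `nRetained`, `reason` (`NA` for tested segments, otherwise why
the segment was untestable, e.g. `no contrast`).

## Run report (`report.json`)

Validated by `inst/schema/report-schema.json`; top-level sections
`provenance` (config hash, seed, package version), `population`,
`classification`, `ploidy`, `fitness`, `associationScan`, `esr`.
Deterministic: no wall-clock fields, so identical config + seed gives a
byte-identical file.

## Growth curves and colony sizes (inputs)

* growth curves: `time_min`, `od600` — uniform 20-minute grid, OD > 0.
* colony sizes: `strain`, `colony_mm` — one row per colony.
* expression counts: genes x strains matrix, first column gene id.
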