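{
  "transcript": "SYNTHETIC-ABCA4-LIKE-1",
  "comment": "Synthetic transcript/domain model for demonstrations and tests. Coding-sequence length and protein size mimic the scale of ABCA4 (6822-nt CDS, 2273-aa protein) but exon boundaries and domain ranges are invented; this is NOT the NM_000350 gene model.",
  "exons": [
    {"index": 1, "cdna_start": 1, "cdna_end": 700},
    {"index": 2, "cdna_start": 701, "cdna_end": 1400},
    {"index": 3, "cdna_start": 1401, "cdna_end": 2100},
    {"index": 4, "cdna_start": 2101, "cdna_end": 2800},
    {"index": 5, "cdna_start": 2801, "cdna_end": 3500},
    {"index": 6, "cdna_start": 3501, "cdna_end": 4200},
    {"index": 7, "cdna_start": 4201, "cdna_end": 4900},
    {"index": 8, "cdna_start": 4901, "cdna_end": 5600},
    {"index": 9, "cdna_start": 5601, "cdna_end": 6300},
    {"index": 10, "cdna_start": 6301, "cdna_end": 6822}
  ],
  "domains": [
    {"name": "TMD1", "aa_start": 1, "aa_end": 350},
    {"name": "ECD1", "aa_start": 351, "aa_end": 950},
    {"name": "NBD1", "aa_start": 951, "aa_end": 1400},
    {"name": "TMD2", "aa_start": 1401, "aa_end": 1700},
    {"name": "ECD2", "aa_start": 1701, "aa_end": 2000},
    {"name": "NBD2", "aa_start": 2001, "aa_end": 2273}
  ]
}
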