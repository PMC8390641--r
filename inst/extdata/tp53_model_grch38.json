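{
  "chrom": "chr17",
  "junction_roles": {
    "cterm_ref": "NM_001126114.2",
    "utr5_ref": "NM_001126112.2",
    "gamma_refs": ["NM_001126113.2", "NM_001276695.2", "NM_001126117.1", "NM_001276699.2"]
  },
  "transcripts": [
    {
      "id": "NM_000546.6", "name": "p53alpha", "strand": "-", "role": "main",
      "exons": [[7687377, 7687490], [7676521, 7676622], [7676382, 7676403],
                [7675994, 7676272], [7675053, 7675236], [7674859, 7674971],
                [7674181, 7674290], [7673535, 7673701], [7673229, 7673339],
                [7670609, 7670715], [7668402, 7669690]]
    },
    {
      "id": "NM_001126114.2", "name": "p53beta", "strand": "-", "role": "alternative",
      "exons": [[7687377, 7687490], [7676521, 7676622], [7676382, 7676403],
                [7675994, 7676272], [7675053, 7675236], [7674859, 7674971],
                [7674181, 7674290], [7673535, 7673701], [7673229, 7673339],
                [7672268, 7672357], [7671739, 7671867]]
    },
    {
      "id": "NM_001276696.2", "name": "delta40p53beta", "strand": "-", "role": "alternative",
      "exons": [[7687377, 7687490], [7676382, 7676622],
                [7675994, 7676272], [7675053, 7675236], [7674859, 7674971],
                [7674181, 7674290], [7673535, 7673701], [7673229, 7673339],
                [7672268, 7672357], [7671739, 7671867]]
    },
    {
      "id": "NM_001126116.1", "name": "delta133p53beta", "strand": "-", "role": "alternative",
      "exons": [[7675053, 7675700], [7674859, 7674971],
                [7674181, 7674290], [7673535, 7673701], [7673229, 7673339],
                [7672268, 7672357], [7671739, 7671867]]
    },
    {
      "id": "NM_001276698.2", "name": "delta160p53beta", "strand": "-", "role": "alternative",
      "exons": [[7675053, 7675650], [7674859, 7674971],
                [7674181, 7674290], [7673535, 7673701], [7673229, 7673339],
                [7672268, 7672357], [7671739, 7671867]]
    },
    {
      "id": "NM_001126113.2", "name": "p53gamma", "strand": "-", "role": "alternative",
      "exons": [[7687377, 7687490], [7676521, 7676622], [7676382, 7676403],
                [7675994, 7676272], [7675053, 7675236], [7674859, 7674971],
                [7674181, 7674290], [7673535, 7673701], [7673229, 7673339],
                [7671278, 7671444]]
    },
    {
      "id": "NM_001276695.2", "name": "delta40p53gamma", "strand": "-", "role": "alternative",
      "exons": [[7687377, 7687490], [7676382, 7676622],
                [7675994, 7676272], [7675053, 7675236], [7674859, 7674971],
                [7674181, 7674290], [7673535, 7673701], [7673229, 7673339],
                [7671278, 7671444]]
    },
    {
      "id": "NM_001126117.1", "name": "delta133p53gamma", "strand": "-", "role": "alternative",
      "exons": [[7675053, 7675700], [7674859, 7674971],
                [7674181, 7674290], [7673535, 7673701], [7673229, 7673339],
                [7671278, 7671444]]
    },
    {
      "id": "NM_001276699.2", "name": "delta160p53gamma", "strand": "-", "role": "alternative",
      "exons": [[7675053, 7675650], [7674859, 7674971],
                [7674181, 7674290], [7673535, 7673701], [7673229, 7673339],
                [7671278, 7671444]]
    },
    {
      "id": "NM_001126112.2", "name": "p53alpha-altUTR", "strand": "-", "role": "alternative",
      "exons": [[7687377, 7687490], [7676521, 7676619], [7676382, 7676403],
                [7675994, 7676272], [7675053, 7675236], [7674859, 7674971],
                [7674181, 7674290], [7673535, 7673701], [7673229, 7673339],
                [7670609, 7670715], [7668402, 7669690]]
    }
  ]
}
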