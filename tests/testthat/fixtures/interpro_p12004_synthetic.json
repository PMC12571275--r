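{
  "count": 2,
  "note": "synthetic stand-in for an InterPro entry/pfam/protein/uniprot payload, for parser tests",
  "results": [
    {
      "metadata": {
        "accession": "PF00705",
        "name": "Proliferating cell nuclear antigen, N-terminal domain",
        "type": "domain"
      },
      "proteins": [
        {
          "accession": "p12004",
          "entry_protein_locations": [
            { "fragments": [ { "start": 1, "end": 125 } ] }
          ]
        }
      ]
    },
    {
      "metadata": {
        "accession": "PF02747",
        "name": "Proliferating cell nuclear antigen, C-terminal domain",
        "type": "domain"
      },
      "proteins": [
        {
          "accession": "p12004",
          "entry_protein_locations": [
            { "fragments": [ { "start": 135, "end": 255 } ] }
          ]
        }
      ]
    }
  ]
}
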