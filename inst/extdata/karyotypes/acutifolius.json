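{
  "genotype": "P. acutifolius",
  "chromosomes": ["pa1", "pa2", "pa3", "pa4", "pa5", "pa6", "pa7", "pa8", "pa9", "pa10", "pa11"],
  "assignments": [
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "pa1",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "pa2",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa1",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa2",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa3",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa4",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa5",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa6",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa1",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa2",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa3",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa4",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa5",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pa6",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    }
  ],
  "assumptions": ["Which numbered chromosome carries which centromeric signal is unknowable without chromosome-specific markers in these species; ids are arbitrary.", "Five chromosome pairs show very weak or no khipu signal; they are encoded with none."],
  "annotations": []
}
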