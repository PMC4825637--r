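{
  "genotype": "P. dumosus",
  "chromosomes": ["pc1", "pc2", "pc3", "pc4", "pc5", "pc6", "pc7", "pc8", "pc9", "pc10", "pc11"],
  "assignments": [
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "pc1",
      "position_class": "centromere",
      "intensity": "strong"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "pc2",
      "position_class": "centromere",
      "intensity": "strong"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "pc3",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "pc4",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "pc5",
      "position_class": "centromere",
      "intensity": "weak"
    },
    {
      "probe": "CentPv2",
      "channel": "red",
      "chrom": "pc6",
      "position_class": "centromere",
      "intensity": "strong"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc1",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc2",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc3",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc4",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc5",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc6",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc7",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc8",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc9",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc10",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc11",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc1",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc2",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc3",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc4",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc5",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc6",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc7",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc8",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc9",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc10",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "pc11",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    }
  ],
  "assumptions": ["Which numbered chromosome carries which centromeric signal is unknowable without chromosome-specific markers in these species; ids are arbitrary.", "khipu marks most termini uniformly with no distinctively strong locus."],
  "annotations": []
}
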