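{
  "genotype": "G19833",
  "chromosomes": ["chr1", "chr2", "chr3", "chr4", "chr5", "chr6", "chr7", "chr8", "chr9", "chr10", "chr11"],
  "assignments": [
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "chr1",
      "position_class": "centromere",
      "intensity": "strong"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "chr3",
      "position_class": "centromere",
      "intensity": "strong"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "chr4",
      "position_class": "centromere",
      "intensity": "strong"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "chr7",
      "position_class": "centromere",
      "intensity": "strong"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "chr2",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "chr8",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "chr9",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv1",
      "channel": "blue",
      "chrom": "chr10",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv1_A",
      "channel": "green",
      "chrom": "chr8",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv1_B",
      "channel": "red",
      "chrom": "chr3",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv2",
      "channel": "red",
      "chrom": "chr5",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv2",
      "channel": "red",
      "chrom": "chr6",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv2",
      "channel": "red",
      "chrom": "chr11",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv2_A",
      "channel": "green",
      "chrom": "chr11",
      "position_class": "centromere",
      "intensity": "medium"
    },
    {
      "probe": "CentPv2_A",
      "channel": "green",
      "chrom": "chr5",
      "position_class": "centromere",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr4",
      "position_class": "subtelomere_S",
      "intensity": "strong"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr11",
      "position_class": "subtelomere_L",
      "intensity": "medium"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr1",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr2",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr3",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr6",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr7",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr9",
      "position_class": "subtelomere_S",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr3",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr9",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "khipu",
      "channel": "red",
      "chrom": "chr10",
      "position_class": "subtelomere_L",
      "intensity": "weak"
    },
    {
      "probe": "5S_rDNA",
      "channel": "green",
      "chrom": "chr10",
      "position_class": "arm_S",
      "intensity": "medium"
    },
    {
      "probe": "BAC_0100C06",
      "channel": "green",
      "chrom": "chr7",
      "position_class": "arm_S",
      "intensity": "medium"
    }
  ],
  "assumptions": ["Intensities use the ordinal scale none < weak < medium < strong; prose qualifiers (strong, middle-strength/secondary, minor/weak) map onto it directly.", "The 5S rDNA locus position (chr10, short arm) and the set of termini carrying minor subtelomeric khipu signals are fixture assumptions: they are shown only in figures, not stated in prose.", "Signatures are per chromosome pair; homolog-level differences are carried as annotations, not records."],
  "annotations": []
}
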