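# karyoprobe

`karyoprobe` implements the in-silico side of a FISH-based karyotyping
system for plant genomes, modelled on the common bean (*Phaseolus
vulgaris*, 2n = 22) system: a probe mixture of centromeric satellite
repeats (CentPv1, CentPv2 and their chromosome-specific variants),
the subtelomeric repeat *khipu*, 5S rDNA and chromosome-specific BAC
clones that lets every chromosome pair be identified under the
microscope. It is aimed at plant cytogeneticists who have a
chromosome-scale assembly and want to design and reason about such a
probe cocktail before ordering oligos.

The package covers four computational problems:

1. **BAC anchoring and selection.** BAC end-sequence hits against
   pseudo-chromosomes are filtered at identity > 99% and query coverage
   > 90% (coverage = alignment length / query length); end pairs on the
   same chromosome, on opposite strands with the `+` hit upstream (ends
   facing inward), whose outer span lies in 50–200 kb, anchor the clone.
   With 1-based inclusive coordinates the insert length is
   `last − first + 1`, and the physical position along the chromosome is
   `100 · ((first + last)/2) / L`. Candidates for FISH need repeat
   content < 20% and no tandem-repeat overlap, and are ranked by
   `min(p, 100 − p)` — proximity to a chromosome end.
2. **Chromosome-specific satellite variants.** Centromeric arrays are
   decomposed into monomers by greedy consensus tiling (identity ≥ 70%);
   every length-*k* monomer window (default k = 25, the oligo probe
   length) is counted per chromosome, and a window is called *specific*
   when it is abundant on one chromosome (count ≥ 5, on-target fraction
   ≥ 0.95) and differs from the consensus — the route by which a variant
   confined to one centromere becomes a discriminating probe.
3. **Oligo probes and cocktails.** Candidate oligos are enumerated over
   polymorphic windows; genome-wide specificity is the per-chromosome
   count of binding sites on both strands within Hamming distance d
   (default 2 — hybridization tolerates mismatches). Cocktail assembly
   maps fluorophores to imaging channels (FAM/fluorescein → green,
   TEX615/Texas Red → red, Cy5 → blue) and warns when two same-channel
   probes target the same locus class on the same chromosome — such
   signals are visually confounded.
4. **Karyotype signal maps.** A karyotype map is a set of
   (chromosome, position class, channel, intensity) records with
   per-probe provenance; same-channel co-located signals merge to the
   maximum intensity. A chromosome is *distinguishable* under a probe
   subset when its signature — the set of (position class, channel,
   intensity) triples — is unique. Maps can be diffed across accessions
   and species (gain / loss / intensity change). Encoded signal tables
   for seven *Phaseolus* genotypes ship with the package.

A seeded synthetic-genome generator (planted centromeric arrays with
variant monomers, subtelomeric arrays with varying copy number, BAC
libraries with recorded placements) provides ground truth for every
stage.

## Worked example

```r
library(karyoprobe)

# anchored-clone arithmetic on the bundled reference BAC table
ref <- kp_bac_reference()
kp_insert_length(ref$first_base[1], ref$last_base[1])
#> [1] 143631

# how many chromosomes do probe subsets distinguish in the reference map?
g <- kp_karyotype_fixture("g19833")
g
#> <kp_karyotype> G19833: 11 chromosomes, 28 signal records from 8 probe(s)
four <- kp_distinguishable(g, c("CentPv1", "CentPv2", "CentPv1_A", "CentPv2_A"))
four$count                                   # 4  (chromosomes 5, 6, 8, 11)
six <- kp_distinguishable(g, c("CentPv1", "CentPv2", "CentPv1_A", "CentPv2_A",
                               "khipu", "5S_rDNA"))
six$count                                    # 11 (all chromosome pairs unique)

# recover a planted chromosome-specific satellite variant from a
# synthetic genome, then screen it genome-wide as an oligo probe
gen <- kp_generate_genome(kp_genome_spec(seed = 7))
cen <- subset(gen$truth$arrays, class == "centromere")
arrays <- tibble::tibble(
  id = cen$chrom,
  seq = substr(setNames(gen$genome$seq, gen$genome$id)[cen$chrom],
               cen$start, cen$end))
monomers <- kp_monomer_sets(arrays, gen$truth$satellite_consensus)
calls <- kp_detect_variants(kp_variant_profile(monomers, k = 25))
dplyr::count(calls, status, target_chrom)
#>   status         target_chrom     n
#> 1 consensus_like chr1            26
#> 2 specific       chr3            26

canonical <- with(kp_truth_windows(gen$truth, k = 25), window[canonical])
counts <- kp_oligo_hits(canonical, gen$genome, d = 2)
counts
#>  chr1  chr2  chr3  chr4  chr5  chr6  chr7  chr8  chr9 chr10 chr11
#>     0     0    12     0     0     0     0     0     0     0     0
kp_specificity(counts, "chr3")
#>   on_target off_target on_target_fraction decision
#> 1        12          0                  1 accept
```

The variant screen calls exactly the windows of the planted variant
monomer `specific` on chromosome 3 (26 windows of the 50-bp monomer each
cover at least one planted polymorphism); the genome-wide count shows
the candidate oligo binds only the 12 variant monomer copies on
chromosome 3, so it is accepted as a chromosome-3-specific probe — the
in-silico analogue of a probe hybridizing to a single pair of
centromeres.

A command-line wrapper over the same functions ships at
`inst/cli/karyoprobe.R` (subcommands `simulate`, `anchor`, `screen`,
`variants`, `oligo`, `karyotype`); see `?kp_run`.

## Further reading

The methods vignette (`vignettes/karyoprobe-methods.Rmd`) describes the
signal model and its assumptions, the selection and detection
thresholds, what the synthetic generator does and does not emulate, and
the package's design choices.
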