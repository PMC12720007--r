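# telopeaks

Telomeric repeat content and overlap analysis of genomic peak sets.

## The problem

Long non-coding RNAs such as TERRA (the telomeric repeat–containing RNA)
can occupy chromatin far from the loci that transcribe them. One proposed
mechanism is R-loop formation: the RNA hybridises with genomic DNA wherever
the sequence is complementary — for TERRA, wherever the genome carries
tandem telomeric repeats. Testing that hypothesis from sequencing data
reduces to a small set of reusable questions about two peak sets (an RNA
occupancy map *A* and an R-loop map *B*, both as BED/narrowPeak files):

1. **Do A and B co-locate more than chance allows?** A peak of *A* is
   *shared* if it intersects a peak of *B* by at least one base pair
   (0-based half-open BED arithmetic), *unique* otherwise. Significance is
   assessed by a constrained permutation test: each of *n* permutations
   re-places every peak uniformly on its own chromosome, preserving peak
   number, sizes and chromosome distribution, and recomputes the shared
   count *S*. The empirical p-value is
   `p = #{S_perm >= S_obs} / n` (with the `(r+1)/(n+1)` estimator reported
   alongside, since the raw proportion can be zero).
2. **Are the shared peaks distinguished by telomeric repeat content?**
   Every peak's sequence is scanned for the exact hexamers `TTAGGG` and
   `CCCTAA`; maximal zero-gap, strand-pure series of units form *tandem
   runs*, and each peak is typed: **I** no repeats, **II** one repeat,
   **III** several but scattered (no run of ≥ 4 units), **IV** exactly one
   run of ≥ 4 units, **V** several such runs. Summary statistics contrast
   shared vs unique peaks: fraction with ≥ 1 repeat, fraction of all
   repeat occurrences, medians, tandem-filter pass rates, and a Welch
   t-test on per-peak repeat counts.
3. **Where do the shared peaks sit?** Midpoint-based annotation against
   BED12 gene models (promoter–TSS > TTS > exon > intron > intergenic
   precedence, HOMER-like windows), nearest-TSS gene association, and
   overlap of associated genes with an external (e.g. knockdown
   differential-expression) gene list.

Because real CHIRT-seq/DRIP-seq data are external and large, the package
also ships a synthetic-fixture generator: a desk-scale genome with a
verifiably motif-free background, planted tandem arrays of known size and
position, two peak sets with a designed overlap fraction and repeat
enrichment concentrated in the designed shared peaks, toy gene models, and
a `truth.json` that predicts every bookkeeping quantity exactly.

## Worked example

```r
library(telopeaks)

cfg <- synth_config(chrom_lengths = setNames(rep(2e6, 3), paste0("chr", 1:3)),
                    n_arrays = 30, n_peaks_a = 200, n_peaks_b = 200,
                    target_overlap_fraction = 0.15,
                    fraction_shared_on_arrays = 0.5,
                    subtel_margin = 2e5, n_genes = 40, seed = 42,
                    exact_bookkeeping = TRUE)
write_fixture(cfg, "fixture")
fixt <- read_fixture("fixture")
an <- peak_overlap_analysis(fixt$a, fixt$b, genome = fixt$genome,
                            chromsizes = fixt$chromsizes, genes = fixt$genes,
                            n_perm = 1000, seed = 1)
print(an)
```

```
peak_overlap_analysis
overlap_result (min overlap 1 bp)
  TERRA: 30 shared / 170 unique of 200
  RLOOP: 30 shared / 170 unique of 200
  30 overlapping pair(s)
Repeat-content summary (tandem threshold 4 units)
  shared peaks: 30; with >=1 repeat: 15 (50%)
  unique peaks: 170; with >=1 repeat: 0 (0%)
  >1 repeat among repeat-bearing shared: 14 (93.3%), median 8
  =1 repeat among repeat-bearing unique: 0 (0%), median NA
  repeat share: shared 100% / unique 0%
  tandem filter pass: shared 14 (46.7%), unique 0 (0%)
Annotation of shared peaks:
     category count percentage
 promoter_tss     0    0.00000
         exon     4   13.33333
       intron     5   16.66667
          tts     0    0.00000
   intergenic    21   70.00000
Permutation test of peak overlap (TERRA vs RLOOP)
  statistic: shared, min overlap 1 bp, 1000 permutations (both)
  observed = 30, null = 7.18 +/- 2.69
  p (empirical) = 0, p (pseudocount) = 0.000999, z = 8.49
```

Reading the output: the 30 designed shared peaks are recovered exactly
(exact bookkeeping suppresses chance collisions); under the constrained
null only ~7 shared peaks are expected, so no permutation reaches the
observed 30 and the raw empirical p is 0 (pseudocount 1/1001). Repeat
occurrences concentrate entirely in shared peaks — half of them planted on
arrays — and the 14 peaks whose planted array reaches 4 tandem units pass
the tandem filter. `write_report(an, "out/")` writes the JSON/TSV bundle;
`null_summary`, `per_chromosome_counts`, `length_summary`,
`annotation_breakdown` and `gene_list_overlap` expose the individual
tables.

On real data, replace the fixture by `read_bed()` on your narrowPeak
files, `read_chrom_sizes()`, a genome FASTA, `read_gene_models()` on a
BED12, and optionally `exclude_regions()` with a blacklist plus
`subtelomere_regions()` (500 kb terminal margins by default).

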