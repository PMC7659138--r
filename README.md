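# LinkedReadTools

Metagenome assembly from linked-read (10x-style barcoded) sequencing is
governed by a small parameter vector, and choosing it well matters more
than raw sequencing effort. **LinkedReadTools** is an R/Bioconductor-style
toolkit for exploring that parameter space on microbial communities with
uneven abundance. It is aimed at people planning or evaluating linked-read
metagenome experiments: it simulates libraries with known ground truth,
recovers the parameter vector from barcode-aware alignments, produces
depth-titration series by subsampling, and triages assembly bins into
draft-genome quality tiers.

## The model

A linked-read library is described by four parameters (plus read geometry):

| symbol | meaning |
|--------|---------|
| `C_R`    | average short-read depth per long fragment (X) |
| `C_F`    | physical depth of the genome by long DNA fragments (X) |
| `N_F/P`  | average number of fragments per barcode partition |
| `mu_FL`, `Wmu_FL` | unweighted / length-weighted mean fragment length (`Wmu_FL = Σ L² / Σ L`) |

with the total read depth tied by `C = C_R × C_F`. For a community with
relative abundances `A_i` (molarities normalized to sum to 1) over `G`
genomes, the physical depth is spread as `C_Fi = C_F × A_i × G`, and the
fragment-length budget per genome is `M_i = C_Fi × L_i`.

Long fragments are reconstructed from co-barcoded alignment coordinates by
greedy extension: sort by barcode then position, terminate a fragment when
the nearest co-barcoded read is more than 50 kb away, keep fragments with
at least two read pairs spanning at least 2 kb. Bins are classified
HIGH / MEDIUM / LOW / OTHER from completeness, contamination, rRNA
presence and tRNA count, with HIGH+MEDIUM+LOW counting as draft genomes,
and bin abundance computed as `size(bin)·dp(bin) / (len(read)·sum(read))`.

## Worked example

Estimate the parameter vector of a small fragment set:

```r
library(LinkedReadTools)
st <- estimateStats(data.frame(length = c(2000, 8000),
                               n_read_pairs = c(2, 8),
                               barcode = c("b1", "b2")),
                    readLength = 150, genomeSize = 1e6)
st
#> LinkedReadStats
#>   C    =    0.003X   (total read bases / genome size)
#>   C_R  =    0.300X   (unweighted; length-weighted 0.300X)
#>   C_F  =    0.010X
#>   mu_FL =    5000 bp  W_mu_FL =    6800 bp
#>   N_F/P =    1.00    (2 fragments / 2 barcodes, 10 read pairs)
```

Both fragments carry 0.3X of reads, so `C_R = 0.3X`; the length-weighted
mean length (6,800 bp) exceeds the plain mean (5,000 bp) because long
fragments carry more of the DNA. At `C_F = 28X` and a target `C = 10X`,
the implied per-fragment depth is `impliedCR(C = 10, CF = 28)` → `0.36`.

Classify bins and summarize an assembly:

```r
bins <- data.frame(completeness = c(96, 95, 70, 40, 60),
                   contamination = c(2, 3, 6, 5, 15),
                   has_5S  = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                   has_16S = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                   has_23S = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                   n_tRNA = c(20, 19, 9, 3, 2),
                   size_bp = c(2.9e6, 2.2e6, 1.4e6, 0.8e6, 3.0e6))
classifyBin(bins)
#> [1] HIGH   MEDIUM MEDIUM LOW    OTHER
summarizeAssembly(bins, config = "example")[, c("n_bins", "high", "medium",
                                                "low", "other", "draft_pct")]
#>   n_bins high medium low other draft_pct
#> 1      5    1      2   1     1        80
```

The second bin is 95% complete at 3% contamination but lacks a 16S rRNA,
so it is MEDIUM, not HIGH; the draft-genome proportion counts everything
except OTHER.

The full loop — synthetic community → simulated barcoded FASTQ →
reconstruction from true read coordinates → parameter recovery → bin
triage — is packaged as `runDemo(outDir, seed)`:

```
== parameter recovery report ==
  configured: C_F = 20X, C_R = 0.77X (C = 15.4X), mu_FL = 10000, N_F/P = 1
  truth:      C = 22.35X, C_F = 28.94X, C_R = 0.769X, mu_FL = 9967, N_F/P = 1.57
  recovered:  C = 22.29X, C_F = 26.38X, C_R = 0.855X, mu_FL = 9553, N_F/P = 1.50
  reconstruction recall = 0.852, precision = 0.896 (overlap 0.8)
  draft-genome proportion of demo bins: 66.67%
```

(The truth `C_F` exceeds the configured 20X because the demo community is
staggered: pooled physical depth is abundance-weighted, while `mean(C_Fi)`
equals the configured value.)

A thin command-line wrapper is installed at `inst/scripts/linkedsim`:

```sh
Rscript inst/scripts/linkedsim simulate --community community.tsv --out sim/ \
    --c-f 28 --c-r 0.36 --seed 1
Rscript inst/scripts/linkedsim reconstruct --alignments aln.tsv --dialect tsv --out frags.tsv
Rscript inst/scripts/linkedsim binqc --bins bins.tsv --out summary.tsv
```

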