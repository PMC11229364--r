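# sammycomp

Chromatin A/B compartments and eight-level sub-compartments from
biochemical fractionation sequencing (SAMMY-seq), with a parallel Hi-C
path for comparison.

## What it does and for whom

The genome segregates into an active, accessible **A** compartment and
an inactive, compacted **B** compartment. Hi-C infers this segregation
from pairwise contact frequencies. Sequential chromatin fractionation
offers an orthogonal readout: chromatin is extracted in fractions of
decreasing solubility (DNase-digested material size-separated into
short **S2S** and long **S2L** pools, a high-salt **S3** extract, and
the urea-solubilized **S4** residue), each fraction is sequenced, and
every genomic bin acquires an m-vector of RPKM coverage across
fractions. Bins sharing a nuclear neighbourhood share a biochemical
milieu and hence a fraction profile.

`sammycomp` is for computational (epi)genomicists who have binned
fraction coverage (bedGraph) and, optionally, raw Hi-C bin-pair counts,
and want compartment and sub-compartment calls plus quantitative
concordance between the two assays.

The core computation, per chromosome:

1. build a bin-bin similarity matrix `C` — Pearson correlation of the
   m-dimensional fraction vectors (fraction path), or of the rows of
   the ICE-balanced, observed/expected-normalized contact matrix
   (Hi-C path), after removing null bins;
2. extract the first eigenvector **E1** of `C` via uncentered, scaled
   PCA (columns scaled to unit RMS about zero);
3. orient the sign by gene density (gene-dense group = A), scale by
   max |E1|: bins with E1 > 0 are **A**, E1 < 0 are **B**;
4. for sub-compartments (50 kb bins): Euclidean distances between
   fraction vectors, profile correlation, windowed boundary detection,
   a binary trend matrix of domain profiles embedded in 10 principal
   components, deterministic bisecting 2-means (depth 3, up to 8
   leaves), and lowess-projection ranking into the ordered labels
   `B.2.2 < B.2.1 < B.1.2 < B.1.1 < A.2.2 < A.2.1 < A.1.2 < A.1.1`.

Concordance between callsets is scored by the per-label Jaccard index,
eigenvector Pearson correlation (per chromosome and genome-wide), and
per-bin discordance classes (A-A, B-B, A→B, B→A). A built-in simulator
generates fraction tracks, toy contact matrices, genes and chromatin
states from one latent openness field so everything is testable
end to end.

## Worked example

```r
library(sammycomp)

sim <- simulateScenario(seed = 7, bins = 600)   # 600 x 50 kb, 2 chromosomes

# fraction path at 250 kb
sammy <- compartmentsFromFractions(rebinFractions(sim$fractions, 250000),
                                   sim$truth$genes)
sammy
#> CompartmentCall: 120 bins; A = 59 B = 61 NA = 0

# Hi-C path on the simulated contacts
hic <- compartmentsFromContacts(sim$contacts, sim$truth$genes)

rep <- concordanceReport(hic, sammy)
rep$jaccard$overall        # 0.818  (mean of J(A) = 0.810, J(B) = 0.826)
rep$pearson$genome         # 0.863  eigenvector correlation, shared bins
rep$discordance$counts
#>  A-A  B-B A->B B->A
#>   51   57    4    8

# sub-compartments at 50 kb on the fraction path
sub <- subCompartmentsFromFractions(sim$fractions, sim$truth$genes)
table(subCompartmentLabels(sub))
#> B.2.2 B.2.1 B.1.2 B.1.1 A.2.2 A.2.1 A.1.2 A.1.1
#>   239    60     0     0     0     0    95   206
```

The two paths agree on 108 of 120 shared bins here; the Jaccard and
eigenvector correlations quantify that agreement, and the discordance
classes say in which direction the 12 disagreements go (reference =
Hi-C, so `A->B` means active by Hi-C, inactive by the fraction path).
Against the simulation's known openness field, the sub-compartment
ranks reach Spearman 0.907 on this seed.

A thin command-line wrapper with `simulate`, `bin`, `compartments`,
`subcompartments` and `concordance` subcommands is installed at
`system.file("cli/sammycomp.R", package = "sammycomp")`.

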