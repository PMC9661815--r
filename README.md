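# fourgamete

Exact two-locus haplotype phasing for SNP pairs that **fail the four-gamete
test**, and the analyses it unlocks: direct linkage-disequilibrium
estimation, haplotyping of recombination-free chromosomal regions, and a
third-haplotype mixed-model GWAS.

## Who this is for

Population and livestock geneticists working with diploid biallelic SNP
data — especially from closed or highly drifted populations where many SNP
pairs carry only two or three of the four possible haplotypes. For such
pairs the usual obstacle to phasing (the AaBb double heterozygote) vanishes:
the phase is *forced*, and haplotype frequencies, LD and haplotype-based
association tests become exact counting problems instead of iterative
estimation.

## The idea

Tabulate the two-locus genotype counts n_ij in a 3×3 table (rows AA/Aa/aa,
columns BB/Bb/bb). Each corner block of three cells contains exactly the
unambiguous genotypes carrying one haplotype, so an all-zero corner
identifies the absent haplotype:

| empty corner | missing haplotype | forced phase of AaBb |
|--------------|-------------------|----------------------|
| I            | AB                | Ab/aB                |
| II           | Ab                | AB/ab                |
| III          | aB                | AB/ab                |
| IV           | ab                | Ab/aB                |

With phases fixed, frequencies are gamete counts over 2N, e.g. with AB
missing f_Ab = (2 n_AAbb + n_AABb + n_Aabb + n_AaBb) / 2N, and

D = f_AB·f_ab − f_Ab·f_aB,  D′ = D / D_max,  r² = D² / (f_A f_a f_B f_b).

Three applications are built on this primitive:

1. **Direct LD** per pair, with an Excoffier–Slatkin EM baseline for
   comparison; pairs where the two disagree (|Δr²| ≥ 0.04) are flagged as
   likely genotyping errors.
2. **Region haplotyping**: maximal intervals in which *every* SNP pair fails
   the four-gamete test are phased end-to-end by chaining pairwise phases,
   giving a multi-allelic marker scored by PIC and heterozygosity.
3. **Third-haplotype GWAS**: when three haplotypes segregate, single-marker
   tests tag only two of them; the third is tested on its exact 0/1/2 copy
   number under y = Wb + xg + a + e with a VanRaden GRM, REML variance
   components (spectral, EMMAX-style) and Benjamini–Hochberg FDR control
   with an effective number of tests.

## A worked example

The two SNPs at 39,631,490 and 39,638,306 bp on pig chromosome 2, with only
three observed genotypes — AABB: 382, AABb: 17, AaBb: 36 (N = 435):

```r
library(fourgamete)
counts <- matrix(0L, 3, 3, dimnames = list(c("AA","Aa","aa"), c("BB","Bb","bb")))
counts["AA","BB"] <- 382L; counts["AA","Bb"] <- 17L; counts["Aa","Bb"] <- 36L
pt <- pair_table_from_counts(counts)
st <- detect_corners(pt)
#> Warning: adjacent corners III, IV all empty; corner IV selected by
#> precedence (IV > III > II > I); phasing is ambiguous
st
#> corner_status: 3 haplotype(s) segregating
#>   empty corner(s): III, IV
#>   missing haplotype(s): ab
#>   double-heterozygote phase: Ab/aB
#>   (ambiguous: tie broken by corner precedence)
haplotype_freqs_direct(pt, st)
#> haplotype_freqs (corners):
#>     AB     Ab     aB     ab
#> 0.8977 0.0609 0.0414 0.0000
#>   missing: ab
#>   (ambiguous corner tie)
r2_direct(pt, st)
#> ld_result (corners): D = -0.0025, D' = -1, r2 = 0.0028
em <- em_haplotype_freqs(pt); round(em$f, 2)
#>   AB   Ab   aB   ab
#> 0.94 0.02 0.00 0.04
ld_from_freqs(em)
#> ld_result (em): D = 0.0389, D' = 1, r2 = 0.6654
```

Both corners III and IV are empty — an ambiguous tie. The precedence rule
treats ab as missing and phases all 36 double heterozygotes Ab/aB, giving
haplotype frequencies (0.90, 0.06, 0.04, 0.00) and r² ≈ 0.003, while the EM
maximum-likelihood solution puts the mass on ab instead (0.94, 0.02, 0.00,
0.04; r² ≈ 0.665). A discrepancy this large is exactly what
`compare_methods()` flags: the genotype counts are internally inconsistent,
pointing to a genotyping error at one of the two SNPs.

Region haplotyping on the package's shipped nine-SNP example
(`ssc1_example()`, six haplotypes):

```r
ex <- ssc1_example()
pic(ex$pool$frequency)            # 0.724
heterozygosity(ex$pool$frequency) # 0.760
```

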