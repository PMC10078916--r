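# hybridclass

Full-likelihood Bayesian classification of diploid individuals into six
two-generation genealogical classes — pure population A, pure population B,
F1 hybrid, F2 hybrid, and the two backcrosses — from biallelic SNP data on
**linked** markers. It is aimed at conservation and population geneticists
who need to call recent hybrids (e.g. across a hybrid zone) from genomic
sequence data, where the classical assumption of independently assorting
loci does not hold.

## The model in brief

A non-inbred two-generation pedigree has four purebred founders; the 16
founder-population assignments collapse under parent/founder exchange into
six genealogical classes *a*–*f*. For each class, the likelihood of the
individual's diplotype (pair of haplotypes per chromosome) is exact:

* Crossovers follow a no-interference Poisson process, so the population
  origin of a marker switches across an interval of map length *m* Morgans
  with probability `P(m) = (1 − e^(−2m))/2` (Haldane).
* A recombinant chromosome's ancestry state *z* ∈ {0,1}^L has prior
  `Q(z | d, r)`: an equal mixture over the two founder origins times
  change/no-change probabilities per inter-marker interval.
* Given *z*, a haplotype's probability is the product over maximal
  constant-ancestry segments of the matching population's marginal
  sub-haplotype frequency, and the recombinant likelihood is
  `L(x) = Σ_z f(x|z) Q(z|d,r)` — evaluated by an exact segment dynamic
  program rather than the naive 2^L enumeration.
* Class likelihoods combine pure-haplotype frequencies (Hardy–Weinberg
  style) and recombinant likelihoods per chromosome, multiply across
  chromosomes, and feed Bayes' rule under a configurable prior (uniform
  1/6 by default). Unphased test individuals are handled by exact phase
  integration over all compatible diplotypes.
* Population haplotype frequencies are estimated from phased reference
  panels by the Dirichlet(1/H)–multinomial posterior mean
  `(n_h + 1/H)/(1 + 2N)`.

The package also implements the unlinked composite-likelihood baseline
(per-locus genotype probabilities with known allele frequencies, no MCMC),
a factorial simulator of the study conditions, and calibration / power /
ROC metrics for comparing the two methods.

## Worked example

Classify a simulated F1 hybrid from 10 chromosomes, each with 10 markers
spanning 50 cM, with haplotype frequencies estimated from reference panels:

```r
library(hybridclass)
set.seed(7)
maps <- lapply(1:10, function(i)
  makeDesignMap(L = 10, R = 50, chrom = paste0("chr", i)))
tables <- lapply(1:10, function(i) {
  pA <- simulateHaplotypePanel(h = 10, L = 10, c = 0.1)
  pB <- simulateHaplotypePanel(h = 10, L = 10, c = 0.1)
  estimateFreqTable(rep(pA, 4), rep(pB, 4), chrom = paste0("chr", i),
                    L = 10)
})
ind <- simulateIndividual("c", tables, maps)
posteriorOverClasses(ind, maps, tables)
#> ClassPosterior (MAP class: c )
#>      a      b      c      d      e      f
#> 0.0000 0.0049 0.9906 0.0000 0.0037 0.0009
```

The posterior concentrates on class *c* (F1): virtually all mass is on the
true class, with the small remainder on the adjacent backcross/F2 classes,
which share recombinant chromosomes with the F1's children. Comparing the
full likelihood with the unlinked composite baseline on 2,000 simulated
individuals (10 chromosomes, 5 linked markers each):

```r
sim <- simulateDataset(n = 2000, K = 10, L = 5, R = 25, h = 5, c = 0.1)
full <- classifyIndividuals(sim$hapM, sim$hapP, sim$maps, sim$tables)
af <- do.call(rbind, lapply(sim$tables, alleleFrequencies))
comp <- classifyComposite(
  genotypesFromHaplotypes(sim$hapM, sim$hapP, rep(5L, 10)), af$pA, af$pB)
sapply(c("a","b","c","d","e","f"), function(g)
  c(full = rocAuc(full, sim$classes, g),
    composite = rocAuc(comp, sim$classes, g)))
#>               a     b     c     d     e     f
#> full      0.997 0.981 0.994 0.999 0.978 0.957
#> composite 0.969 0.867 0.909 0.976 0.852 0.811
```

The full-likelihood ROC dominates the composite baseline for every class;
the gap is largest for the backcross and F2 classes, where linkage carries
most of the signal.

A thin command-line wrapper over these functions is installed at
`inst/scripts/hybridclass-cli.R` (subcommands `simulate`, `infer`,
`baseline`, `estimate-freqs`, `evaluate`).

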