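# emsnv

An ensemble single-nucleotide-variant (SNV) caller for diploid genomes.
`emsnv` treats the aligned read bases covering each reference position as
votes cast by an *ensemble of learners* — strata of reads grouped by base
quality — and estimates each learner's reliability **without any labeled
data** using expectation–maximization. Candidate variants from the EM
genotyper are then screened by a shallow (depth ≤ 5) decision tree. The
package also contains a seeded read simulator with planted ground-truth
SNVs, a genotype-aware precision/recall/F1 evaluator, and a command-line
interface, so the whole call–evaluate loop is reproducible end to end.

## The model in brief

At each locus the diploid genotype is one of ten unordered allele pairs
over {A,C,G,T}: `AA CC GG TT AC AG AT CG CT GT`. Learner *j* (a
base-quality bin, default Q0–9 / Q10–19 / Q20–29 / Q30+) emits base *b*
under true genotype *k* with probability θ<sub>j</sub>(b | k); genotype
priors π<sub>r</sub>(k) are conditioned on the reference base *r*. Given
per-locus, per-learner base counts n<sub>ijb</sub>, the class posterior is

> q<sub>i</sub>(k) ∝ π<sub>r(i)</sub>(k) · ∏<sub>j,b</sub> θ<sub>j</sub>(b | k)<sup>n<sub>ijb</sub></sup>

and θ, π are fitted by EM with Dirichlet (pseudocount) smoothing, the
E step running in log space over pattern-collapsed loci. A locus is an SNV
candidate when the posterior-argmax genotype differs from homozygous
reference. Candidates carry four features — genotype, depth, alternate
allele fraction, and posterior Shannon entropy (bits) — on which the
CART filter is trained against a truth set. Full derivations, numerical
choices, and the simulator's noise model are in the methods vignette,
`vignettes/emsnv-methods.Rmd`.

## Worked example

Simulate a 20 kb diploid genome at 30× coverage, call variants with the
two-step pipeline, and score the calls against the planted truth:

```r
library(emsnv)

sim <- run_simulate(seed = 7, genome_length = 20000L, dir = "demo")
res <- run_call(sim$fasta, sim$sam, out = "demo/calls.vcf")
nrow(res$candidates); nrow(res$kept)
#> [1] 18
#> [1] 18

run_eval("demo/calls.vcf", sim$truth_vcf)
#> eval_report: TP=18 FP=0 FN=0 | precision=1.0000 recall=1.0000 f1=1.0000

head(res$kept[, c("pos", "ref", "genotype", "depth",
                  "alt_fraction", "entropy_bits", "post_prob")], 4)
#>    pos ref genotype depth alt_fraction entropy_bits post_prob
#> 1 2718   A       AC    29    0.5862069 4.684846e-10 1.0000000
#> 2 3178   G       TT    32    1.0000000 3.410550e-07 1.0000000
#> 3 3711   G       AA    24    1.0000000 3.130456e-08 1.0000000
#> 4 5331   A       CC    19    1.0000000 2.554712e-04 0.9999855
```

(Candidate tables use 0-based positions internally; the VCF writer emits
the standard 1-based coordinates.) The output VCF begins:

```text
##fileformat=VCFv4.2
##source=emsnv
##contig=<ID=sim1,length=20000>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth at the locus">
##INFO=<ID=AF,Number=1,Type=Float,Description="Fraction of reads with a non-reference base">
##INFO=<ID=ENT,Number=1,Type=Float,Description="Shannon entropy (bits) of the 10-class genotype posterior">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SAMPLE
sim1	2719	.	A	C	99	PASS	DP=29;AF=0.58620689655172409;ENT=4.684846331679249e-10	GT	0/1
sim1	3179	.	G	T	79.24	PASS	DP=32;AF=1;ENT=3.4105495298865221e-07	GT	1/1
```

The same pipeline is available from a shell:

```sh
Rscript inst/cli/emsnv.R simulate --seed 7 --genome-length 20000 --out-dir demo
Rscript inst/cli/emsnv.R call --ref demo/reference.fa --bam demo/reads.sam --out demo/calls.vcf
Rscript inst/cli/emsnv.R eval --calls demo/calls.vcf --truth demo/truth.vcf
```

To call on your own data, the inputs are a reference FASTA and a
coordinate-sorted SAM/BAM; train a filter on a truth set you trust with
`run_train_filter()` (or `train-filter` from the CLI) and pass the saved
model to `run_call(..., model = path)`. Without a user model, a default
filter trained deterministically on a documented simulated regime is used;
`no_filter = TRUE` gives the raw EM candidate set.

## Layout

| path | contents |
|---|---|
| `R/pileup.R` | BAM/SAM → per-locus, per-learner base counts (Rsamtools/GenomicAlignments) |
| `R/em.R` | model init, E/M steps, MAP-EM loop, candidate extraction |
| `R/filter.R` | feature extraction, depth-≤5 CART training and application |
| `R/vcf.R` | VCF 4.2 writing, reading, BED masking, genotype-aware evaluation |
| `R/simulator.R` | seeded diploid read simulator with planted truth |
| `R/pipeline.R` | `run_call` / `run_simulate` / `run_train_filter` / `run_eval` |
| `inst/cli/emsnv.R` | command-line wrapper with those four subcommands |
| `vignettes/emsnv-methods.Rmd` | methods: model, assumptions, numerics, limitations |
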