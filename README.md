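# fishor — olfactory receptor gene repertoire evolution in fish genomes

Teleost fishes smell with a repertoire of olfactory receptor (OR) genes —
intronless G-protein-coupled receptor genes of ~310 codons, classified into
families (β, γ, δ, ε, ζ, η; α only outside teleosts) — that evolves by
*birth-and-death*: recurrent duplication (birth) and pseudogenization or
deletion (death). Comparative questions about this process need several
pieces of machinery that usually live in separate tools: mining OR genes
from assemblies and classifying them as functional, pseudogene
(≥ 1 premature stop or frameshift), truncated (incomplete, no lesion) or
scaffold-edge artifacts; reconciling gene trees with a dated species tree to
count per-branch gains `G` and losses `L` and convert them into rates
`b = G/(n_anc·t)`, `d = L/(n_anc·t)` per gene per Myr; simulating how long a
dead gene stays detectable by homology search; reconstructing ancestral
states of olfactory-epithelium morphology (the multilamellar rosette,
present when ≥ 3 primary lamellae); and testing repertoire–morphology
correlations with phylogenetically corrected regression.

`fishor` packages all of this as tested R functions, together with a
synthetic-data generator that produces genomes, gene-family histories and
trait data with known ground truth, so that every stage can be validated
end-to-end. The search engine is exact dynamic programming (Smith–Waterman
and a frameshift-aware protein-to-DNA aligner, in C++) with Karlin–Altschul
e-values (`E = K·m·n·e^(−λS)`, gapped BLOSUM62 defaults λ = 0.267,
K = 0.041) — no external BLAST binaries are required.

Audience: molecular evolution / phylogenomics researchers who want a
reproducible desk-scale model of a multigene-family annotation-and-rates
pipeline, and anyone needing the individual components (translated search,
duplication–loss reconciliation, Fitch/F81 ancestral reconstruction,
PGLS/Pagel-λ/phylogenetic logistic regression) behind a plain R API.

## Worked example

```r
library(fishor)

## 1. a synthetic genome with a known OR complement
refs   <- make_reference_set(seed = 1)          # 6 families x 3 refs + 7 decoys
genome <- implant_genome(refs, implant_plan(n_functional = 8, n_pseudo = 3,
                                            n_truncated = 2, n_edge = 1,
                                            scaffold_sizes = rep(12000L, 4)),
                         seed = 7)

## 2. two-pass mining: 1e-10 external refs -> ORFs > 750 nt -> OR-vs-decoy
##    validation; then 1e-20 with the genome's own genes -> classification
rep <- annotate_genome(genome, refs, species = "demo_fish")
print(rep)
#> OR repertoire for demo_fish
#> functional pseudogene  truncated       edge
#>          8          3          2          1
repertoire_eval(rep, genome$truth)$precision
#> functional pseudogene  truncated       edge
#>          1          1          1          1

## 3. birth/death rates from gene-tree/species-tree reconciliation
tr    <- simulate_species_tree(16, 250, seed = 1)
set.seed(2)
hists <- replicate(10, simulate_gene_history(tr, 15, 0.007, 0.007),
                   simplify = FALSE)
recs  <- lapply(hists, function(h)
  reconcile(ape::read.tree(text = h$gene_tree), tr, rooted = TRUE))
summarize_rates(aggregate_reconciliations(recs))
#> mean birth 0.0076, mean death 0.0048 over 30 branches

## 4. how long does a dead OR stay findable? (defaults: subs 1e-8/site/gen,
##    indels 0.05e-8, detection at translated-search e-value 1e-20)
decay_distribution(refs$cds[[1]], n_reps = 30, seed = 1)
#> pseudogene decay: 30 replicates, median 3.66e+07 generations (IQR 3.44e+07-4.04e+07)
```

The annotation recovers the implanted complement exactly; the inferred
birth rate sits at the simulated 0.007 while the death rate shows the
parsimony undercount discussed in the vignette; and a ~930-nt OR coding
sequence stops being detectable after a median of ≈ 3.7 × 10⁷ generations —
pseudogenes older than a few tens of Myr are simply not countable, which is
why loss counts and observed pseudogene numbers only agree on short terminal
branches (see `loss_pseudo_sweep()`).

## Command line

A light dispatcher wraps the main flows:

```sh
Rscript -e 'fishor::fishor_cli()' simulate-genome --seed 1 --out genome.fasta --truth truth.tsv
Rscript -e 'fishor::fishor_cli()' annotate --genome genome.fasta --or-refs refs.faa --decoys decoys.faa --out-dir out/
Rscript -e 'fishor::fishor_cli()' decay --reps 300 --seed 1 --out decay.tsv
Rscript -e 'fishor::fishor_cli()' asr --tree sp.nwk --traits rosette.tsv --method ml-mppa --out asr.tsv
```

Outputs follow the field's plain-text conventions: FASTA (80-column), GFF3
(1-based, `class=`/`family=` attributes), Newick, TSV.
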