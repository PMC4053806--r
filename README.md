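# graphrbp

Graph-kernel models of RNA-binding protein (RBP) binding preferences.

RBPs recognize their targets through sequence *and* secondary structure:
many proteins bind a motif only when it sits in a hairpin loop, an
accessible single strand, or next to a stem. `graphrbp` learns such
preferences from CLIP-seq derived binding sites (bound/unbound
classification) or from in-vitro affinity measurements (regression), and
applies the fitted model to score sites, draw per-nucleotide binding
profiles, call high-affinity sites, and extract sequence/structure motif
matrices for logos.

## The method in brief

1. **Sites → contexts.** Binding sites (BED6 + FASTA) are filtered
   (length ≤ 75 nt; iCLIP cross-links widened ±15 nt), extended ±150 nt
   for folding, and the original interval is marked as the *viewpoint*.
   Unbound sites are drawn by coordinate shuffling within occupied genes.
2. **Contexts → structure ensembles.** Each context is folded in sliding
   150/37-nt windows; per window up to three shape-representative
   structures (*shreps*) within 10% of the window MFE are kept. Shapes
   abstract away stem lengths (levels 1/3/5 keep decreasing loop detail).
3. **Ensembles → graphs.** Sequence and structures become one directed
   annotated hypergraph per site: nucleotide vertices with 5'→3' backbone
   and base-pair edges, an abstract layer of structure elements
   (S/E/H/I/M/B) joined outer→inner, non-traversable relation vertices
   tying elements to their nucleotides, plus a reversed relabeled copy of
   everything for direction sensitivity.
4. **Graphs → features.** An explicit neighborhood-subgraph-pairwise-
   distance (NSPD) kernel map: for radii r ≤ R and root distances d ≤ D,
   features pair the canonical labels of two neighborhood subgraphs, with
   hybrid features linking substructure content to its abstract context.
   At least one root must lie in the viewpoint. Features are
   block-normalized and hashed to 2^bits dimensions.
5. **Features → models.** A margin classifier (Pegasos-style SGD on the
   hinge loss; parameters λ and epochs) or ε-insensitive support vector
   regression (parameters c and ε; solved in the dual, primal weights
   reconstructed). Tenfold cross-validation, AUROC / average precision,
   relative error reduction (x′−x)/(1−x), and a round-robin line search
   on a held-aside min(1000, 10%) tuning subset are built in.
6. **Models → biology.** Margins decompose exactly into per-nucleotide
   profiles; 12-mer window scores and top-1% calling with abut-merging
   yield high-affinity sites; the top-1000 best viewpoint 12-mers (per
   folding hypothesis) give sequence (4×k) and structure (6×k) logo
   matrices.

A deterministic built-in folder (stacking-aware Nussinov-style DP with
exact suboptimal enumeration) makes the whole pipeline self-contained;
an adapter for ViennaRNA's `RNAsubopt` is included. A synthetic-data
module generates motif-implant fixtures (optionally constrained to
hairpin loops or stems) and graded affinity sets with known ground truth.

## Worked example

```r
library(graphrbp)

spec  <- synthetic_spec(n_pos = 100, n_neg = 100, seq_len = 60, seed = 42)
sites <- generate_classification_set(spec)   # 8-mer UCAUGUAC, 10% mutation

fit <- graphrbp(sites, mode = "sequence")
fit
#> Graph-kernel RBP binding model (classification, sequence mode)
#>   sites: 200; kernel R=2 D=5 bits=20
#>   nonzero weights: 30073; bias: -0.4562

crossvalidate(sites, k = 10, seed = 42, mode = "sequence")
#> Cross-validation (10 folds)
#>   mean AUROC: 0.8970
#>   mean APR:   0.9125

mot <- extract_motif(fit, sites[sites$label == "bound", ], top_n = 100)
head(mot$kmers, 3)
#>   site_id start          seq       struct     score
#> 1   s0092     6 UCAUGUACCAUG EEEEEEEEEEEE 0.1855349
#> 2   s0036    23 UCAUGUACAUUC EEEEEEEEEEEE 0.1739330
#> 3   s0010    29 CUUGUCAUGUAC EEEEEEEEEEEE 0.1663458
mean(grepl("UCAUGUAC", mot$kmers$seq, fixed = TRUE))
#> [1] 0.51
```

The cross-validated AUROC of 0.897 says held-out bound sequences outrank
unbound ones ~90% of the time despite the mutated implants; half of the
pooled top 12-mers contain the intact implanted motif. With
`mode = "structure"` the same call folds every site and adds the
hypergraph structure layer — on hairpin-constrained data (see the
vignette) that lifts AUROC from chance to ~0.93 when sequence composition
alone carries no signal.

A thin command-line wrapper over these functions is installed at
`inst/cli/graphrbp` (subcommands `simulate`, `prep`, `train`, `cv`, `ls`,
`predict`, `profile`, `callsites`, `motif`).

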