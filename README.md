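# paritysig

Discovery and transfer of parity-associated gene expression signatures in
breast tissue.

Parity — having given birth — reshapes the breast transcriptome, and the
residual expression pattern carries information about breast cancer risk
that differs between estrogen-receptor-positive (ER+) and ER-negative
tumors. `paritysig` implements a complete, reproducible pipeline for this
class of analysis:

1. **Signature discovery** in a training cohort of nulliparous vs parous
   normal-tissue samples, using a SAM-style moderated statistic
   `d = (x̄_parous − x̄_nulliparous) / (s + s₀)` with a percentile-searched
   fudge factor `s₀` and a permutation false discovery rate: thresholds Δ
   on the deviation of ordered `d` values from their permutation-expected
   order statistics, with FDR(Δ) estimated as the expected permutation
   false-call count over the observed call count.
2. **Cluster validation**: average-linkage hierarchical clustering of
   samples over the signature genes (distance = 1 − Pearson correlation of
   median-centered expression), with cluster-based parity prediction
   accuracy per class.
3. **Signature transfer** into an independent cohort of paired tumor /
   cancer-adjacent normal tissues, by three complementary methods:
   - a weighted running-sum **gene set enrichment score**
     `ES ∈ [−1, 1]` over the list of genes ranked by the parous-vs-
     nulliparous t statistic, with a phenotype-permutation family-wise
     error rate (significant at FWER ≤ 15%) and leading-edge extraction;
   - the **Creighton correlation classifier**: a ±1 template built from
     the signature's training fold changes (+1 above the median FC, −1
     below), correlated against each sample's median-centered expression;
     `r > 0` calls the sample signature-positive;
   - **2×2 association** of signature calls with parity: cross-product
     odds ratio `(ad)/(bc)`, Wald 95% CI
     `exp(ln OR ± 1.96·√(1/a+1/b+1/c+1/d))`, and a χ² (no continuity
     correction) or Fisher exact p-value chosen by the minimum expected
     cell count (< 5 → Fisher).
4. **Stratified sensitivity analyses** (ER status, age at first birth
   ≤ 25 / > 25 years, interval since last birth < 10 / ≥ 10 years,
   menopausal status), run marginally per stratum.
5. A **synthetic-cohort generator** that reproduces the statistical
   structure of the design — a 130-sample training cohort (76 parous / 54
   nulliparous) with a planted block of 251 upregulated genes at linear
   fold changes ≈ 1.1–1.9, and a 150-subject paired test cohort (79%
   parous, 78% ER+) in which the planted signal is attenuated in tumors
   and disrupted in ER− subjects — so the entire pipeline is testable
   without any external data.

## Worked example

```r
library(paritysig)

cfg <- synthetic_config(n_genes = 2000, n_signature_genes = 100,
                        train_n_parous = 40, train_n_nulliparous = 30,
                        test_n_subjects = 80, seed = 42)
train <- simulate_training_cohort(cfg)
disc <- run_discovery(train$expression, train$annotation,
                      sam_params(n_permutations = 300, target_fdr = 0.05,
                                 seed = 1))
disc
#> SAM result: 82 gene(s) selected of 2000 (s0 = 0.162, delta = 0.494, achieved FDR = 0.0496, 300 permutations)
#> cluster-based parity accuracy: parous 42%, nulliparous 60%

test <- simulate_test_cohort(cfg, disc$signature)
run_transfer(test$expression, test$annotation, disc$signature,
             n_perm = 199, seed = 2)
#> Signature transfer (82 genes, 100% matched)
#>           tissue stratum n_parous n_nulliparous    es     fwer                     or      p_value test_used
#>  adjacent_normal     all       65            15  0.90 0% (sig) 30.07 (1.73 to 523.68) 0.0004510953      chi2
#>  adjacent_normal     ER+       52            12  0.93 0% (sig) 23.18 (1.30 to 411.98) 0.0019828142    fisher
#>  adjacent_normal     ER-       13             3  0.18      90%  8.08 (0.35 to 187.32) 0.2125000000    fisher
#>            tumor     all       65            15  0.73 0% (sig)   2.25 (0.72 to 7.08)  0.1592901114      chi2
#>            tumor     ER+       52            12  0.79 0% (sig)  8.68 (1.72 to 43.87)  0.0033326144      chi2
#>            tumor     ER-       13             3 -0.19      70%   0.43 (0.03 to 5.98)  1.0000000000    fisher
```

Discovery finds 82 of the 100 planted genes at an estimated FDR just
under the 5% target. The transfer table shows the qualitative pattern the
design plants: strong, significant enrichment (FWER ≤ 15%) in ER+
adjacent-normal and tumor tissue, and no significant enrichment in the
(null by construction) ER− strata. The clustering accuracies illustrate
that a modest-effect signature separates samples only partially even when
differential expression is clearly detectable.

Association statistics can also be computed directly from counts — for
example the training-cohort classification table
(nulliparous 37/17, parous 27/49):

```r
associate(contingency_table(37, 17, 27, 49))
#> OR (95% CI) = 3.95 (1.88 to 8.29), p = 0.000209 [chi2, min expected 26.6]
```

## Package layout

| File | Contents |
|---|---|
| `R/expression-io.R` | TSV expression/annotation/signature I/O, probe collapse, signature alignment |
| `R/synthetic-data.R` | study-structured cohort simulation |
| `R/sam.R` | SAM d statistic, s₀ search, permutation FDR, signature extraction |
| `R/clustering.R` | average-linkage clustering, parity prediction accuracy |
| `R/gsea.R` | ranked lists, running-sum ES, permutation FWER, leading edge, core refinement |
| `R/creighton.R` | ±1 template construction and per-sample correlation calls |
| `R/association.R` | 2×2 odds ratio, Wald CI, χ²/Fisher tests |
| `R/pipeline.R` | `run_discovery()` / `run_transfer()` orchestration and strata |

The methods vignette (`vignettes/parity-signature-workflow.Rmd`) documents
the statistical model, the default parameters and the numerical decisions
in detail.
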