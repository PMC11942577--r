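# dadsp

Domain-adaptive deep transfer learning for cancer drug sensitivity
prediction in R.

## The problem

High-throughput pharmacogenomic screens measure IC50 — the compound
concentration inhibiting half of a cell line's activity — for hundreds of
drugs across hundreds of cell lines, alongside the lines' gene-expression
profiles. Because two screens of the same biology differ in their
measurement distributions, a predictor fitted on one database transfers
poorly to another. `dadsp` is for computational pharmacologists who want
to train on a large labeled *source* screen and predict on a smaller,
differently distributed *target* screen.

Inputs are the field's standard triple: a cell-line-by-gene expression
matrix per domain (RMA-scale values), drug structures as SMILES converted
to 256-bit hashed circular (Morgan) fingerprints, and response triplets
`(cell line, drug, IC50)` modeled as `-log10(IC50)`.

## The models

**DADSP-A — adversarial adaptation.** Four sub-networks: a gene feature
extractor `G` (initialized from a stacked autoencoder pretrained layer by
layer on source expression), a drug branch `D` on fingerprint bits, a
domain discriminator `C` behind a gradient reversal layer (GRL), and a
regressor `R` with a sigmoid head. With source batch `x_s` (labels `y`)
and unlabeled target batch `x_t`:

    features  f = G([x_s; x_t])                  (concatenated along the batch)
    ŷ         = R([f_s, D(drug bits)])           (source features only)
    L_MSE     = mean (y − ŷ)²
    L_domain  = mean CE(domain label, C(GRL_λ(f)))
    L_Total   = L_MSE + L_domain

The GRL is the identity forward and multiplies the backward gradient by
−λ (λ = 2/(1+exp(−γp)) − 1, γ = 10, p = training progress), so the
discriminator's own minimization simultaneously drives `G` toward
domain-indistinguishable features. Training: Adam, learning rate 1e-4,
batch 128, 15 epochs, early stopping patience 3.

**DADSP-B — discrepancy-based adaptation.** Three stages with explicit
freezing: (1) `G` + `R` trained on source; (2) the shared encoder adapted
layer-wise on target data by minimizing target reconstruction error plus
the squared maximum mean discrepancy `MMD²(f_s, f_t)` at each layer's
codes, regressor frozen; (3) extractors frozen, `R` refit on source with
MSE only.

Also included: the evaluation metrics (RMSE, the literal published
fit statistic and the conventional R²), standard and blind
(leave-drug-and-cell-line-out) splits, an ablation harness over model
variants, a domain-confusion probe quantifying feature alignment,
integrated-gradients gene attribution with ranked key-gene reports, and a
synthetic source/target generator with a known response surface so the
whole pipeline runs without external downloads.

## Worked example

Train the adversarial model on a synthetic domain pair with a latent
covariate shift, evaluate on held-out target pairs, and attribute one
prediction to genes:

```r
library(dadsp)

pair <- generateDomainPair(SimulationConfig(seed = 1))   # 500 genes, 200/60 cells, 30 drugs
prep <- prepareDomainPair(pair, SplitSpec("standard", seed = 1))

sae   <- pretrainLayerwise(prep$sourceGene, SAEConfig(seed = 1))
model <- trainDadsp(prep$source$X_gene, prep$source$X_drug, prep$source$y,
                    targetGene = prep$targetGene,
                    config = DadspConfig(seed = 1),
                    encoderInit = exportEncoder(sae),
                    norm = list(features = prep$norm$features,
                                labels   = prep$norm$sourceLabels))
model

pred <- predictDadsp(model, prep$targetTest$X_gene, prep$targetTest$X_drug)
evaluatePredictions(prep$targetTest$y, pred$normalized)

att <- integratedGradients(model, prep$targetGene[1, ],
                           fingerprintBits(pair$fingerprints)["D01", ],
                           cellId = "T001", drugId = "D01",
                           geneIds = geneIds(pair$target$expr))
head(rankGenes(att, topN = 10), 3)
```

```
DadspModel [DADSP-A]: 500-gene input, 14 epochs trained
  final losses: L_MSE=0.00446  L_domain=0.67594  L_Total=0.68040
    n      rmse r2_conventional   r2_paper r2_paper_defined   slope_k
1 120 0.1121656       0.3907475 -0.6591915             TRUE 0.9656569
  gene_id       score
1   G0280 0.003708020
2   G0175 0.003044182
3   G0310 0.002856236
```

Reading the output: the target-domain RMSE (0.112 on the normalized
label scale) is the headline error; `r2_conventional` is the variance
explained on held-out target pairs; `r2_paper` is the literal published
fit statistic reported for comparability (flagged rather than thrown when
undefined); a domain loss near `log 2 = 0.693` means the discriminator
ends at chance — the adversarial optimum. The gene table is the ranked
integrated-gradients report for one (cell line, drug) pair. Comparing
variants over seeds (`runAblation()`) shows the transfer orderings:
adversarial training beats the adversary-off source-only model, and the
three-stage MMD pipeline beats its own stage-1 model applied directly to
the target, on most seeds (see below).

A thin command-line wrapper over these functions ships in
`inst/scripts/dadsp-cli.R` (subcommands `simulate`, `train`, `train-b`,
`evaluate`, `attribute`, `split`).

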