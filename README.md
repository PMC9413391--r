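# afsync

Detection of atrial fibrillation and flutter (merged into one class, *AF*)
in one- to twelve-lead ECG records, using only the stability of
atrioventricular (AV) synchronization. The package is aimed at biomedical
signal-processing researchers who want a transparent, feature-based AF
detector — one whose every input can be read off the ECG — rather than an
end-to-end black box on raw waveforms.

## What it computes

Three ECG phenomena carry the AF signature, each summarized per record by a
mean and a standard deviation:

| metric | meaning | unit | scope |
|---|---|---|---|
| RRi-mean, RRi-std | interval between consecutive R-wave fiducials | ms | global (reference lead I) |
| PQi-mean, PQi-std | interval from the P-/f-peak to the next QRS onset | ms | per lead |
| PQa-mean, PQa-std | amplitude difference between P-/f-peak and QRS onset | mV | per lead |

This gives a feature map of 2 + 4 × n\_leads dimensions: **6** (single
lead), **26** (limb or chest leads), **50** (twelve leads). A shrinking
dense neural network — batch-normalized input, 1–3 non-increasing ReLU
hidden layers with dropout α = 0.3, sigmoid output P(x ∈ AF) = σ(z) —
is trained with class-weighted binary cross-entropy,

    Loss = −(1/N) Σₙ [ δₙ · w_AF · log P(xₙ∈AF) + (1−δₙ) · w_nonAF · log(1−P(xₙ∈AF)) ],

with w\_AF + w\_nonAF = 1 derived from prevalence (w\_AF = 0.92 at 8% AF),
Adam (lr 0.001, β₁ = 0.9, β₂ = 0.999), at most 400 epochs and early
stopping (patience 10). The operating point P\_thr is the validation-ROC
point maximizing balanced accuracy BAC = (Se + Sp)/2. Feature importance
is explained with Shapley values,

    SHAP_Fi = Σ_{S ⊆ M∖{i}} |S|!(|M|−|S|−1)!/|M|! · [f(S ∪ {i}) − f(S)],

exact by subset enumeration up to 15 features, permutation-sampled above,
with global importance = mean |SHAP| over records, reported as
percent-of-max.

Upstream of the classifier sit a zero-phase filtering chain (mains notch,
0.64 Hz recursive high-pass, three-regime adaptive Savitzky–Golay
smoothing) and rule-based delineation: adaptive spatial-velocity QRS
detection, low-slope QRS-onset search within 120 ms before R
(Thr\_Q = 20 µV, incremented until satisfiable), and high-slope P-/f-peak
search 40–300 ms before the onset (Thr\_P = 3 µV). A 12-lead synthetic ECG
generator with exact ground-truth fiducials (sinus and AF morphologies)
makes the whole pipeline testable without external data.

## Worked example

```r
library(afsync)
res <- run_pipeline(pipeline_config(n_records = 80, af_fraction = 0.1,
                                    seed = 42, n_permutations = 200,
                                    background_size = 30))
print(res$model)
print(res$metrics, row.names = FALSE)
print(head(res$importance$report$ranked, 8), row.names = FALSE)
```

```
Dense AF/non-AF classifier
  architecture: [16,8], input dim 50 (1061 parameters)
  best validation loss 0.10103 at epoch 29/40
  probability threshold P_thr = 0.7809 (max validation BAC)
 stratum tp fn tn fp  se  sp bac f1
   Total  1  0  8  0 100 100 100  1
      feature      global percent_of_max flagged
  PQi_std_aVL 0.003169594            100    TRUE
      RRi_std 0.002972920             94    TRUE
  PQi_mean_II 0.002933723             93    TRUE
   PQi_std_V5 0.002639621             83    TRUE
 PQi_mean_aVF 0.002636819             83    TRUE
  PQi_mean_V4 0.002591060             82    TRUE
   PQi_std_V6 0.002590003             82    TRUE
   PQi_std_V1 0.002444829             77    TRUE
```

The pipeline generated 80 synthetic records (10% AF), split them
patient-wise 70/20/10, extracted the 50-feature map, trained a [16,8]
network, picked the threshold at maximal validation BAC and evaluated the
held-out test records: all 9 were classified correctly (the synthetic
classes are nearly separable in this feature space — see the vignette for
why that is an upper bound, not an estimate, of clinical performance).
The importance ranking shows PQ-interval instability and RR variability
dominating, as expected for AF.

A shell front end with the same stages lives at `inst/cli/afsync`
(`afsync synth | ingest | features | train | evaluate | explain |
pipeline`).

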