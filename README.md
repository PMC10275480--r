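# paradiv

Transcriptional vs translational divergence of paralogous genes, and
in-silico evolution of expression after gene duplication.

## The problem

Steady-state protein abundance is set by a transcription rate β<sub>m</sub>
(mRNA/h) and a translation rate β<sub>p</sub> (proteins per mRNA per hour):
p = β<sub>m</sub>β<sub>p</sub>/(α<sub>m</sub>α<sub>p</sub>). The two rates
contribute symmetrically, yet within budding-yeast paralog pairs most
expression divergence is transcriptional. `paradiv` is for researchers in
molecular evolution who want to (i) quantify that bias from molecular rate
tables, (ii) check it against measurement-noise and shared-measurement
artifacts, and (iii) test mechanistic explanations by simulating
post-duplication evolution.

Per pair, divergence in either rate is the log2 fold change
fc = log₂(max(θ₁,θ₂)/min(θ₁,θ₂)), and the transcription bias of a pair is
D = fc<sub>βm</sub> − fc<sub>βp</sub>. Two Spearman correlations relate the
two divergence dimensions (between magnitudes, and between signed fold
changes on the orientation-duplicated dataset), with percentile bootstrap
intervals resampling pairs.

Two fitness models drive sequential-fixation simulations of duplicate
pairs. In both, a gene's fitness is a parabola of protein abundance with
vertex (p_opt, μ) and curvature Q/(2·opt) relative to the optimum; after
duplication, selection acts on the summed abundance of the pair with the
optimum moved to 1.87× the ancestral one — the smallest multiple (at 0.01
granularity) that keeps the duplication-induced doubling viable even for
the narrowest admissible fitness function, derived from the cellular
constants by `minimal_delta_opt()`. The *minimal* model stops there
(quantitative subfunctionalization: only total abundance matters). The
*precision–economy* model adds expression noise
(σ² = P + α_p(p₁²/β<sub>m,1</sub> + p₂²/β<sub>m,2</sub>) + cv₀²P²) and a
transcription cost (l_m·c_m·Σβ<sub>m</sub>) to fitness, making noise and
cost depend on how expression is bought — the trade-off that channels
divergence into transcription. Mutations are multiplicative relative
effects assigned to β<sub>m</sub> or β<sub>p</sub> by mutational target
size (normal, skew-normal, or correlated bivariate families) and fix by a
modified Metropolis rule, P_fix = 1 if F_j > F_i else
exp(−2N(log F_i − log F_j)).

Synthetic generators reproduce the statistical structure the analyses
assume (log-normal rate marginals consistent with cellular totals,
cor(log m, log s) = 0.981, pair fold-change SDs 2.29/1.11 in log2 units,
decay variation around 5.10 h⁻¹), with ground truth emitted beside every
table.

## Worked example

```r
library(paradiv)

spec  <- synthetic_spec(seed = 1)          # yeast-like study conditions
genes <- generate_gene_table(spec)         # 4440-gene rate table
synth <- generate_paralog_pairs(spec, genes)  # 245 WGD + 164 SSD pairs

res <- analyze_divergence(synth$genes, synth$pairs, n_boot = 2000, seed = 1)
s <- res$summary
```

This prints (numbers from this exact run):

```
pairs 409 | median fc_bm 1.46 fc_bp 0.72 ratio 2.02 | biased 72.9%
MWW p 4.39e-23
Spearman rho = 0.129  [0.029, 0.228]  (n = 409, p = 0.00924)
Spearman rho = 0.479  [0.404, 0.554]  (n = 818, p = 0)
```

Median transcriptional divergence is 2.02× the translational one and 72.9%
of pairs are transcription-biased (D > 0), a difference the
Mann–Whitney–Wilcoxon test calls far from chance; the magnitudes of the
two divergences correlate weakly (ρ = 0.13) and the signed fold changes
strongly (ρ = 0.48 on the 818-row orientation-duplicated set) — the
structure the generator was asked to emulate, recovered by the analysis.

A mock trade-off simulation (50 pairs, σ_mut = 0.025, N = 10⁶, equal
mutational target sizes, stopped when simulated protein divergence matches
the WGD reference by Mood's median test):

```r
ref <- reference_fold_changes(res$records, dup_type = "WGD")
cfg <- simulation_config("precision_economy", N = 1e6, n_pairs = 50,
                         mutation = mutation_model(sigma_mut = 0.025),
                         reference_fc = ref$fc_p, seed = 11)
sim <- run_simulation(cfg, synth$genes)
fc  <- population_fold_changes(sim$population)
median(fc$fc_bm) / median(fc$fc_bp)
```

yields a transcription/translation divergence ratio well above 1: the
precision–economy trade-off alone, with no mutational bias, reproduces
transcription-dominant divergence. `run_pipeline()` chains all stages
(synthesis → analysis → simulation → assessment) and writes TSV/JSON
outputs with a digest manifest; `grid_search()` calibrates σ_mut and the
target-size ratio against a reference divergence pattern.

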