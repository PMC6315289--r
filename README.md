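# pseudokl

Capture-time-anchored pseudotime inference and KL-divergence trajectory
ranking for single-cell RNA-seq time courses.

## The problem

When naïve mouse embryonic stem cells (ESCs, 2i/Lif) are induced towards
primed epiblast-like cells (EpiLCs), cells harvested at the same wall-clock
time (0, 24, 48 h) sit at different points of the underlying transition.
Ordering single-cell transcriptomes along a latent *pseudotime* recovers
that hidden progression, and asking *which transcripts change most* along
the trajectory — pluripotency regulators, epiblast markers, metabolic
enzymes — requires a statistic that sees changes in both the level and the
spread of expression. This package implements that analysis chain for
computational biologists working with capture-time-stamped single-cell count
matrices:

1. **QC and normalization** — cells kept with ≥ 6×10⁶ uniquely mapped reads;
   invariant transcripts dropped; counts transformed as log₁₀(count + 1);
   48 h cells with high residual naïve-marker expression
   (log₁₀(*Tfcp2l1* + 1) > 1.5) excluded; median-of-ratios size factors.
2. **Gene selection** — a curated regulator list plus the transcripts with the
   highest ratio of between-capture-time to within-capture-time variance,
   135 by default.
3. **Pseudotime** — each cell's latent time τ_c gets a Gaussian prior centred
   on its capture time k_c, τ_c ~ N(k_c, σ_τ²) with σ_τ = 8 h; each
   transcript's expression over cells is a Gaussian process in τ with a
   squared-exponential kernel (shared length-scale l = 48 h, per-transcript
   amplitude ψ_g and noise ω_g). The joint posterior is sampled by MCMC.
4. **Ordering test** — a permutation roughness test: the mean root-mean-square
   successive difference of expression along the inferred ordering, compared
   with random orderings.
5. **Trajectory ranking** — a fresh GP trajectory is fitted per transcript
   over the inferred pseudotimes; the Kullback–Leibler divergence between the
   trajectory posteriors at the representative (median) start and end
   pseudotimes,

   KL(N(μ₁,s₁²) ‖ N(μ₂,s₂²)) = ln(s₂/s₁) + (s₁² + (μ₁−μ₂)²)/(2s₂²) − ½,

   ranks transcripts by how much their expression distribution changed.
6. **OSN occupancy** — a gene counts as OCT4/SOX2/NANOG-occupied when all
   three factors bind within 20 kb upstream to 4 kb downstream of its TSS in
   at least two of three reference ChIP-seq datasets.

A synthetic-data generator with known ground truth (true pseudotimes, true
trajectory classes, true size factors, planted occupancy) makes the whole
chain testable end to end.

## Worked example

```r
library(pseudokl)

sim <- simulate_expression(sim_config(n_cells_per_group = 15, n_down = 25,
                                      n_up = 25, n_flat = 50, seed = 1))
cfg <- run_config(kl_direction = "symmetrized", mcmc_warmup = 150,
                  mcmc_draws = 150, n_analysis_genes = 60)
pp  <- preprocess(sim$counts, sim$cells, cfg)
fit <- fit_pseudotime(pp$working[pp$analysis_genes, ], pp$cells, cfg)
test <- roughness_permutation_test(pp$working[pp$analysis_genes, names(fit$tau_hat)],
                                   fit$tau_hat, n_perm = 999, seed = 2)
rk  <- kl_rank_transcripts(pp$working, fit, pp$cells, cfg)
```

which prints (reproducibly, seed 1):

```
pseudotime_fit: 45 cells, 60 transcripts
  sigma_tau = 8 h; length-scale = 48 h
  tau_hat range: -16.0 .. 63.5 h
  min ESS(tau): 7

roughness: observed 0.364 vs null mean 0.733, p = 0.001

           gene   D rank mu_start mu_end
1   gene0050_up 292    1    1.429  2.578
2 gene0022_down 289    2    2.157  0.728
3   gene0043_up 280    3    0.954  2.302
4          Pdk3 276    4    0.664  2.028
5 gene0018_down 266    5    2.644  1.400
6         Zfp42 260    6    2.622  1.366
```

Reading this: the inferred pseudotimes spread beyond the 0–48 h capture range
(the prior permits it), the inferred ordering is far smoother than random
(p at the permutation floor 1/1000), and the top of the KL ranking is
dominated by planted dynamic transcripts — *Pdk3* rising (μ 0.66 → 2.03 on
the log₁₀ scale) and the naïve marker *Zfp42* falling, while flat control
genes land at the bottom. Against the generator's truth, the fitted
pseudotimes have Spearman correlation 0.988.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pseudokl", package = "pseudokl"))')
Rscript "$CLI" simulate   --out-dir sim --seed 3
Rscript "$CLI" run        --counts sim/counts.tsv --metadata sim/metadata.tsv \
                          --out-dir results --kl-direction symmetrized
Rscript "$CLI" osn        --tss tss.bed --binding-dir beds/ --out osn.tsv
```

Subcommands: `simulate`, `preprocess`, `pseudotime`, `klrank`, `osn`, `run`.
Flags mirror `run_config()`; `--config file.json` supplies a declarative
config that flags override. Logs go to stderr; outputs are TSV/JSON files
plus a `manifest.json` recording config, seeds, versions and row counts.

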