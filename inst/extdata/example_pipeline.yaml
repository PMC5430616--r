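# Example configuration for `run_pipeline()` / `admixscan run`.
# A synthetic study is generated in place of real input files; replace the
# `input` section with `genotypes`/`format`/`cohort_samples` paths to run on
# real data.
seed: 42
output_dir: admixscan_run
input:
  simulate:
    n_admixed: 100
    n_snps: 600
    n_proxy_pool: 25
qc:
  call_rate_min: 0.99
  maf_min: 0.05
prune:
  r2_max: 0.3
  window_snps: 50
  step_snps: 5
pca:
  n_components: 2
proxies:
  n_proxy: 15
admixture:
  mode: supervised
  K: 3
  n_restarts: 1
scan:
  mode: lsbl
  focal: 2
  top_k: 10
  merge_bp: 1000000
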