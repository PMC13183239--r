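# Demo pipeline configuration: full default synthetic vineyard, light
# jackknife so the run stays fast.  Run with:
#   Rscript inst/scripts/vitispec.R run --config inst/extdata/demo_pipeline.yaml --out demo_out
simulate:
  seed: 1
window: [400, 2400]
a_max_cap: 15
jackknife: yes
jk_B: 100
out_dir: vitispec_demo_output
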