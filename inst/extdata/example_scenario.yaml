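# Example scenario configuration for the command-line front end:
#   Rscript inst/cli/effort.R run --config inst/extdata/example_scenario.yaml --seed 1 --out effort_out
task: pointing
scenario: TORQUE
repeats: 5
phase3: true
plant:
  noise_sd: 0.05
criterion:
  radius: 0.025
  threshold: 0.15
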