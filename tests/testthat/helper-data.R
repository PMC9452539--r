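# Shared small fixtures, generated once per test run.

tiny_sep_dataset <- simulate_dataset(
  simulation_spec(n_enhancer = 60, n_non_enhancer = 60, effect = 1, seed = 101))
tiny_sep_table <- extract_dataset(tiny_sep_dataset)

tiny_null_table <- extract_dataset(simulate_dataset(
  simulation_spec(n_enhancer = 60, n_non_enhancer = 60, effect = 0, seed = 102)))

fast_config <- forest_config(n_trees = 100, seed = 5)
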