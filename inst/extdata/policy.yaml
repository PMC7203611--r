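# Default testing policy.
# dose_cutpoints split the daily MME dose into the three base risk bands:
#   [0, 40) -> low, [40, 100] -> moderate, (100, Inf) -> high.
# test_probabilities are the pre-set per-visit chances that a test is
# recommended in each (possibly escalated) risk category.
dose_cutpoints: [40.0, 100.0]
test_probabilities:
  low: 0.25
  moderate: 0.33
  high: 0.50
  high_plus: 0.60
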