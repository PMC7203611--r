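# Default equianalgesic conversion table, version 1.
# Factors are MME per mg/day of oral drug, except `rate:` entries, which are
# MME per (mcg/hr) of a continuous transdermal formulation.
# Morphine must be exactly 1 (definition of the MME scale).
# Methadone converts on a dose-dependent tier schedule applied to the pooled
# daily methadone dose; `upper` is the inclusive upper bound of each tier and
# the last tier is unbounded.
linear:
  morphine: 1.0
  codeine: 0.15
  hydrocodone: 1.0
  oxycodone: 1.5
  oxymorphone: 3.0
  hydromorphone: 4.0
  tramadol: 0.1
  tapentadol: 0.4
tiered:
  methadone:
  - upper: 20.0
    factor: 4.0
  - upper: 40.0
    factor: 8.0
  - upper: 60.0
    factor: 10.0
  - upper: .inf
    factor: 12.0
rate:
  fentanyl: 2.4
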