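# Default substance dictionary and metabolite map, version 1.
# The four analyte classes must be pairwise disjoint. `excluded` analytes
# (THC by default) never influence the consistency ruling. `metabolites`
# maps each prescribable opioid to the analytes detectable after its use
# (always including the parent itself); six_mam is the heroin-specific
# 6-monoacetylmorphine marker and is classed as illicit.
opioids:
  - morphine
  - codeine
  - oxycodone
  - oxymorphone
  - noroxycodone
  - hydrocodone
  - hydromorphone
  - norhydrocodone
  - fentanyl
  - norfentanyl
  - methadone
  - eddp
  - tramadol
  - o_desmethyltramadol
  - tapentadol
illicit:
  - cocaine
  - benzoylecgonine
  - six_mam
  - amphetamine
  - methamphetamine
  - mdma
  - pcp
excluded:
  - thc
benzodiazepines:
  - alprazolam
  - diazepam
  - nordiazepam
  - oxazepam
  - temazepam
  - clonazepam
  - lorazepam
metabolites:
  morphine: [morphine]
  codeine: [codeine, morphine]
  oxycodone: [oxycodone, oxymorphone, noroxycodone]
  oxymorphone: [oxymorphone]
  hydrocodone: [hydrocodone, hydromorphone, norhydrocodone]
  hydromorphone: [hydromorphone]
  fentanyl: [fentanyl, norfentanyl]
  methadone: [methadone, eddp]
  tramadol: [tramadol, o_desmethyltramadol]
  tapentadol: [tapentadol]
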