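# Synthetic example tree: illustrates the engine's config schema only and is
# NOT the published machine-learning tree, whose full structure is not public.
feature: longitudinal_cord_T2
"yes": NMOSD
"no":
  feature: bilateral_optic_nerve
  "yes": NMOSD
  "no":
    feature: ovoid_T2
    "yes": MS
    "no":
      feature: bright_spotty_cord_T2
      "yes": NMOSD
      "no":
        feature: periventricular_T2
        "yes": MS
        "no":
          feature: cord_gd
          "yes": NMOSD
          "no": MS
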