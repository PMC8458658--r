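# Synthetic example rule set: illustrates the declarative boolean schema used
# to encode externally published criteria; not a published criteria set.
name: synthetic-letm-rule
expression: longitudinal_cord_T2 AND NOT dawsons_fingers
predicts: NMOSD
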