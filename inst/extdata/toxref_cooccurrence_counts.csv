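category,n_positive
universe,774
any_male_repro_effect,281
weight,227
histology,126
sperm,58
tumor,31
malformation,18
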