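cohort	nonsyn	syn
PJL_panel_subset_synthetic	88	100
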