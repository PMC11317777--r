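death
drug ineffective
condition aggravated
treatment failure
drug resistance
sepsis
off label use
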