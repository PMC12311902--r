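file,md5
allele_registry.csv,f9b8223ae83ccc9f2fb15cc85329eba5
ims_scores.csv,a670b66d3ccb0ac3e96eb893fe002ef6
expected_scores.csv,f5e924eed85b0bd1b7fcfb754fb751cd
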