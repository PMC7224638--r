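metric,value
total_cells,29033
multiplets,1532
undetermined,243
singlets_reported,27258
donor1_singlets,8984
donor2_singlets,8956
donor3_singlets,9318
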