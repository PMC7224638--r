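component,n_genes
predefined,397
custom,95
total_reported,492
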