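# Desk-scale architecture: three resolution levels at 64 px, ~0.4M parameters
input_size: 64
depth: 3
base_filters: 8
dense_layers: 4
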