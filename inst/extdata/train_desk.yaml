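# Desk-scale training protocol (demo learning rate; the full-scale reference
# protocol is epochs 100, learning_rate 1.0e-6)
epochs: 15
batch_size: 8
learning_rate: 1.0e-3
loss: bce
split_ratio: 0.8
seed: 11
target: liver
window:
  hu_min: -100
  hu_max: 400
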