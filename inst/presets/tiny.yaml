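# CPU-scale preset for tests and desk experiments
preset: tiny
depths: [1, 1, 2, 1]
dims: [16, 32, 64, 128]
heads: [1, 2]
window: 4
groups: 4
decoder_width: 64
num_classes: 2
stem_sizes: [4, 8, 16, 32]
stem_stride: 4
mlp_ratio: 4
input_size: 512
crop_size: 224
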