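# Full-scale configuration (GPU-scale training; shipped for completeness)
preset: paperlike
depths: [2, 2, 6, 2]
dims: [96, 192, 384, 768]
heads: [3, 6]
window: 7
groups: 4
decoder_width: 256
num_classes: 2
stem_sizes: [4, 8, 16, 32]
stem_stride: 4
mlp_ratio: 4
input_size: 512
crop_size: 224
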