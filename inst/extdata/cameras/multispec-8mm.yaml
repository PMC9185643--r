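# Generic nadir multispectral survey camera.
name: multispec-8mm
focal_length_mm: 8
pixel_pitch_mm: 0.003
n_px_x: 4000
n_px_y: 3000
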