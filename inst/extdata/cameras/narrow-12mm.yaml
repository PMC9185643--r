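# Narrower-FOV mapping camera (sensor size + resolution parameterization).
name: narrow-12mm
focal_length_mm: 12
sensor_width_mm: 13.2
sensor_height_mm: 8.8
n_px_x: 5472
n_px_y: 3648
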