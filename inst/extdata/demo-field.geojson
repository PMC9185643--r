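{
  "type": "Feature",
  "properties": {
    "name": "demo-field",
    "description": "100 m x 120 m rectangle fixture"
  },
  "geometry": {
    "type": "Polygon",
    "coordinates": [
      [
        [-3.7000000000000002, 40],
        [-3.69882601902018, 40],
        [-3.69882601902018, 40.001079185927104],
        [-3.7000000000000002, 40.001079185927104],
        [-3.7000000000000002, 40]
      ]
    ]
  }
}
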