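{
  "type": "FeatureCollection",
  "comment": "Synthetic example of the editable region-polygon configuration consumed by read_regions(): coarse boxes sketching broad regions of a Baltic-to-Africa flyway. Edit or replace for real analyses.",
  "features": [
    {
      "type": "Feature",
      "properties": {"name": "northern_seas"},
      "geometry": {"type": "Polygon", "coordinates": [[
        [-5, 53], [32, 53], [32, 66], [-5, 66], [-5, 53]
      ]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "europe"},
      "geometry": {"type": "Polygon", "coordinates": [[
        [-10, 36], [32, 36], [32, 53], [-10, 53], [-10, 36]
      ]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "sahara_mediterranean"},
      "geometry": {"type": "Polygon", "coordinates": [[
        [-17, 18], [40, 18], [40, 36], [-17, 36], [-17, 18]
      ]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "coasts_sahel"},
      "geometry": {"type": "Polygon", "coordinates": [[
        [-18, 4], [45, 4], [45, 18], [-18, 18], [-18, 4]
      ]]}
    }
  ]
}
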