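{
  "format": "drusenseq canonical visit table, CSV with header (UTF-8)",
  "time_column": {
    "note": "exactly one of 'month' or 'date'",
    "month": "numeric months from the eye's baseline visit",
    "date": "ISO-8601; converted to fractional months via days / 30.44"
  },
  "required": {
    "patient_id": "string",
    "eye_id": "string",
    "dx_status": "one of: dry, exudative",
    "treated": "logical; TRUE marks a treatment (event) visit",
    "n_drusen": "count of individually separated drusen",
    "mean_volume": "mm^3 per druse",
    "total_volume": "mm^3",
    "mean_area": "mm^2 per druse",
    "total_area": "mm^2",
    "extent_area": "mm^2 (convex hull of affected region)",
    "density": "total_area / extent_area, in (0, 1]",
    "max_height": "mm above Bruch's membrane",
    "avg_slope": "dimensionless gradient (mm/mm)",
    "mean_reflectivity": "normalized 0-1 units",
    "std_reflectivity": "normalized 0-1 units",
    "area_3mm": "mm^2 within 3 mm of the fovea center",
    "area_5mm": "mm^2 within 5 mm of the fovea center",
    "volume_3mm": "mm^3 within 3 mm of the fovea center",
    "volume_5mm": "mm^3 within 5 mm of the fovea center"
  },
  "optional": {
    "age_months": "numeric",
    "gender": "male/female (missing allowed)",
    "race": "white/black/asian/native_american/pacific_islander (missing allowed)",
    "smoking_status": "never/previous/current (missing allowed)",
    "visual_acuity": "letter score (continuous)",
    "signal_strength": "device 0-10 scale; rows < 7 can be filtered",
    "total_area_cirrus": "device-reported pass-through",
    "area_3mm_cirrus": "device-reported pass-through",
    "area_5mm_cirrus": "device-reported pass-through",
    "total_volume_cirrus": "device-reported pass-through",
    "volume_3mm_cirrus": "device-reported pass-through",
    "volume_5mm_cirrus": "device-reported pass-through"
  }
}
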