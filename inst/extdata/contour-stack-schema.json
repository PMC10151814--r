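{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cmrqc contour stack",
  "description": "One reader's subpixel contour annotation of one cardiac short-axis case. Coordinates are 0-based pixel units, x = column, y = row; physical distances follow from pixel_spacing_mm. Rings are implicitly closed; the first ring of a record is the outer boundary, later rings are holes.",
  "type": "object",
  "required": ["schema_version", "case_id", "reader_id", "pixel_spacing_mm",
               "slice_thickness_mm", "slice_gap_mm", "slice_order",
               "image_shape", "grid", "contours"],
  "properties": {
    "schema_version": {"const": "1"},
    "case_id": {"type": "string"},
    "reader_id": {"type": "string"},
    "pixel_spacing_mm": {
      "type": "array", "items": {"type": "number", "exclusiveMinimum": 0},
      "minItems": 2, "maxItems": 2,
      "description": "(row, column) spacing in mm/pixel"
    },
    "slice_thickness_mm": {"type": "number", "exclusiveMinimum": 0},
    "slice_gap_mm": {"type": "number", "minimum": 0},
    "slice_order": {
      "enum": ["apex_to_base", "base_to_apex"],
      "description": "direction of increasing slice_index in this file; readers normalise to apex_to_base (index 0 = most apical slice)"
    },
    "image_shape": {
      "type": "array", "items": {"type": "integer", "exclusiveMinimum": 0},
      "minItems": 2, "maxItems": 2,
      "description": "(rows, columns) of the image grid"
    },
    "grid": {
      "type": "array",
      "description": "slice index range per phase; cells without a contour record are empty slice annotations",
      "items": {
        "type": "object",
        "required": ["phase_label", "slice_min", "slice_max"],
        "properties": {
          "phase_label": {"type": "string"},
          "slice_min": {"type": "integer", "minimum": 0},
          "slice_max": {"type": "integer", "minimum": 0}
        }
      }
    },
    "contours": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["slice_index", "phase_label", "structure_label", "rings"],
        "properties": {
          "slice_index": {"type": "integer", "minimum": 0},
          "phase_label": {"type": "string", "description": "ED, ES, or another phase name"},
          "structure_label": {"enum": ["lv_endo", "lv_epi", "rv_endo"]},
          "rings": {
            "type": "array", "minItems": 1,
            "items": {
              "type": "array", "minItems": 3,
              "items": {
                "type": "array", "items": {"type": "number"},
                "minItems": 2, "maxItems": 2,
                "description": "[x, y] vertex in subpixel pixel coordinates"
              }
            }
          }
        }
      }
    }
  }
}
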