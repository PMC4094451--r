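{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "rulenet-model-1.0",
  "title": "Rule-based model document",
  "type": "object",
  "required": ["format_version", "molecules", "species", "rules"],
  "additionalProperties": false,
  "properties": {
    "format_version": {"type": "string"},
    "metadata": {"type": "object"},
    "molecules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "components": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["name"],
              "properties": {
                "name": {"type": "string", "minLength": 1},
                "state_variables": {
                  "type": "array", "items": {"type": "string"}
                },
                "binding_sites": {
                  "type": "array", "items": {"type": "string"}
                }
              }
            }
          }
        }
      }
    },
    "species": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "molecule_instances"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "molecule_instances": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["instance_id", "molecule"],
              "properties": {
                "instance_id": {"type": "string"},
                "molecule": {"type": "string"}
              }
            }
          },
          "structural_bonds": {
            "type": "array",
            "items": {
              "type": "array",
              "items": {"type": "integer", "minimum": 1},
              "minItems": 2, "maxItems": 2
            }
          },
          "complexes": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["name"],
              "properties": {
                "name": {"type": "string", "minLength": 1},
                "states": {
                  "type": "array",
                  "items": {
                    "type": "object",
                    "required": ["instance_id", "component",
                                 "state_variable", "value"],
                    "properties": {
                      "instance_id": {"type": "string"},
                      "component": {"type": "string"},
                      "state_variable": {"type": "string"},
                      "value": {"enum": ["on", "off", "dont_care"]}
                    }
                  }
                }
              }
            }
          }
        }
      }
    },
    "rules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "category", "reactants", "products"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "category": {
            "enum": ["association", "dissociation", "transformation"]
          },
          "reactants": {"$ref": "#/definitions/complex_refs"},
          "products": {"$ref": "#/definitions/complex_refs"},
          "bond_sites": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["species", "site_index"],
              "properties": {
                "species": {"type": "string"},
                "site_index": {"type": "integer", "minimum": 1}
              }
            },
            "minItems": 2, "maxItems": 2
          },
          "rate_constant": {"type": "number", "minimum": 0}
        }
      }
    }
  },
  "definitions": {
    "complex_refs": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["species", "complex"],
        "properties": {
          "species": {"type": "string"},
          "complex": {"type": "string"}
        }
      }
    }
  }
}
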