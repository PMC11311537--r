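{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Synthetic transcription of the mzQC 1.0.0 structural rules",
  "description": "A JSON Schema written for this package's validator tests. It transcribes the structural constraints of the mzQC 1.0.0 format (it is NOT the official published schema, which is unavailable offline). Two constraints the format implies but draft-07 cannot express are declared with extension keywords: x-equal-length-arrays (all columns of a tabular metric value have equal length) and x-unique-by (array items are unique under one field).",
  "type": "object",
  "required": ["mzQC"],
  "properties": {
    "mzQC": {
      "type": "object",
      "required": ["version", "creationDate", "controlledVocabularies"],
      "anyOf": [
        { "required": ["runQualities"] },
        { "required": ["setQualities"] }
      ],
      "properties": {
        "version": { "type": "string", "pattern": "^1\\.0\\.0$" },
        "creationDate": {
          "type": "string",
          "pattern": "^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}(\\.[0-9]+)?(Z|[+-][0-9]{2}:?[0-9]{2})?$"
        },
        "description": { "type": "string" },
        "contactName": { "type": "string" },
        "contactAddress": { "type": "string" },
        "controlledVocabularies": {
          "type": "array",
          "minItems": 1,
          "items": { "$ref": "#/definitions/cvReference" }
        },
        "runQualities": {
          "type": "array",
          "minItems": 1,
          "items": { "$ref": "#/definitions/runQuality" }
        },
        "setQualities": {
          "type": "array",
          "minItems": 1,
          "items": { "$ref": "#/definitions/setQuality" }
        }
      }
    }
  },
  "definitions": {
    "accession": {
      "type": "string",
      "pattern": "^[A-Z]+[A-Z0-9]*:[0-9]+$"
    },
    "cvReference": {
      "type": "object",
      "required": ["name", "uri"],
      "properties": {
        "name": { "type": "string", "minLength": 1 },
        "uri": { "type": "string", "minLength": 1 },
        "version": { "type": "string" }
      }
    },
    "cvParameter": {
      "type": "object",
      "required": ["accession", "name"],
      "properties": {
        "accession": { "$ref": "#/definitions/accession" },
        "name": { "type": "string", "minLength": 1 }
      }
    },
    "inputFile": {
      "type": "object",
      "required": ["name", "location"],
      "properties": {
        "name": { "type": "string", "minLength": 1 },
        "location": { "type": "string", "minLength": 1 },
        "fileFormat": { "$ref": "#/definitions/cvParameter" },
        "fileProperties": {
          "type": "array",
          "items": { "$ref": "#/definitions/cvParameter" }
        }
      }
    },
    "analysisSoftware": {
      "type": "object",
      "required": ["accession", "name", "version"],
      "properties": {
        "accession": { "$ref": "#/definitions/accession" },
        "name": { "type": "string", "minLength": 1 },
        "version": { "type": "string", "minLength": 1 },
        "uri": { "type": "string" }
      }
    },
    "metadataRun": {
      "type": "object",
      "required": ["inputFiles", "analysisSoftware"],
      "properties": {
        "inputFiles": {
          "type": "array",
          "minItems": 1,
          "items": { "$ref": "#/definitions/inputFile" }
        },
        "analysisSoftware": {
          "type": "array",
          "minItems": 1,
          "items": { "$ref": "#/definitions/analysisSoftware" }
        },
        "label": { "type": "string" },
        "cvParameters": {
          "type": "array",
          "items": { "$ref": "#/definitions/cvParameter" }
        }
      }
    },
    "metadataSet": {
      "type": "object",
      "required": ["inputFiles", "analysisSoftware"],
      "properties": {
        "inputFiles": {
          "type": "array",
          "minItems": 2,
          "items": { "$ref": "#/definitions/inputFile" }
        },
        "analysisSoftware": {
          "type": "array",
          "minItems": 1,
          "items": { "$ref": "#/definitions/analysisSoftware" }
        },
        "label": { "type": "string" },
        "cvParameters": {
          "type": "array",
          "items": { "$ref": "#/definitions/cvParameter" }
        }
      }
    },
    "metricValue": {
      "x-equal-length-arrays": true,
      "anyOf": [
        { "type": ["number", "string", "boolean"] },
        { "type": "array", "minItems": 1 },
        { "type": "object", "minProperties": 1 }
      ]
    },
    "qualityMetric": {
      "type": "object",
      "required": ["accession", "name", "value"],
      "properties": {
        "accession": { "$ref": "#/definitions/accession" },
        "name": { "type": "string", "minLength": 1 },
        "description": { "type": "string" },
        "value": { "$ref": "#/definitions/metricValue" }
      }
    },
    "qualityMetrics": {
      "type": "array",
      "minItems": 1,
      "items": { "$ref": "#/definitions/qualityMetric" },
      "x-unique-by": "accession"
    },
    "runQuality": {
      "type": "object",
      "required": ["metadata", "qualityMetrics"],
      "properties": {
        "metadata": { "$ref": "#/definitions/metadataRun" },
        "qualityMetrics": { "$ref": "#/definitions/qualityMetrics" }
      }
    },
    "setQuality": {
      "type": "object",
      "required": ["metadata", "qualityMetrics"],
      "properties": {
        "metadata": { "$ref": "#/definitions/metadataSet" },
        "qualityMetrics": { "$ref": "#/definitions/qualityMetrics" }
      }
    }
  }
}
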