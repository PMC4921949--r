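{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "genevalid evidence bundle",
  "description": "Structured evidence store for variant pathogenicity classification and gene-condition clinical validity assessment. All collections are optional and default to empty; ids must be unique within their collection and every cross-reference must resolve.",
  "type": "object",
  "additionalProperties": false,
  "properties": {
    "genes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["symbol"],
        "properties": {
          "symbol": { "type": "string", "minLength": 1 },
          "aliases": { "type": "array", "items": { "type": "string" } },
          "preliminary_links": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["condition", "kind"],
              "properties": {
                "condition": { "type": "string" },
                "kind": {
                  "enum": ["case_series_vus_only", "linkage_only",
                           "functional_only", "animal_only"]
                }
              }
            }
          }
        }
      }
    },
    "conditions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": { "type": "string" },
          "name": { "type": "string" },
          "inheritance": {
            "type": "array", "items": { "enum": ["AD", "AR", "XL"] }
          },
          "features": { "type": "array", "items": { "type": "string" } },
          "is_syndromic": { "type": "boolean" },
          "is_generic": {
            "type": "boolean",
            "description": "The gene-anchored generic entity; id must be '<gene symbol>_related' and at most one may exist per gene."
          }
        }
      }
    },
    "variants": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "gene", "hgvs", "consequence"],
        "properties": {
          "id": { "type": "string" },
          "gene": { "type": "string" },
          "hgvs": {
            "type": "string",
            "pattern": "^[cpgmnr]\\.\\S+$",
            "description": "Opaque HGVS-style token; syntax-checked only."
          },
          "consequence": {
            "enum": ["missense", "nonsense", "frameshift", "splice",
                     "exonic_deletion", "synonymous", "other"]
          },
          "in_silico_support": {
            "type": "boolean",
            "description": "Pre-tagged computational support; contributes at most a supporting criterion."
          }
        }
      }
    },
    "cases": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variant", "proband", "family", "condition"],
        "properties": {
          "variant": { "type": "string" },
          "proband": { "type": "string" },
          "family": {
            "type": "string",
            "description": "Distinct family ids define unrelatedness."
          },
          "condition": { "type": "string" },
          "phenotype_features": {
            "type": "array", "items": { "type": "string" }
          },
          "severity": { "enum": ["mild", "classic", "severe"] },
          "onset": { "enum": ["infantile", "childhood", "adult"] },
          "de_novo": { "enum": ["none", "assumed", "confirmed_parentage"] },
          "zygosity": { "enum": ["het", "hom", "compound_het"] }
        }
      }
    },
    "segregations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variant", "family", "lod", "condition"],
        "properties": {
          "variant": { "type": "string" },
          "family": { "type": "string" },
          "lod": {
            "type": "number",
            "description": "log10 odds; may be a combined multi-family value."
          },
          "families": { "type": "integer", "minimum": 1 },
          "condition": { "type": "string" }
        }
      }
    },
    "functionals": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variant", "assay", "effect"],
        "properties": {
          "variant": { "type": "string" },
          "assay": { "enum": ["biochemical", "cellular", "animal_model"] },
          "effect": {
            "enum": ["loss_of_function", "gain_of_function", "no_effect"]
          },
          "mechanism_concordant": { "type": "boolean" }
        }
      }
    },
    "populations": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variant", "cohort", "allele_count", "allele_number"],
        "properties": {
          "variant": { "type": "string" },
          "cohort": { "type": "string" },
          "allele_count": { "type": "integer", "minimum": 0 },
          "allele_number": { "type": "integer", "minimum": 1 }
        }
      }
    }
  }
}
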