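{
  "label": "tajikistan-recalibrated",
  "horizon_years": 1,
  "baseline_survival": 0.4708,
  "recalibration_shape": 0.8093,
  "coefficients": {
    "sex": {
      "female": -0.45
    },
    "age_band": {
      "a30_39": -0.25,
      "a40_49": -0.6,
      "a50plus": -1
    },
    "length_of_incarceration": {
      "m6_12": -0.0098,
      "m12_24": 0.5949,
      "ge24m": -0.1066
    },
    "violent_index_offense": 0.25,
    "previous_violent_crime": 0.6,
    "civil_status": {
      "unmarried": 0.2
    },
    "education": {
      "y9_11": -0.25,
      "ge12y": -0.55
    },
    "employment": -0.55,
    "income": {
      "stable": -0.35
    },
    "alcohol_misuse": 0.4,
    "drug_misuse": 0.45,
    "any_mental_disorder": 0.25,
    "any_severe_mental_disorder": 0.35
  },
  "imputed_terms": {
    "immigrant_status": {
      "beta": -0.0348,
      "mean": 0.3075
    },
    "neighborhood_deprivation": {
      "beta": 0.0259,
      "mean": 0.39
    }
  },
  "schema": {
    "sex": {
      "name": "sex",
      "kind": "categorical",
      "required": true,
      "levels": [
        "male",
        "female"
      ]
    },
    "age_band": {
      "name": "age_band",
      "kind": "categorical",
      "required": true,
      "levels": [
        "a18_29",
        "a30_39",
        "a40_49",
        "a50plus"
      ]
    },
    "length_of_incarceration": {
      "name": "length_of_incarceration",
      "kind": "categorical",
      "required": true,
      "levels": [
        "lt6m",
        "m6_12",
        "m12_24",
        "ge24m"
      ]
    },
    "violent_index_offense": {
      "name": "violent_index_offense",
      "kind": "binary",
      "required": true
    },
    "previous_violent_crime": {
      "name": "previous_violent_crime",
      "kind": "binary",
      "required": true
    },
    "civil_status": {
      "name": "civil_status",
      "kind": "categorical",
      "required": true,
      "levels": [
        "other",
        "unmarried"
      ]
    },
    "education": {
      "name": "education",
      "kind": "categorical",
      "required": true,
      "levels": [
        "lt9y",
        "y9_11",
        "ge12y"
      ]
    },
    "employment": {
      "name": "employment",
      "kind": "binary",
      "required": true
    },
    "income": {
      "name": "income",
      "kind": "categorical",
      "required": true,
      "levels": [
        "low",
        "stable"
      ]
    },
    "alcohol_misuse": {
      "name": "alcohol_misuse",
      "kind": "binary",
      "required": true
    },
    "drug_misuse": {
      "name": "drug_misuse",
      "kind": "binary",
      "required": true
    },
    "any_mental_disorder": {
      "name": "any_mental_disorder",
      "kind": "binary",
      "required": true
    },
    "any_severe_mental_disorder": {
      "name": "any_severe_mental_disorder",
      "kind": "binary",
      "required": true
    },
    "immigrant_status": {
      "name": "immigrant_status",
      "kind": "binary",
      "required": false
    },
    "neighborhood_deprivation": {
      "name": "neighborhood_deprivation",
      "kind": "continuous",
      "required": false
    }
  }
}
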