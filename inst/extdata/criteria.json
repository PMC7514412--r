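{
  "level1": {
    "rfv_conditions": [
      {
        "name": "Dead on arrival (RFV code)",
        "codes": 58950
      },
      {
        "name": "Respiratory arrest",
        "codes": 57051
      },
      {
        "name": "Cardiac arrest",
        "codes": 57050
      },
      {
        "name": "Cardiopulmonary arrest",
        "codes": 57055
      },
      {
        "name": "Unconscious on arrival",
        "codes": 11100
      }
    ],
    "flags": [
      {
        "name": "Dead on arrival (checkbox)",
        "field": "doa_flag"
      },
      {
        "name": "Endotracheal intubation",
        "field": "intubation_flag"
      },
      {
        "name": "Cardiopulmonary resuscitation",
        "field": "cpr_flag"
      }
    ],
    "vitals": [
      {
        "name": "Pulse ≤50 and age >25",
        "vital": "pulse_bpm",
        "le": 50,
        "age_gt_years": 25
      },
      {
        "name": "Systolic blood pressure ≤80 and Age >25",
        "vital": "bp_systolic_mmhg",
        "le": 80,
        "age_gt_years": 25
      }
    ]
  },
  "level2": {
    "rfv_conditions": [
      {
        "name": "Fainting (Syncope)",
        "codes": 10350
      },
      {
        "name": "Hostile behavior",
        "codes": 11530
      },
      {
        "name": "Neurological weakness or speech difficulty",
        "codes": [12050, 12250]
      },
      {
        "name": "Shortness of breath/breathing problem",
        "codes": [14150, 14200]
      },
      {
        "name": "Gastrointestinal bleeding",
        "codes": [15350, 15360]
      },
      {
        "name": "Retention of urine",
        "codes": 16550
      },
      {
        "name": "Sepsis, septicemia",
        "codes": 24600
      },
      {
        "name": "Ischemic heart disease",
        "codes": 22250
      },
      {
        "name": "Violence/self-harm",
        "codes": [58200, 11520]
      },
      {
        "name": "Rape",
        "codes": 58250
      },
      {
        "name": "Altered level of consciousness",
        "codes": 11050
      },
      {
        "name": "Abdominal pain (elderly)",
        "codes": 15450,
        "age_min_years": 65
      },
      {
        "name": "Abdominal pain, vomiting and diarrhea",
        "all_of": [15450, 15300, 15250]
      },
      {
        "name": "Abdominal pain (youth)",
        "codes": 15450,
        "age_max_years": 2
      },
      {
        "name": "Head Trauma (infants)",
        "codes": 58550,
        "age_max_years": 1
      }
    ],
    "vital_bands": [
      {
        "age_min_days": 0,
        "age_max_days": 90,
        "pulse_gt": 180,
        "temp_ge_f": 100.4
      },
      {
        "age_min_days": 90,
        "age_max_years": 3,
        "pulse_gt": 160
      },
      {
        "age_min_years": 3,
        "age_max_years": 8,
        "pulse_gt": 140
      },
      {
        "age_min_years": 8,
        "pulse_gt": 100
      }
    ]
  },
  "level3": {
    "severe_pain": {
      "name": "Severe pain",
      "pain_min": 4
    },
    "pediatric_fever": {
      "name": "Pediatric fever",
      "age_max_years": 2,
      "temp_ge_f": 100.4
    },
    "motor_vehicle_accident": {
      "name": "Motor vehicle accident",
      "codes": [58000, 58005]
    }
  },
  "resources": {
    "groups": [
      {
        "name": "laboratory",
        "count": 1,
        "items": ["CBC", "ELECTROL", "CARDENZ", "LFT", "BLOODCX", "URINE"]
      },
      {
        "name": "xray",
        "count": 1,
        "items": "XRAY"
      },
      {
        "name": "ct",
        "count": 1,
        "items": "CATSCAN"
      },
      {
        "name": "mri",
        "count": 1,
        "items": "MRI"
      },
      {
        "name": "ultrasound",
        "count": 1,
        "items": "ULTRASND"
      },
      {
        "name": "ecg",
        "count": 1,
        "items": "EKG"
      },
      {
        "name": "iv_fluids",
        "count": 1,
        "items": "IVFLUIDS"
      },
      {
        "name": "parenteral_meds",
        "count": 1,
        "items": "INJECTION"
      },
      {
        "name": "simple_procedure",
        "count": 1,
        "items": ["SUTURE", "SPLINT", "NEBULIZER", "FOLEY"]
      },
      {
        "name": "complex_procedure",
        "count": 2,
        "items": ["CENTLINE", "LUMBAR", "SEDATION"]
      }
    ],
    "excluded_items": ["ORALMED", "GLUCOSEPOC"]
  }
}
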