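year: 2014
format: fwf
fields:
- raw: VISITID
  canonical: visit_id
  width: 8
  type: character
- raw: VYEAR
  canonical: year
  width: 5
  type: integer
- raw: RFV1
  canonical: rfv1
  width: 7
  type: integer
  sentinels:
  - -9
- raw: RFV2
  canonical: rfv2
  width: 7
  type: integer
  sentinels:
  - -9
- raw: RFV3
  canonical: rfv3
  width: 7
  type: integer
  sentinels:
  - -9
- raw: AGE
  canonical: age_years
  width: 4
  type: integer
  sentinels:
  - -9
- raw: AGEDAYS
  canonical: age_days
  width: 5
  type: integer
  sentinels:
  - -7
  - -9
- raw: PULSE
  canonical: pulse_bpm
  width: 5
  type: integer
  sentinels:
  - -9
  - 998
- raw: BPSYS
  canonical: bp_systolic_mmhg
  width: 5
  type: integer
  sentinels:
  - -9
  - 998
- raw: TEMPF
  canonical: temp_f
  width: 6
  type: numeric
  sentinels:
  - -9
  scale: 0.1
- raw: PAINSCALE
  canonical: pain_level
  width: 4
  type: integer
  sentinels:
  - -8
  - -9
- raw: DOA
  canonical: doa_flag
  width: 2
  type: checkbox
- raw: ENDOINT
  canonical: intubation_flag
  width: 2
  type: checkbox
- raw: CPR
  canonical: cpr_flag
  width: 2
  type: checkbox
- raw: IMMED
  canonical: immed_recorded
  width: 4
  type: integer
  sentinels:
  - -8
  - -9
- raw: ADMITHOS
  canonical: admitted_flag
  width: 3
  type: yesno
  sentinels:
  - -9
- raw: ICUADMIT
  canonical: critical_care_flag
  width: 3
  type: yesno
  sentinels:
  - -9
- raw: ARREMS
  canonical: ambulance_flag
  width: 3
  type: yesno
  sentinels:
  - -9
- raw: LWBS
  canonical: lwbs_flag
  width: 3
  type: yesno
  sentinels:
  - -9
- raw: WAITTIME
  canonical: wait_minutes
  width: 7
  type: numeric
  sentinels:
  - -9
  digits: 0
- raw: LOV
  canonical: los_minutes
  width: 7
  type: numeric
  sentinels:
  - -9
  digits: 0
- raw: PATWT
  canonical: visit_weight
  width: 12
  type: numeric
  digits: 2
- raw: CSTRATM
  canonical: stratum_id
  width: 9
  type: character
- raw: CPSUM
  canonical: psu_id
  width: 9
  type: character
- raw: ESAID
  canonical: service_area
  width: 11
  type: character
service_fields:
- CBC
- ELECTROL
- CARDENZ
- LFT
- BLOODCX
- URINE
- XRAY
- CATSCAN
- MRI
- ULTRASND
- EKG
- IVFLUIDS
- INJECTION
- SUTURE
- SPLINT
- NEBULIZER
- FOLEY
- CENTLINE
- LUMBAR
- SEDATION
- ORALMED
- GLUCOSEPOC
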