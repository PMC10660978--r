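# Default (version 1) scoring configuration for PAD case-finding.
#
# Eight equally weighted categories. Item weights below are a documented,
# deliberately simple placeholder scheme chosen to reproduce the published
# score *structure* (per-occurrence antibiotic points, per-code infection
# points, a 3-point GP-visit frequency criterion); the original catalog's
# per-item weights are not public. Edit freely: everything that defines the
# score lives in this file, not in code.
#
# Code matching is exact or by prefix at a sub-code boundary
# ("R81" matches "R81.02"). Dates count within a half-open window
# (censor_date - lookback_years, censor_date].
version: v1
age_window: [12, 70]
category_weights:
  antibiotics: 1
  rti: 1
  gi: 1
  other_infections: 1
  autoimmune: 1
  malignancy_lymphoproliferative_other: 1
  laboratory: 1
  gp_visits: 1
# Diagnoses that can be both a PAD complication and a cause of secondary
# antibody deficiency: their registration date becomes the censoring date.
ambiguous_diagnosis_codes: [B72, B74.02]
cutoffs:
  step1: 17            # version-1 high-risk threshold for step 1
  step2: 15.5          # version-3 Youden threshold within the high-risk set
  step2_full_sensitivity: 9.5
  spad_referral: 21.5  # version-3 score advising referral without reduced Ig
items:
  # --- Antibiotic prescriptions (4-year lookback) -----------------------
  - item_id: antibiotic_rx
    category: antibiotics
    codes: [J01]               # systemic antibacterials, ATC stem
    kind: antibiotic_prescription
    lookback_years: 4
    weight: 1.5
    counting: per_occurrence
    cap: 45
  # --- Respiratory tract infections (4-year lookback) -------------------
  - item_id: pneumonia
    category: rti
    codes: [R81]
    lookback_years: 4
    weight: 2.5
    counting: per_occurrence
  - item_id: acute_bronchitis
    category: rti
    codes: [R78]
    lookback_years: 4
    weight: 1.5
    counting: per_occurrence
  - item_id: sinusitis
    category: rti
    codes: [R75]
    lookback_years: 4
    weight: 1.5
    counting: per_occurrence
  - item_id: otitis_media
    category: rti
    codes: [H71]
    lookback_years: 4
    weight: 1.5
    counting: per_occurrence
  - item_id: upper_respiratory_infection
    category: rti
    codes: [R74]
    lookback_years: 4
    weight: 1.0
    counting: per_occurrence
  - item_id: acute_tonsillitis
    category: rti
    codes: [R76]
    lookback_years: 4
    weight: 1.5
    counting: per_occurrence
  - item_id: influenza
    category: rti
    codes: [R80]
    lookback_years: 4
    weight: 0.5
    counting: per_occurrence
  # --- Gastro-intestinal complaints (4-year lookback) -------------------
  - item_id: gi_infection
    category: gi
    codes: [D70, D73]
    lookback_years: 4
    weight: 2.0
    counting: per_occurrence
  - item_id: chronic_diarrhoea
    category: gi
    codes: [D11]
    lookback_years: 4
    weight: 1.0
    counting: per_occurrence
  # --- Other infections (4-year lookback) -------------------------------
  - item_id: meningitis
    category: other_infections
    codes: [N71]
    lookback_years: 4
    weight: 3.0
    counting: per_occurrence
  - item_id: osteomyelitis
    category: other_infections
    codes: [L70.01]
    lookback_years: 4
    weight: 3.0
    counting: per_occurrence
  - item_id: sepsis
    category: other_infections
    codes: [A78]
    lookback_years: 4
    weight: 3.0
    counting: per_occurrence
  - item_id: cellulitis_erysipelas
    category: other_infections
    codes: [S76]
    lookback_years: 4
    weight: 1.5
    counting: per_occurrence
  - item_id: herpes_zoster
    category: other_infections
    codes: [S70]
    lookback_years: 4
    weight: 1.0
    counting: per_occurrence
  # --- Auto-immune symptoms (10-year lookback) --------------------------
  - item_id: rheumatoid_arthritis
    category: autoimmune
    codes: [L88]
    lookback_years: 10
    weight: 1.5
    counting: once
  - item_id: inflammatory_bowel_disease
    category: autoimmune
    codes: [D94]
    lookback_years: 10
    weight: 1.5
    counting: once
  - item_id: autoimmune_thyroiditis
    category: autoimmune
    codes: [T86]
    lookback_years: 10
    weight: 1.0
    counting: once
  - item_id: immune_thrombocytopenia
    category: autoimmune
    codes: [B83]
    lookback_years: 10
    weight: 1.5
    counting: once
  - item_id: pernicious_anaemia
    category: autoimmune
    codes: [B81]
    lookback_years: 10
    weight: 1.0
    counting: once
  # --- Malignancy, lymphoproliferative and other symptoms (10-year) -----
  - item_id: lymphadenopathy
    category: malignancy_lymphoproliferative_other
    codes: [B02]
    lookback_years: 10
    weight: 1.0
    counting: once
  - item_id: splenomegaly
    category: malignancy_lymphoproliferative_other
    codes: [B87]
    lookback_years: 10
    weight: 1.5
    counting: once
  - item_id: bronchiectasis
    category: malignancy_lymphoproliferative_other
    codes: [R95.01]
    lookback_years: 10
    weight: 2.0
    counting: once
  - item_id: malignancy_other
    category: malignancy_lymphoproliferative_other
    codes: [A79]
    lookback_years: 10
    weight: 1.0
    counting: once
  # --- Previously registered reduced immunoglobulins (10-year) ----------
  # Thresholds shared with the immunoglobulin module's adult bands.
  - item_id: low_igg_on_record
    category: laboratory
    codes: [IGG]
    kind: lab_result
    lookback_years: 10
    weight: 5.0
    counting: once
    value_below: 7.0
  - item_id: low_igm_on_record
    category: laboratory
    codes: [IGM]
    kind: lab_result
    lookback_years: 10
    weight: 5.0
    counting: once
    value_below: 0.4
  - item_id: low_iga_on_record
    category: laboratory
    codes: [IGA]
    kind: lab_result
    lookback_years: 10
    weight: 5.0
    counting: once
    value_below: 0.7
  # --- GP visit frequency ----------------------------------------------
  - item_id: frequent_gp_visits
    category: gp_visits
    codes: []
    kind: gp_visit
    lookback_years: 1
    weight: 3.0
    counting: threshold
    min_count: 6
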