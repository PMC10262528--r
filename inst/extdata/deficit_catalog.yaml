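# Synthetic deficit catalog for trials in cognitive impairment: 40 physical
# deficits (18 medication-inferred conditions, 6 laboratory thresholds,
# 3 clinical measurements + polypharmacy, 5 neurological-examination
# binaries, 7 ADL ordinals) plus 5 cognitive deficits. Constructed to satisfy
# the standard frailty-index criteria (>= 30 deficits, >= 5 physiological
# systems); it is a plausible stand-in, not any trial's actual deficit list.
name: synthetic-dementia-mci
version: '1.0'
cognitive_n: 5
deficits:
- id: hypertension
  label: Hypertension (medication-inferred)
  system: cardiovascular
  kind: binary
  source: medication
- id: dyslipidaemia
  label: Dyslipidaemia (medication-inferred)
  system: cardiovascular
  kind: binary
  source: medication
- id: ischaemic_heart_disease
  label: Ischaemic heart disease (medication-inferred)
  system: cardiovascular
  kind: binary
  source: medication
- id: heart_failure
  label: Heart failure (medication-inferred)
  system: cardiovascular
  kind: binary
  source: medication
- id: arrhythmia
  label: Cardiac arrhythmia (medication-inferred)
  system: cardiovascular
  kind: binary
  source: medication
- id: thromboembolic_disease
  label: Thromboembolic disease (medication-inferred)
  system: cardiovascular
  kind: binary
  source: medication
- id: diabetes
  label: Diabetes mellitus (medication-inferred)
  system: endocrine
  kind: binary
  source: medication
- id: thyroid_disorder
  label: Thyroid disorder (medication-inferred)
  system: endocrine
  kind: binary
  source: medication
- id: chronic_lung_disease
  label: Chronic lung disease (medication-inferred)
  system: respiratory
  kind: binary
  source: medication
- id: acid_related_disease
  label: Peptic ulcer / reflux disease (medication-inferred)
  system: gastrointestinal
  kind: binary
  source: medication
- id: depression
  label: Depression (medication-inferred)
  system: mental-health
  kind: binary
  source: medication
- id: anxiety
  label: Anxiety disorder (medication-inferred)
  system: mental-health
  kind: binary
  source: medication
- id: psychotic_illness
  label: Psychotic illness (medication-inferred)
  system: mental-health
  kind: binary
  source: medication
- id: epilepsy
  label: Epilepsy (medication-inferred)
  system: neurological
  kind: binary
  source: medication
- id: parkinsonism
  label: Parkinsonism (medication-inferred)
  system: neurological
  kind: binary
  source: medication
- id: osteoporosis
  label: Osteoporosis (medication-inferred)
  system: musculoskeletal
  kind: binary
  source: medication
- id: chronic_pain
  label: Chronic pain / arthritis (medication-inferred)
  system: musculoskeletal
  kind: binary
  source: medication
- id: gout
  label: Gout (medication-inferred)
  system: musculoskeletal
  kind: binary
  source: medication
- id: anaemia
  label: Anaemia (haemoglobin < 12 g/dL)
  system: laboratory
  kind: threshold
  threshold: 12.0
  direction: below
- id: renal_impairment
  label: Renal impairment (eGFR < 60)
  system: laboratory
  kind: threshold
  threshold: 60.0
  direction: below
- id: hypoalbuminaemia
  label: Hypoalbuminaemia (albumin < 35 g/L)
  system: laboratory
  kind: threshold
  threshold: 35.0
  direction: below
- id: hyperglycaemia
  label: Elevated fasting glucose (> 7 mmol/L)
  system: laboratory
  kind: threshold
  threshold: 7.0
  direction: above
- id: leukocytosis
  label: Raised white-cell count (> 11 x10^9/L)
  system: laboratory
  kind: threshold
  threshold: 11.0
  direction: above
- id: elevated_crp
  label: Raised C-reactive protein (> 10 mg/L)
  system: laboratory
  kind: threshold
  threshold: 10.0
  direction: above
- id: high_systolic_bp
  label: Systolic blood pressure >= 160 mmHg
  system: clinical-measurement
  kind: threshold
  threshold: 160.0
  direction: above
- id: low_bmi
  label: Body-mass index <= 20 kg/m2
  system: clinical-measurement
  kind: threshold
  threshold: 20.0
  direction: below
- id: ecg_abnormality
  label: Electrocardiographic abnormality
  system: clinical-measurement
  kind: binary
- id: polypharmacy
  label: Polypharmacy (5+ medications)
  system: clinical-measurement
  kind: binary
  source: polypharmacy
- id: muscle_weakness
  label: Muscle weakness on neurological examination
  system: neurological
  kind: binary
- id: sensory_impairment
  label: Sensory impairment on neurological examination
  system: neurological
  kind: binary
- id: tremor
  label: Tremor on neurological examination
  system: neurological
  kind: binary
- id: gait_abnormality
  label: Gait abnormality on neurological examination
  system: neurological
  kind: binary
- id: impaired_coordination
  label: Impaired coordination on neurological examination
  system: neurological
  kind: binary
- id: adl_bathing
  label: Difficulty bathing (ADL, 4-level)
  system: ADL
  kind: ordinal
  n_levels: 4
- id: adl_dressing
  label: Difficulty dressing (ADL, 4-level)
  system: ADL
  kind: ordinal
  n_levels: 4
- id: adl_toileting
  label: Difficulty toileting (ADL, 4-level)
  system: ADL
  kind: ordinal
  n_levels: 4
- id: adl_transfer
  label: Difficulty transferring (ADL, 4-level)
  system: ADL
  kind: ordinal
  n_levels: 4
- id: adl_feeding
  label: Difficulty feeding (ADL, 4-level)
  system: ADL
  kind: ordinal
  n_levels: 4
- id: adl_continence
  label: Incontinence (ADL, 4-level)
  system: ADL
  kind: ordinal
  n_levels: 4
- id: adl_mobility
  label: Impaired mobility (ADL, 4-level)
  system: ADL
  kind: ordinal
  n_levels: 4
- id: cog_orientation
  label: Impaired orientation (4-level)
  system: cognition
  kind: ordinal
  n_levels: 4
  variant_class: cognitive
- id: cog_memory
  label: Impaired memory (4-level)
  system: cognition
  kind: ordinal
  n_levels: 4
  variant_class: cognitive
- id: cog_language
  label: Impaired language (4-level)
  system: cognition
  kind: ordinal
  n_levels: 4
  variant_class: cognitive
- id: cog_executive
  label: Impaired executive function (4-level)
  system: cognition
  kind: ordinal
  n_levels: 4
  variant_class: cognitive
- id: cog_praxis
  label: Impaired constructional praxis (4-level)
  system: cognition
  kind: ordinal
  n_levels: 4
  variant_class: cognitive
medication_map:
- pattern: antihypertensive
  condition: hypertension
- pattern: statin
  condition: dyslipidaemia
- pattern: nitrate
  condition: ischaemic_heart_disease
- pattern: loop_diuretic
  condition: heart_failure
- pattern: antiarrhythmic
  condition: arrhythmia
- pattern: anticoagulant
  condition: thromboembolic_disease
- pattern: antidiabetic
  condition: diabetes
- pattern: thyroid_hormone
  condition: thyroid_disorder
- pattern: bronchodilator
  condition: chronic_lung_disease
- pattern: antacid_ppi
  condition: acid_related_disease
- pattern: antidepressant
  condition: depression
- pattern: anxiolytic
  condition: anxiety
- pattern: antipsychotic
  condition: psychotic_illness
- pattern: antiepileptic
  condition: epilepsy
- pattern: antiparkinson
  condition: parkinsonism
- pattern: bisphosphonate
  condition: osteoporosis
- pattern: analgesic
  condition: chronic_pain
- pattern: urate_lowering
  condition: gout
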