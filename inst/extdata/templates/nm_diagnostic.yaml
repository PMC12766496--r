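# Synthetic nuclear-medicine DIAGNOSTIC risk-assessment template.
# The process map and failure-mode register below are fixtures authored for
# this package: they follow the standard structure of a conventional
# NM/PET diagnostic workflow (7 steps, 13 failure modes, occurrence 1-2,
# detectability 1-4, RPN between 1 and 20) but are NOT a reproduction of any
# institution's survey data.
# Probabilities in this file are expressed in percent.
name: nm_diagnostic
scenario: diagnostic
synthetic: true
rating_system: default
workflows:
  - workflow_id: diag_small
    name: Conventional NM diagnostic service (small)
    scenario: diagnostic
    patients_per_year: 1300
    size_class: small
steps:
  - step_id: s1
    name: Patient admittance
    order: 1
    functions:
      - Identify the patient unambiguously
      - Verify the examination request
      - Screen for pregnancy and breastfeeding
  - step_id: s2
    name: Radiopharmaceutical / activity preparation
    order: 2
    functions:
      - Prepare the prescribed radiopharmaceutical
      - Measure and record the activity
      - Label the syringe for the intended patient
  - step_id: s3
    name: Medical history
    order: 3
    functions:
      - Record relevant clinical history
      - Identify interfering medication
  - step_id: s4
    name: Radiopharmaceutical administration
    order: 4
    functions:
      - Administer the full activity to the correct patient
      - Avoid contamination during injection
  - step_id: s5
    name: Image acquisition
    order: 5
    functions:
      - Acquire images with the correct protocol
      - Keep the patient still and positioned
  - step_id: s6
    name: Image processing
    order: 6
    functions:
      - Reconstruct with validated parameters
      - Keep images attributed to the correct patient
  - step_id: s7
    name: Patient discharge and reporting
    order: 7
    functions:
      - Give radiation-protection instructions
      - Archive and report under the correct record
effects:
  - effect_id: incorrect_exam_attribution
    label: Incorrect attribution of examination
    severity_default: 7
  - effect_id: pregnant_administration
    label: Administration to a pregnant patient
    severity_default: 10
  - effect_id: wrong_radiopharmaceutical
    label: Wrong radiopharmaceutical administered
    severity_default: 8
  - effect_id: incorrect_activity
    label: Incorrect activity administered
    severity_default: 5
  - effect_id: non_diagnostic_image
    label: Non-diagnostic image quality
    severity_default: 4
  - effect_id: repeat_examination
    label: Repetition of the examination
    severity_default: 4
  - effect_id: rebooking
    label: Rebooking of the examination
    severity_default: 2
  - effect_id: unintended_exposure
    label: Unintended exposure of carers or public
    severity_default: 5
failure_modes:
  - id: d01
    step_ref: s1
    cause: Homonymous patients and manual identity check
    cause_class: organizational
    mode: Examination booked under the wrong patient record
    effect_id: incorrect_exam_attribution
    severity: 10
    occurrence_initial: 1
    detectability_initial: 2
  - id: d02
    step_ref: s1
    cause: Pregnancy status not asked at admittance
    cause_class: procedural
    mode: Radiopharmaceutical administered to a pregnant patient
    effect_id: pregnant_administration
    severity: 10
    occurrence_initial: 1
    detectability_initial: 1
  - id: d03
    step_ref: s2
    cause: Syringes for different patients prepared side by side
    cause_class: procedural
    mode: Incorrect syringe identification
    effect_id: wrong_radiopharmaceutical
    severity: 8
    occurrence_initial: 1
    detectability_initial: 2
  - id: d04
    step_ref: s2
    cause: Dose calibrator drift not noticed
    cause_class: technical
    mode: Activity measured incorrectly
    effect_id: incorrect_activity
    severity: 5
    occurrence_initial: 2
    detectability_initial: 2
  - id: d05
    step_ref: s3
    cause: Interfering medication not recorded in history
    cause_class: training
    mode: Uptake-altering medication missed
    effect_id: non_diagnostic_image
    severity: 4
    occurrence_initial: 2
    detectability_initial: 2
  - id: d06
    step_ref: s4
    cause: Difficult venous access
    cause_class: technical
    mode: Extravasation of the radiopharmaceutical
    effect_id: repeat_examination
    severity: 4
    occurrence_initial: 2
    detectability_initial: 1
  - id: d07
    step_ref: s4
    cause: Unnoticed droplet spill during injection
    cause_class: procedural
    mode: Contamination of the gamma camera during the procedure
    effect_id: rebooking
    severity: 1
    occurrence_initial: 2
    detectability_initial: 4
  - id: d08
    step_ref: s5
    cause: Long acquisition and patient discomfort
    cause_class: organizational
    mode: Patient motion during acquisition
    effect_id: repeat_examination
    severity: 2
    occurrence_initial: 2
    detectability_initial: 1
  - id: d09
    step_ref: s5
    cause: Protocol list not updated on the console
    cause_class: informatic_technology
    mode: Wrong acquisition protocol selected
    effect_id: non_diagnostic_image
    severity: 3
    occurrence_initial: 1
    detectability_initial: 3
  - id: d10
    step_ref: s6
    cause: Reconstruction preset altered after maintenance
    cause_class: informatic_technology
    mode: Incorrect reconstruction parameters applied
    effect_id: non_diagnostic_image
    severity: 4
    occurrence_initial: 1
    detectability_initial: 4
  - id: d11
    step_ref: s6
    cause: Manual renaming of image series
    cause_class: informatic_technology
    mode: Image series attributed to the wrong patient
    effect_id: incorrect_exam_attribution
    severity: 5
    occurrence_initial: 1
    detectability_initial: 4
  - id: d12
    step_ref: s7
    cause: Discharge instructions not handed over
    cause_class: training
    mode: Radiation-protection advice to carers omitted
    effect_id: unintended_exposure
    severity: 2
    occurrence_initial: 2
    detectability_initial: 2
  - id: d13
    step_ref: s7
    cause: Report filed into the wrong record
    cause_class: organizational
    mode: Report archived under another patient
    effect_id: incorrect_exam_attribution
    severity: 1
    occurrence_initial: 1
    detectability_initial: 1
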