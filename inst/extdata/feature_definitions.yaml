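# Versioned baseline feature definitions for the cognitive-decline
# prognostic analysis.  Comparators are strict: gt = value > cutoff,
# lt = value < cutoff; equality at the cutoff means the feature is absent.
# Single-item ordinal features encode "response >= k" as gt (k - 1).
# "Moderate or severe" MDS-UPDRS item features use >= 3 (item anchors label
# 3 = moderate, 4 = severe); this reading is flagged as unverified.
# STAI "very much so" / "almost always" cutoffs take the maximum response
# category (4).  hypothesis_sign: +1 means higher raw values are riskier.
version: 1
features:
  - name: hyposmia
    source: upsit_total
    comparator: lt
    cutoff_female: 31
    cutoff_male: 30
    hypothesis_sign: -1
    hypothesis: olfaction
    description: UPSIT score lower than 31 for females or 30 for males
  - name: lightheadedness
    source: u1_lightheadedness
    comparator: gt
    cutoff: 2
    hypothesis_sign: 1
    hypothesis: orthostatic
    description: Moderate or severe light-headedness on standing (MDS-UPDRS 1.12)
  - name: speech_disorder
    source: u2_speech
    comparator: gt
    cutoff: 2
    hypothesis_sign: 1
    hypothesis: bulbar
    description: Moderate or severe speech disorder (MDS-UPDRS 2.1)
  - name: chewing_swallowing
    source: u2_chewing
    comparator: gt
    cutoff: 2
    hypothesis_sign: 1
    hypothesis: bulbar
    description: Moderate or severe chewing and swallowing difficulty (MDS-UPDRS 2.3)
  - name: tremor_impact
    source: u2_tremor
    comparator: gt
    cutoff: 2
    hypothesis_sign: 1
    hypothesis: tremor
    description: Moderate or severe tremor impact (MDS-UPDRS 2.10)
  - name: right_rigidity
    source: rigidity_right
    comparator: gt
    cutoff: 5
    hypothesis_sign: 1
    hypothesis: motor_laterality
    description: Sum of right upper and lower limb MDS-UPDRS III rigidity higher than 5
  - name: stroke
    source: stroke
    comparator: flag
    hypothesis_sign: 1
    hypothesis: vascular
    description: History of ischemic or hemorrhagic stroke
  - name: stool_incontinence
    source: scopa_7
    comparator: gt
    cutoff: 0
    hypothesis_sign: 1
    hypothesis: autonomic_gi
    description: Involuntary loss of stools in the past month (SCOPA-AUT 7)
  - name: urinary_frequency
    source: scopa_12
    comparator: gt
    cutoff: 0
    hypothesis_sign: 1
    hypothesis: autonomic_urinary
    description: Passing urine again within 2 hours (SCOPA-AUT 12)
  - name: nocturia
    source: scopa_13
    comparator: gt
    cutoff: 0
    hypothesis_sign: 1
    hypothesis: autonomic_urinary
    description: Passing urine at night (SCOPA-AUT 13)
  - name: fainting
    source: scopa_16
    comparator: gt
    cutoff: 0
    hypothesis_sign: 1
    hypothesis: orthostatic
    description: Fainted in the past 6 months (SCOPA-AUT 16)
  - name: autonomic_burden
    source: scopa_total
    comparator: gt
    cutoff: 20
    hypothesis_sign: 1
    hypothesis: autonomic_global
    description: Total SCOPA-AUT score higher than 20
  - name: feeling_upset
    source: stai1_6
    comparator: gt
    cutoff: 3
    hypothesis_sign: 1
    hypothesis: anxiety
    description: I feel upset, very much so (STAI-X1 question 6)
  - name: difficulties_piling
    source: stai2_8
    comparator: gt
    cutoff: 3
    hypothesis_sign: 1
    hypothesis: anxiety
    description: Difficulties are piling up, almost always (STAI-X2 question 8)
  - name: taking_things_hard
    source: stai2_11
    comparator: gt
    cutoff: 3
    hypothesis_sign: 1
    hypothesis: anxiety
    description: Inclined to take things hard, almost always (STAI-X2 question 11)
  - name: rumination
    source: stai2_18
    comparator: gt
    cutoff: 3
    hypothesis_sign: 1
    hypothesis: anxiety
    description: Cannot get disappointments out of my mind, almost always (STAI-X2 question 18)
  - name: trait_anxiety
    source: stai2_total
    comparator: gt
    cutoff: 50
    hypothesis_sign: 1
    hypothesis: anxiety
    description: Trait anxiety score higher than 50 (STAI-X2 total)
  - name: rhino_naming
    source: moca_rhino
    comparator: lt
    cutoff: 1
    hypothesis_sign: -1
    hypothesis: cognition_naming
    description: Unable to name the rhinoceros (MoCA naming)
  - name: clock_numbers
    source: moca_clock_numbers
    comparator: lt
    cutoff: 1
    hypothesis_sign: -1
    hypothesis: cognition_visuospatial
    description: Clock numbers drawn incorrectly (MoCA clock drawing)
  - name: visuospatial_executive
    source: moca_visuospatial_executive
    comparator: lt
    cutoff: 3
    hypothesis_sign: -1
    hypothesis: cognition_visuospatial
    description: Visuospatial/executive domain score less than 3 (MoCA)
  - name: low_moca_z
    source: moca_z
    comparator: lt
    cutoff: -1
    hypothesis_sign: -1
    hypothesis: cognition_global
    description: MoCA total normalized to z-score lower than -1
  - name: vocalization
    source: rbdsq_6_1
    comparator: gt
    cutoff: 0
    hypothesis_sign: 1
    hypothesis: rbd
    description: Speaking, shouting, swearing or laughing loudly during dreams (RBDSQ 6.1)
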