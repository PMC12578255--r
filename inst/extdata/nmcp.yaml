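cohort_size: 15000.0
profiles:
- assay_id: maldi_head_thorax
  time_per_sample: '2.01'
  adjusted_time_per_sample: '2.01'
  materials_cost_per_sample: '0.59'
  labour_cost_per_sample: '0.11'
- assay_id: maldi_bloodmeal
  time_per_sample: '2.01'
  adjusted_time_per_sample: '2.01'
  materials_cost_per_sample: '0.59'
  labour_cost_per_sample: '0.11'
- assay_id: pcr_species
  time_per_sample: '2.62'
  adjusted_time_per_sample: '0.62'
  materials_cost_per_sample: '1.49'
  labour_cost_per_sample: '0.3'
- assay_id: sanger_sequencing
  time_per_sample: '15.958'
  adjusted_time_per_sample: '12.624'
  materials_cost_per_sample: '23.23'
  labour_cost_per_sample: '0.51'
- assay_id: csp_elisa
  time_per_sample: '4.245'
  adjusted_time_per_sample: '1.579'
  materials_cost_per_sample: '0.3'
  labour_cost_per_sample: '0.12'
- assay_id: csp_elisa_repeat
  time_per_sample: '4.245'
  adjusted_time_per_sample: '4.245'
  materials_cost_per_sample: '0.3'
  labour_cost_per_sample: '0.12'
- assay_id: bloodmeal_elisa
  time_per_sample: '3.9'
  adjusted_time_per_sample: '1.234'
  materials_cost_per_sample: '1.21'
  labour_cost_per_sample: '0.06'
- assay_id: parity_dissection
  time_per_sample: '0'
  adjusted_time_per_sample: '0'
  materials_cost_per_sample: '0.012'
  labour_cost_per_sample: '0.104'
workflows:
  current:
    assays:
    - pcr_species
    - csp_elisa
    branches:
    - label: species_unsatisfactory
      probability: 0.1
      node:
        assays:
        - sanger_sequencing
        branches:
        - label: csp_positive
          probability: 0.05
          node:
            assays:
            - csp_elisa_repeat
            branches:
            - label: blood_fed
              probability: 0.2
              node:
                assays:
                - bloodmeal_elisa
                branches:
                - label: bm_detected
                  probability: 0.9
                  node: []
                - label: bm_undetected
                  probability: 0.1
                  node: []
            - label: unfed
              probability: 0.8
              node: []
        - label: csp_negative
          probability: 0.95
          node:
            branches:
            - label: blood_fed
              probability: 0.2
              node:
                assays:
                - bloodmeal_elisa
                branches:
                - label: bm_detected
                  probability: 0.9
                  node: []
                - label: bm_undetected
                  probability: 0.1
                  node: []
            - label: unfed
              probability: 0.8
              node: []
    - label: species_satisfactory
      probability: 0.9
      node:
        branches:
        - label: csp_positive
          probability: 0.05
          node:
            assays:
            - csp_elisa_repeat
            branches:
            - label: blood_fed
              probability: 0.2
              node:
                assays:
                - bloodmeal_elisa
                branches:
                - label: bm_detected
                  probability: 0.9
                  node: []
                - label: bm_undetected
                  probability: 0.1
                  node: []
            - label: unfed
              probability: 0.8
              node: []
        - label: csp_negative
          probability: 0.95
          node:
            branches:
            - label: blood_fed
              probability: 0.2
              node:
                assays:
                - bloodmeal_elisa
                branches:
                - label: bm_detected
                  probability: 0.9
                  node: []
                - label: bm_undetected
                  probability: 0.1
                  node: []
            - label: unfed
              probability: 0.8
              node: []
  proposed:
    assays:
    - maldi_head_thorax
    branches:
    - label: maldi_unsatisfactory
      probability: 0.1
      node:
        assays:
        - sanger_sequencing
        - csp_elisa
        branches:
        - label: csp_positive
          probability: 0.05
          node:
            assays:
            - id: csp_elisa_repeat
              dims:
              - materials
              - labour
            branches:
            - label: blood_fed
              probability: 0.2
              node:
                assays:
                - maldi_bloodmeal
                branches:
                - label: bm_satisfactory
                  probability: 0.9
                  node: []
                - label: bm_unsatisfactory
                  probability: 0.1
                  node:
                    assays:
                    - bloodmeal_elisa
            - label: unfed
              probability: 0.8
              node: []
        - label: csp_negative
          probability: 0.95
          node:
            branches:
            - label: blood_fed
              probability: 0.2
              node:
                assays:
                - maldi_bloodmeal
                branches:
                - label: bm_satisfactory
                  probability: 0.9
                  node: []
                - label: bm_unsatisfactory
                  probability: 0.1
                  node:
                    assays:
                    - bloodmeal_elisa
            - label: unfed
              probability: 0.8
              node: []
    - label: maldi_satisfactory
      probability: 0.9
      node:
        branches:
        - label: blood_fed
          probability: 0.2
          node:
            assays:
            - maldi_bloodmeal
            branches:
            - label: bm_satisfactory
              probability: 0.9
              node: []
            - label: bm_unsatisfactory
              probability: 0.1
              node:
                assays:
                - bloodmeal_elisa
        - label: unfed
          probability: 0.8
          node: []
  ideal:
    assays:
    - maldi_head_thorax
    branches:
    - label: blood_fed
      probability: 0.2
      node:
        assays:
        - maldi_bloodmeal
    - label: unfed
      probability: 0.8
      node: []
labour_rate:
  annual_salary: '6289.82'
  hours_per_week: 40.0
  weeks_per_year: 52.0
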