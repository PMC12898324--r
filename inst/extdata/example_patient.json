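{
  "provenance": "single-patient example (synthetic)",
  "patients": [
    {
      "patient_id": "pt-001",
      "age_at_index": 71.2,
      "sex": "male",
      "surgically_fit": true,
      "limited_life_expectancy": false,
      "comorbidities": [
        "diabetes_or_ifg",
        "cholelithiasis_ccy"
      ],
      "outcome_pdac": false,
      "outcome_pdac_date": null,
      "clinical_followup_months": 60,
      "radiological_followup_months": 48,
      "observations": [
        {
          "observation_date": "2016-03-10",
          "leading_cyst_size": 9,
          "n_cysts": 1,
          "mpd_diameter": 2.4,
          "wall_thickened": false,
          "abrupt_duct_change": false,
          "lymphadenopathy": false,
          "obstructive_jaundice": false,
          "ca19_9": 14,
          "acute_pancreatitis_episode": false,
          "new_onset_diabetes": false,
          "modality": "mri_mrcp"
        },
        {
          "observation_date": "2016-09-12",
          "leading_cyst_size": 9.5,
          "n_cysts": 1,
          "mpd_diameter": 2.5,
          "wall_thickened": false,
          "abrupt_duct_change": false,
          "lymphadenopathy": false,
          "obstructive_jaundice": false,
          "ca19_9": 15,
          "acute_pancreatitis_episode": false,
          "new_onset_diabetes": false,
          "modality": "mri_mrcp"
        },
        {
          "observation_date": "2018-03-20",
          "leading_cyst_size": 10,
          "n_cysts": 1,
          "mpd_diameter": 2.5,
          "wall_thickened": false,
          "abrupt_duct_change": false,
          "lymphadenopathy": false,
          "obstructive_jaundice": false,
          "acute_pancreatitis_episode": false,
          "new_onset_diabetes": false,
          "modality": "mri_mrcp"
        }
      ],
      "management_events": [
        {
          "event_date": "2016-09-12",
          "event_type": "imaging_mri_mrcp"
        },
        {
          "event_date": "2018-03-20",
          "event_type": "imaging_mri_mrcp"
        }
      ]
    }
  ]
}
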