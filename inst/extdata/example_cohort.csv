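"patient_id","record_kind","date","age_at_index","sex","surgically_fit","limited_life_expectancy","comorbidities","outcome_pdac","outcome_pdac_date","clinical_followup_months","radiological_followup_months","leading_cyst_size","n_cysts","mpd_diameter","mural_nodule_size","mural_nodule_enhancing","wall_thickened","abrupt_duct_change","lymphadenopathy","obstructive_jaundice","ca19_9","acute_pancreatitis_episode","new_onset_diabetes","modality","event_type"
"pt-001","patient","","71.2","male","true","false","diabetes_or_ifg;cholelithiasis_ccy","false","","60","48","","","","","","","","","","","","","",""
"pt-001","observation","2016-03-10","","","","","","","","","","9","1","2.4","","","false","false","false","false","14","false","false","mri_mrcp",""
"pt-001","observation","2016-09-12","","","","","","","","","","9.5","1","2.5","","","false","false","false","false","15","false","false","mri_mrcp",""
"pt-001","observation","2018-03-20","","","","","","","","","","10","1","2.5","","","false","false","false","false","","false","false","mri_mrcp",""
"pt-001","event","2016-09-12","","","","","","","","","","","","","","","","","","","","","","","imaging_mri_mrcp"
"pt-001","event","2018-03-20","","","","","","","","","","","","","","","","","","","","","","","imaging_mri_mrcp"
"pt-002","patient","","66","female","true","false","smoker","false","","24","18","","","","","","","","","","","","","",""
"pt-002","observation","2019-05-02","","","","","","","","","","31","1","6.1","","","true","false","false","false","55","false","false","mri_mrcp",""
"pt-002","observation","2019-11-04","","","","","","","","","","32","1","6.3","","","true","false","false","false","60","false","false","eus",""
"pt-002","event","2019-11-04","","","","","","","","","","","","","","","","","","","","","","","imaging_eus"
"pt-003","patient","","58.9","male","true","false","","false","","30","2","","","","","","","","","","","","","",""
"pt-003","observation","2020-01-15","","","","","","","","","","22","1","11","6","true","false","false","false","false","","false","false","mri_mrcp",""
"pt-003","event","2020-02-10","","","","","","","","","","","","","","","","","","","","","","","surgery_referral"
"pt-003","event","2020-04-01","","","","","","","","","","","","","","","","","","","","","","","surgery_performed"
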