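# Default decision policy for SB-IPMN surveillance under the Kyoto framework.
# Thresholds follow the published feature definitions; interval values encode
# the guideline surveillance schedule and are data, not code: edit this file
# to correct or localize the schedule without touching the engine.
version: kyoto-default-1
thresholds:
  # high-risk stigmata
  mpd_hrs_mm: 10          # main pancreatic duct >= 10 mm
  nodule_hrs_mm: 5        # enhancing mural nodule >= 5 mm
  # worrisome features
  cyst_wf_mm: 30          # cyst >= 30 mm
  mpd_wf_low_mm: 5        # main duct 5-9 mm (closed band, upper edge = mpd_hrs_mm)
  ca19_9_u_ml: 37         # serum CA 19-9 above assay upper limit of normal
  growth_wf_mm_per_2y: 5  # rapid growth: strictly > 5 mm per 2 years
wf_toggles:
  # Kyoto-specific additions to the worrisome-feature set; switchable because
  # guideline editions differ on their inclusion.
  acute_pancreatitis: true
  new_onset_diabetes: true
size_bands:
  # no-WF/no-HRS cysts, partitioned by leading cyst size in mm:
  # [lower, upper) band -> first surveillance visit at interval_months, then
  # every stable_interval_months once the lesion has demonstrated stability.
  - lower_mm: 0
    upper_mm: 20
    modality: mri_mrcp
    interval_months: 6
    stable_interval_months: 18
  - lower_mm: 20
    upper_mm: 30
    modality: mri_mrcp
    interval_months: 6
    stable_interval_months: 12
wf_rules:
  # applied when wf_count >= min_count (highest matching tier wins);
  # a single tier means no per-count escalation.
  - min_count: 1
    modality: eus
    interval_months: 6
hrs_rule:
  action: surgery_referral
unfit_rule:
  # high-risk stigmata present but patient not a surgical candidate
  modality: eus
  interval_months: 6
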