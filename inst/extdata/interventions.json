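[
  {
    "id": "post_attempt_aftercare",
    "kind": "program",
    "label": "Post-attempt assertive aftercare",
    "targets": [
      {"path": "attempt_hazard_post", "transform": "multiply", "value": 0.80}
    ],
    "capacity_cost": {"service": "cmhc", "services_per_person_week": 0.10},
    "note": "Active outreach and enhanced contact after a suicide attempt; re-attempt hazard ratio ~0.8 anchored to brief-contact/aftercare trial meta-analyses. Delivered through existing CMHC teams, so each enrolled post-attempt client consumes CMHC capacity."
  },
  {
    "id": "gp_training",
    "kind": "program",
    "label": "GP training in suicide risk",
    "targets": [
      {"path": "frac_gp_specialist", "transform": "multiply", "value": 1.25}
    ],
    "capacity_cost": null,
    "note": "Short training programs increase referral of suicidal patients from general practice to specialised psychiatric services."
  },
  {
    "id": "community_education",
    "kind": "program",
    "label": "Community-based education programs",
    "targets": [
      {"path": "education_help_seeking_effect", "transform": "add", "value": 0.15}
    ],
    "capacity_cost": null,
    "note": "Gatekeeper-style education raises help seeking; realised effect scales with the community-support factor, which grows with active social-connectedness programs."
  },
  {
    "id": "family_psychoeducation",
    "kind": "program",
    "label": "Family education and support",
    "targets": [
      {"path": "frac_gp_recover", "transform": "multiply", "value": 1.05},
      {"path": "frac_specialist_success", "transform": "multiply", "value": 1.10},
      {"path": "frac_cmhc_success", "transform": "multiply", "value": 1.10},
      {"path": "frac_online_success", "transform": "multiply", "value": 1.10},
      {"path": "attempt_hazard_in_care", "transform": "multiply", "value": 0.85}
    ],
    "capacity_cost": null,
    "note": "Family/carer involvement improves in-care treatment success and lowers the in-care attempt hazard; placeholder effect sizes anchored to psychoeducation trial literature."
  },
  {
    "id": "safety_planning",
    "kind": "program",
    "label": "Safety planning",
    "targets": [
      {"path": "attempt_hazard_post", "transform": "multiply", "value": 0.80}
    ],
    "capacity_cost": null,
    "note": "Safety-planning-type intervention with structured follow-up for suicidal patients presenting to EDs; reduces the re-attempt hazard of the post-attempt group (hazard ratio ~0.8, ED-based safety planning studies)."
  },
  {
    "id": "safe_space",
    "kind": "program",
    "label": "Safe space alternative to ED",
    "targets": [
      {"path": "safe_space_divert", "transform": "add", "value": 0.15}
    ],
    "capacity_cost": null,
    "note": "Safe-haven-cafe-style alternative contact point; diverts a fraction of crisis ED presentations before they are counted, without a care-pathway transition."
  },
  {
    "id": "social_connectedness",
    "kind": "program",
    "label": "Social connectedness programs",
    "targets": [
      {"path": "distress_onset_rate", "transform": "multiply", "value": 0.95},
      {"path": "recovery_untreated", "transform": "multiply", "value": 1.10},
      {"path": "connectedness_coverage", "transform": "set", "value": 1.0}
    ],
    "capacity_cost": null,
    "note": "Community support programs reduce distress onset and improve untreated recovery; full coverage also raises the community-support factor that amplifies community education."
  },
  {
    "id": "acute_care_services",
    "kind": "program",
    "label": "Community-based acute care services",
    "targets": [
      {"path": "acute_care_divert", "transform": "add", "value": 0.15}
    ],
    "capacity_cost": null,
    "note": "Responsive community crisis teams divert a fraction of crisis ED presentations into CMHC-style care (a real transition into treatment), capacity permitting."
  },
  {
    "id": "cap_gp",
    "kind": "capacity_lever",
    "label": "GP mental health services capacity",
    "targets": [
      {"path": "capm_gp", "transform": "set", "value": 2.0}
    ],
    "capacity_cost": null,
    "note": "Multiplies the annual growth rate of weekly GP mental-health consultation capacity (default multiplier 1 = business as usual; lever doubles it)."
  },
  {
    "id": "cap_specialist",
    "kind": "capacity_lever",
    "label": "Psychiatrist and allied services capacity",
    "targets": [
      {"path": "capm_specialist", "transform": "set", "value": 2.0}
    ],
    "capacity_cost": null,
    "note": "Multiplies the annual growth rate of weekly psychiatrist/allied service capacity."
  },
  {
    "id": "cap_inpatient",
    "kind": "capacity_lever",
    "label": "Psychiatric hospital care capacity",
    "targets": [
      {"path": "capm_inpatient", "transform": "set", "value": 2.0}
    ],
    "capacity_cost": null,
    "note": "Multiplies the annual growth rate of the maximum weekly psychiatric admissions."
  },
  {
    "id": "cap_cmhc",
    "kind": "capacity_lever",
    "label": "Community mental healthcare capacity",
    "targets": [
      {"path": "cmhc_increment_per10k", "transform": "set", "value": 0.15}
    ],
    "capacity_cost": null,
    "note": "Annual additive increase in CMHC contacts per 10,000 population per week (default 0 = no capacity growth)."
  }
]
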