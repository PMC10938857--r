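# Shared vocabulary: category levels and component names used across modules.
# (Defined in this file so it is sourced before the modules that use them.)

TRANSFER_COLUMNS <- c(
  "unemployment_benefits", "social_assistance", "state_educational_grants",
  "housing_benefits", "child_youth_benefits", "old_age_pension",
  "disability_pension", "flexi_job", "early_retirement"
)

CONTACT_TYPES <- c("inpatient", "outpatient", "emergency")

PRIMARY_CARE_PROVIDERS <- c(
  "general practitioner", "specialist", "psychologist", "dentist",
  "physiotherapist", "chiropodist", "chiropractor"
)

DRG_CATEGORIES <- c("psych_drg", "somatic_drg")

HEALTHCARE_COMPONENTS <- c(
  "psych_cost", "somatic_cost", "rx_subsidised_cost",
  "rx_out_of_pocket_cost", "primary_care_cost", "combined_healthcare_cost"
)

COST_COMPONENTS <- c(
  HEALTHCARE_COMPONENTS, "personal_income", "transfers_total", TRANSFER_COLUMNS
)

MEASURES <- c("nationwide_annual", "per_case_annual", "per_capita_annual")
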