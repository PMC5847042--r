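column,type,units,allowed,description
patient_id,character,,,unique patient identifier
er_hscore,integer,H-score,0-300,ER staining H-score (intensity-weighted percent); IHC4 uses er_hscore/30
er_percent,numeric,percent,0-100,ER percent positive stained cells (optional; used for ER-positivity eligibility)
er_allred,numeric,Allred,0-8,ER Allred score (optional; used for ER-positivity eligibility)
pgr_percent,numeric,percent,0-100,PgR percent positive tumour nuclei; IHC4 uses pgr_percent/10
her2_ihc,character,category,0|1+|2+|3+,HER2 IHC category; only 3+ counts as positive (no ISH reflex)
ki67_percent,numeric,percent,0-100,Ki67 percent positive; IHC4 uses ln(1+4*ki67_percent)
age_years,numeric,years,>0,age at randomisation; clinical score dichotomises at >=65
nodal_category,character,category,N0|N1to3|Ngt3,number of positive nodes: none / 1-3 / more than 3
tumour_size_cm,numeric,cm,>0,pathological tumour size; categorised <1 / 1-2 / >2-3 / >3
grade,character,category,G1|G2|G3|not_assessable|unknown,histological grade; only G1-G3 scoreable
treatment,character,category,tamoxifen_only|switch_to_exemestane,randomised arm after 2-3 years of tamoxifen
time_months,numeric,months,>=0,follow-up time from randomisation
event_type,character,category,none|distant_recurrence|local_or_regional_recurrence|contralateral|death_breast_cancer|death_unknown_cause|death_other_cause,first recorded outcome terminating follow-up; empty fields encode missing values throughout
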