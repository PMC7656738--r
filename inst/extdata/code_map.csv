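code,condition,charlson_category,weight
DX_MM,,malignancy,2
DX_PRIOR_MAL,,malignancy,2
DX_ARRHYTHMIA,cardiac_arrhythmia,,
DX_CHF,congestive_heart_failure,congestive_heart_failure,1
DX_HTN_COMP,hypertension_complicated,,
DX_HTN_SIMPLE,hypertension_simple,,
DX_HEPATIC,hepatic_disease,mild_liver_disease,1
DX_PULM_CIRC,pulmonary_circulation_disorders,,
DX_RENAL,renal_impairment,renal_disease,2
DX_VALVULAR,valvular_disease,,
DX_MI,,myocardial_infarction,1
DX_PVD,,peripheral_vascular_disease,1
DX_CVD,,cerebrovascular_disease,1
DX_DEMENTIA,,dementia,1
DX_COPD,,chronic_pulmonary_disease,1
DX_RHEUM,,rheumatic_disease,1
DX_PUD,,peptic_ulcer_disease,1
DX_DIABETES,,diabetes,1
DX_DIABETES_COMP,,diabetes_with_complications,2
DX_HEMIPLEGIA,,hemiplegia,2
DX_LIVER_SEVERE,,moderate_severe_liver_disease,3
DX_METASTATIC,,metastatic_solid_tumor,6
DX_AIDS,,aids,6
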