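patient_id,indicator,year,eligible,reason,category
G01,visits_onc_or_pcp,2,TRUE,,adherent
G01,visits_onc_only,2,TRUE,,under
G01,visits_breast_reason,2,TRUE,,under
G01,surveillance_breast_imaging,2,TRUE,,adherent
G01,metastatic_imaging,2,TRUE,,adherent
G01,visits_onc_or_pcp,3,TRUE,,adherent
G01,visits_onc_only,3,TRUE,,under
G01,visits_breast_reason,3,TRUE,,under
G01,surveillance_breast_imaging,3,TRUE,,adherent
G01,metastatic_imaging,3,TRUE,,adherent
G01,visits_onc_or_pcp,4,TRUE,,adherent
G01,visits_onc_only,4,TRUE,,under
G01,visits_breast_reason,4,TRUE,,under
G01,surveillance_breast_imaging,4,TRUE,,adherent
G01,metastatic_imaging,4,TRUE,,adherent
G01,visits_onc_or_pcp,5,TRUE,,adherent
G01,visits_onc_only,5,TRUE,,under
G01,visits_breast_reason,5,TRUE,,under
G01,surveillance_breast_imaging,5,TRUE,,adherent
G01,metastatic_imaging,5,TRUE,,adherent
G01,chronic_CSA,all,FALSE,no_condition_or_no_complete_block,
G01,chronic_CHF,all,FALSE,no_condition_or_no_complete_block,
G01,chronic_COPD,all,FALSE,no_condition_or_no_complete_block,
G01,chronic_TIA,all,FALSE,no_condition_or_no_complete_block,
G01,chronic_DM,all,FALSE,no_condition_or_no_complete_block,
G01,prev_cervical,all,TRUE,,not_adherent
G01,prev_bone_density,all,FALSE,age_or_history,
G01,prev_colorectal,all,TRUE,,adherent
G04,visits_onc_or_pcp,2,TRUE,,over
G04,visits_onc_only,2,TRUE,,under
G04,visits_breast_reason,2,TRUE,,under
G04,surveillance_breast_imaging,2,TRUE,,under
G04,metastatic_imaging,2,TRUE,,adherent
G04,visits_onc_or_pcp,3,TRUE,,under
G04,visits_onc_only,3,TRUE,,under
G04,visits_breast_reason,3,TRUE,,under
G04,surveillance_breast_imaging,3,TRUE,,under
G04,metastatic_imaging,3,TRUE,,not_adherent
G04,visits_onc_or_pcp,4,FALSE,partial_year,
G04,visits_onc_only,4,FALSE,partial_year,
G04,visits_breast_reason,4,FALSE,partial_year,
G04,surveillance_breast_imaging,4,FALSE,partial_year,
G04,metastatic_imaging,4,FALSE,partial_year,
G04,visits_onc_or_pcp,5,FALSE,partial_year,
G04,visits_onc_only,5,FALSE,partial_year,
G04,visits_breast_reason,5,FALSE,partial_year,
G04,surveillance_breast_imaging,5,FALSE,partial_year,
G04,metastatic_imaging,5,FALSE,partial_year,
G04,chronic_CSA,all,FALSE,no_condition_or_no_complete_block,
G04,chronic_CHF,all,FALSE,no_condition_or_no_complete_block,
G04,chronic_COPD,all,FALSE,no_condition_or_no_complete_block,
G04,chronic_TIA,all,TRUE,,adherent
G04,chronic_DM,all,FALSE,no_condition_or_no_complete_block,
G04,prev_cervical,all,FALSE,age_or_history,
G04,prev_bone_density,all,TRUE,,adherent
G04,prev_colorectal,all,FALSE,age_or_history,
G05,visits_onc_or_pcp,2,TRUE,,adherent
G05,visits_onc_only,2,TRUE,,under
G05,visits_breast_reason,2,TRUE,,under
G05,surveillance_breast_imaging,2,TRUE,,adherent
G05,metastatic_imaging,2,TRUE,,not_adherent
G05,visits_onc_or_pcp,3,TRUE,,adherent
G05,visits_onc_only,3,TRUE,,under
G05,visits_breast_reason,3,TRUE,,under
G05,surveillance_breast_imaging,3,TRUE,,adherent
G05,metastatic_imaging,3,TRUE,,adherent
G05,visits_onc_or_pcp,4,FALSE,partial_year,
G05,visits_onc_only,4,FALSE,partial_year,
G05,visits_breast_reason,4,FALSE,partial_year,
G05,surveillance_breast_imaging,4,FALSE,partial_year,
G05,metastatic_imaging,4,FALSE,partial_year,
G05,visits_onc_or_pcp,5,FALSE,partial_year,
G05,visits_onc_only,5,FALSE,partial_year,
G05,visits_breast_reason,5,FALSE,partial_year,
G05,surveillance_breast_imaging,5,FALSE,partial_year,
G05,metastatic_imaging,5,FALSE,partial_year,
G05,chronic_CSA,all,FALSE,no_condition_or_no_complete_block,
G05,chronic_CHF,all,TRUE,,not_adherent
G05,chronic_COPD,all,FALSE,no_condition_or_no_complete_block,
G05,chronic_TIA,all,FALSE,no_condition_or_no_complete_block,
G05,chronic_DM,all,FALSE,no_condition_or_no_complete_block,
G05,prev_cervical,all,TRUE,,adherent
G05,prev_bone_density,all,FALSE,age_or_history,
G05,prev_colorectal,all,FALSE,age_or_history,
G06,visits_onc_or_pcp,2,TRUE,,under
G06,visits_onc_only,2,TRUE,,under
G06,visits_breast_reason,2,TRUE,,under
G06,surveillance_breast_imaging,2,FALSE,bilateral_mastectomy,
G06,metastatic_imaging,2,TRUE,,adherent
G06,visits_onc_or_pcp,3,TRUE,,under
G06,visits_onc_only,3,TRUE,,under
G06,visits_breast_reason,3,TRUE,,under
G06,surveillance_breast_imaging,3,FALSE,bilateral_mastectomy,
G06,metastatic_imaging,3,TRUE,,adherent
G06,visits_onc_or_pcp,4,TRUE,,under
G06,visits_onc_only,4,TRUE,,under
G06,visits_breast_reason,4,TRUE,,under
G06,surveillance_breast_imaging,4,FALSE,bilateral_mastectomy,
G06,metastatic_imaging,4,TRUE,,adherent
G06,visits_onc_or_pcp,5,TRUE,,under
G06,visits_onc_only,5,TRUE,,under
G06,visits_breast_reason,5,TRUE,,under
G06,surveillance_breast_imaging,5,FALSE,bilateral_mastectomy,
G06,metastatic_imaging,5,TRUE,,adherent
G06,chronic_CSA,all,FALSE,no_condition_or_no_complete_block,
G06,chronic_CHF,all,FALSE,no_condition_or_no_complete_block,
G06,chronic_COPD,all,TRUE,,adherent
G06,chronic_TIA,all,FALSE,no_condition_or_no_complete_block,
G06,chronic_DM,all,FALSE,no_condition_or_no_complete_block,
G06,prev_cervical,all,TRUE,,not_adherent
G06,prev_bone_density,all,FALSE,age_or_history,
G06,prev_colorectal,all,FALSE,age_or_history,
G07,visits_onc_or_pcp,2,TRUE,,adherent
G07,visits_onc_only,2,TRUE,,under
G07,visits_breast_reason,2,TRUE,,under
G07,surveillance_breast_imaging,2,TRUE,,under
G07,metastatic_imaging,2,TRUE,,adherent
G07,visits_onc_or_pcp,3,TRUE,,adherent
G07,visits_onc_only,3,TRUE,,under
G07,visits_breast_reason,3,TRUE,,under
G07,surveillance_breast_imaging,3,TRUE,,under
G07,metastatic_imaging,3,TRUE,,adherent
G07,visits_onc_or_pcp,4,TRUE,,adherent
G07,visits_onc_only,4,TRUE,,under
G07,visits_breast_reason,4,TRUE,,under
G07,surveillance_breast_imaging,4,TRUE,,under
G07,metastatic_imaging,4,TRUE,,not_adherent
G07,visits_onc_or_pcp,5,TRUE,,over
G07,visits_onc_only,5,TRUE,,under
G07,visits_breast_reason,5,TRUE,,under
G07,surveillance_breast_imaging,5,TRUE,,under
G07,metastatic_imaging,5,TRUE,,adherent
G07,chronic_CSA,all,FALSE,no_condition_or_no_complete_block,
G07,chronic_CHF,all,FALSE,no_condition_or_no_complete_block,
G07,chronic_COPD,all,FALSE,no_condition_or_no_complete_block,
G07,chronic_TIA,all,FALSE,no_condition_or_no_complete_block,
G07,chronic_DM,all,TRUE,,not_adherent
G07,prev_cervical,all,FALSE,age_or_history,
G07,prev_bone_density,all,FALSE,age_or_history,
G07,prev_colorectal,all,TRUE,,adherent
G10,visits_onc_or_pcp,2,TRUE,,over
G10,visits_onc_only,2,TRUE,,under
G10,visits_breast_reason,2,TRUE,,under
G10,surveillance_breast_imaging,2,TRUE,,over
G10,metastatic_imaging,2,TRUE,,adherent
G10,visits_onc_or_pcp,3,TRUE,,adherent
G10,visits_onc_only,3,TRUE,,under
G10,visits_breast_reason,3,TRUE,,under
G10,surveillance_breast_imaging,3,TRUE,,under
G10,metastatic_imaging,3,TRUE,,adherent
G10,visits_onc_or_pcp,4,TRUE,,adherent
G10,visits_onc_only,4,TRUE,,under
G10,visits_breast_reason,4,TRUE,,under
G10,surveillance_breast_imaging,4,TRUE,,under
G10,metastatic_imaging,4,TRUE,,adherent
G10,visits_onc_or_pcp,5,TRUE,,over
G10,visits_onc_only,5,TRUE,,under
G10,visits_breast_reason,5,TRUE,,under
G10,surveillance_breast_imaging,5,TRUE,,under
G10,metastatic_imaging,5,TRUE,,adherent
G10,chronic_CSA,all,TRUE,,adherent
G10,chronic_CHF,all,FALSE,no_condition_or_no_complete_block,
G10,chronic_COPD,all,FALSE,no_condition_or_no_complete_block,
G10,chronic_TIA,all,FALSE,no_condition_or_no_complete_block,
G10,chronic_DM,all,FALSE,no_condition_or_no_complete_block,
G10,prev_cervical,all,FALSE,age_or_history,
G10,prev_bone_density,all,TRUE,,not_adherent
G10,prev_colorectal,all,FALSE,age_or_history,
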