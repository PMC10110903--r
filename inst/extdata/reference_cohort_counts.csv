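section,category,count,total,percent
sex,male,51,108,47.2
sex,female,57,108,52.8
survival,alive,50,108,46.3
survival,dead,58,108,53.7
cause_of_death,alive,50,108,46.3
cause_of_death,cancer_related,40,108,37.0
cause_of_death,not_cancer_related,11,108,10.2
cause_of_death,unknown,7,108,6.5
local_progression_free_survival,survived_without_progression,36,108,33.3
local_progression_free_survival,progression_or_death,72,108,66.7
two_year_overall_survival,survived,50,108,46.3
two_year_overall_survival,died,42,108,38.9
two_year_overall_survival,insufficient_followup,16,108,14.8
two_year_disease_specific_survival,survived,57,108,52.8
two_year_disease_specific_survival,died,35,108,32.4
two_year_disease_specific_survival,insufficient_followup,16,108,14.8
two_year_local_progression_free_survival,survived,28,108,25.9
two_year_local_progression_free_survival,died_or_progressed,64,108,59.3
two_year_local_progression_free_survival,insufficient_followup,16,108,14.8
prior_treatment,previous_radiation_therapy,33,108,30.6
prior_treatment,previous_surgery,31,108,28.7
prior_treatment,previous_chemotherapy,41,108,38.0
prior_treatment,previous_immunotherapy,2,108,1.9
stage,IA,51,108,47.2
stage,IB,16,108,14.8
stage,IIA,3,108,2.8
stage,IIB,3,108,2.8
stage,IIIA,5,108,4.6
stage,IIIB,16,108,14.8
stage,IV,14,108,13.0
karnofsky_performance_score,100,5,108,4.6
karnofsky_performance_score,90,25,108,23.1
karnofsky_performance_score,80,40,108,37.0
karnofsky_performance_score,70,30,108,27.8
karnofsky_performance_score,60,6,108,5.6
karnofsky_performance_score,below_60,2,108,1.9
histology,adenocarcinoma,55,108,50.9
histology,squamous_cell_carcinoma,41,108,38.0
histology,adenosquamous,2,108,1.9
histology,metastasis_from_prior_nsclc,1,108,0.9
histology,clinical_diagnosis,9,108,8.3
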