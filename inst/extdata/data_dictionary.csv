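column,type,lower,upper,required
subject_id,id,,,TRUE
sex,categorical,,,FALSE
education_years,numeric,0,30,FALSE
age_of_onset,numeric,18,110,FALSE
disease_duration,numeric,0,40,FALSE
bmi,numeric,10,70,FALSE
stroke,binary,0,1,FALSE
head_injury,binary,0,1,FALSE
depression,binary,0,1,FALSE
anxiety,binary,0,1,FALSE
diabetes,binary,0,1,FALSE
smoking,binary,0,1,FALSE
epilepsy,binary,0,1,FALSE
encephalitis,binary,0,1,FALSE
family_history,binary,0,1,FALSE
fainting,binary,0,1,FALSE
vocalization,binary,0,1,FALSE
moca_baseline,integer,0,30,FALSE
moca_y2,integer,0,30,FALSE
moca_y4,integer,0,30,FALSE
moca_total,integer,0,30,FALSE
moca_z,numeric,-10,10,FALSE
upsit_total,integer,0,40,FALSE
scopa_total,integer,0,69,FALSE
stai1_total,integer,20,80,FALSE
stai2_total,integer,20,80,FALSE
rbdsq_total,integer,0,13,FALSE
rigidity_right,numeric,0,8,FALSE
rigidity_left,numeric,0,8,FALSE
rigidity_unilateral,numeric,0,8,FALSE
akinesia_right,numeric,0,20,FALSE
akinesia_left,numeric,0,20,FALSE
akinesia_unilateral,numeric,0,20,FALSE
tremor_right,numeric,0,16,FALSE
tremor_left,numeric,0,16,FALSE
tremor_unilateral,numeric,0,16,FALSE
pigd_score,numeric,0,4,FALSE
tremor_score,numeric,0,4,FALSE
phenotype,categorical,,,FALSE
decline,binary,0,1,FALSE
trajectory,categorical,,,FALSE
moca_visuospatial_executive,integer,0,5,FALSE
moca_naming,integer,0,3,FALSE
moca_attention,integer,0,6,FALSE
moca_language,integer,0,3,FALSE
moca_abstraction,integer,0,2,FALSE
moca_delayed_recall,integer,0,5,FALSE
moca_orientation,integer,0,6,FALSE
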