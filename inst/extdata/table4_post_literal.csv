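subject_id,session,test_name,z_score
subj1,post,corsi_visual,-0.71
subj1,post,corsi_simultaneous,10.72
subj1,post,corsi_sequential,-1.18
subj1,post,bhk_quality,0.54
subj1,post,bhk_velocity,-1.16
subj1,post,tcm_velocity,-0.97
subj1,post,tcm_accuracy,-1.66
subj1,post,rocf_copy,1.15
subj1,post,rocf_memory,-0.3
subj1,post,dem_ratio,0.47
subj2,post,corsi_visual,0.69
subj2,post,corsi_simultaneous,1.19
subj2,post,corsi_sequential,0.05
subj2,post,bhk_quality,0.61
subj2,post,bhk_velocity,-1.71
subj2,post,tcm_velocity,-0.7
subj2,post,tcm_accuracy,-0.27
subj2,post,rocf_copy,1.26
subj2,post,rocf_memory,0.57
subj2,post,dem_ratio,-3.05
subj3,post,bhk_quality,0.05
subj3,post,bhk_velocity,-0.48
subj3,post,tcm_velocity,1.8
subj3,post,tcm_accuracy,-0.78
subj3,post,rocf_copy,-1.58
subj3,post,rocf_memory,-1.29
subj3,post,dem_ratio,-1.15
subj4,post,corsi_visual,0.18
subj4,post,corsi_simultaneous,-1.43
subj4,post,corsi_sequential,-0.66
subj4,post,bhk_quality,-1.59
subj4,post,bhk_velocity,-0.06
subj4,post,tcm_velocity,0.5
subj4,post,tcm_accuracy,-0.15
subj4,post,rocf_copy,-1.51
subj4,post,rocf_memory,-2.14
subj4,post,dem_ratio,-0.39
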