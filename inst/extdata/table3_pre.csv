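subject_id,session,test_name,z_score
subj1,pre,corsi_visual,-1.75
subj1,pre,corsi_simultaneous,-2.28
subj1,pre,corsi_sequential,-0.19
subj1,pre,bhk_quality,-0.11
subj1,pre,bhk_velocity,-0.02
subj1,pre,tcm_velocity,-2.4
subj1,pre,tcm_accuracy,-3.5
subj1,pre,rocf_copy,-3.5
subj1,pre,rocf_memory,-3.8
subj1,pre,dem_ratio,0.06
subj2,pre,corsi_visual,0.36
subj2,pre,corsi_simultaneous,-0.37
subj2,pre,corsi_sequential,1.48
subj2,pre,bhk_quality,0.3
subj2,pre,bhk_velocity,-0.6
subj2,pre,tcm_velocity,-1.4
subj2,pre,tcm_accuracy,-3.6
subj2,pre,rocf_copy,-1.2
subj2,pre,rocf_memory,-2
subj2,pre,dem_ratio,-2.1
subj3,pre,bhk_quality,0.21
subj3,pre,bhk_velocity,-1.48
subj3,pre,tcm_velocity,-0.44
subj3,pre,tcm_accuracy,-3.28
subj3,pre,rocf_copy,-0.05
subj3,pre,rocf_memory,-2.31
subj3,pre,dem_ratio,-0.78
subj4,pre,corsi_visual,0.69
subj4,pre,corsi_simultaneous,1.21
subj4,pre,corsi_sequential,-1.75
subj4,pre,bhk_quality,-1.4
subj4,pre,bhk_velocity,-1.22
subj4,pre,tcm_velocity,-1.05
subj4,pre,tcm_accuracy,-2.6
subj4,pre,rocf_copy,-0.65
subj4,pre,rocf_memory,-1.05
subj4,pre,dem_ratio,-0.81
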