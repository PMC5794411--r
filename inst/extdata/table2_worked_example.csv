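subject_id,session,test_name,z_score
example,baseline,corsi_visual,-3
example,baseline,corsi_simultaneous,-2
example,baseline,corsi_sequential,-1.5
example,baseline,bhk_quality,-0.5
example,baseline,bhk_velocity,-0.5
example,baseline,tcm_velocity,-1.5
example,baseline,tcm_accuracy,-2
example,baseline,rocf_copy,-1.5
example,baseline,rocf_memory,-2
example,baseline,dem_ratio,-2
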