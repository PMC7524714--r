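{"ASIS_L":[115,70,0],"ASIS_R":[-115,70,0],"PSIS_L":[45,-95,15],"PSIS_R":[-45,-95,15],"pubic_symphysis":[0,70,-70],"pubic_tubercle_L":[28,72,-64],"pubic_tubercle_R":[-28,72,-64],"sacral_promontory":[0,9.02173050963862,31.0397658137981],"S1_endplate_anterior":[0,7.4565141959338,32.2847950870733],"S1_endplate_posterior":[0,-14.4565141959338,49.7152049129267],"S1_endplate_center":[0,-3.5,41],"hip_center_L":[85,24.9700949612773,-65.2518408917975],"hip_center_R":[-85,24.9700949612773,-65.2518408917975],"ischial_tuberosity_L":[55,-20,-135],"ischial_tuberosity_R":[-55,-20,-135],"iliac_crest_L":[130,-25,60],"iliac_crest_R":[-130,-25,60],"L1sup_a":[0,-8.25314145536884,152.92279470475],"L1sup_p":[0,-41.7468585446312,147.07720529525],"L5sup_a":[0,0.490362246049724,60.9939199351289],"L5sup_p":[0,-30.4903622460497,69.0060800648711]}
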