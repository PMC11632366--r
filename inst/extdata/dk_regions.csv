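region_id,hemisphere,bilateral_pair_id,braak_stage,reference_candidate,composites
entorhinal_L,left,entorhinal,1,false,meta_temporal;mesial_temporal
entorhinal_R,right,entorhinal,1,false,meta_temporal;mesial_temporal
hippocampus_L,left,hippocampus,2,false,mesial_temporal
hippocampus_R,right,hippocampus,2,false,mesial_temporal
parahippocampal_L,left,parahippocampal,3,false,meta_temporal;mesial_temporal
parahippocampal_R,right,parahippocampal,3,false,meta_temporal;mesial_temporal
fusiform_L,left,fusiform,3,false,meta_temporal;temporoparietal
fusiform_R,right,fusiform,3,false,meta_temporal;temporoparietal
lingual_L,left,lingual,3,false,rest
lingual_R,right,lingual,3,false,rest
amygdala_L,left,amygdala,3,false,meta_temporal;mesial_temporal
amygdala_R,right,amygdala,3,false,meta_temporal;mesial_temporal
middle_temporal_L,left,middle_temporal,4,false,meta_temporal;temporoparietal
middle_temporal_R,right,middle_temporal,4,false,meta_temporal;temporoparietal
caudal_anterior_cingulate_L,left,caudal_anterior_cingulate,4,false,rest
caudal_anterior_cingulate_R,right,caudal_anterior_cingulate,4,false,rest
rostral_anterior_cingulate_L,left,rostral_anterior_cingulate,4,false,rest
rostral_anterior_cingulate_R,right,rostral_anterior_cingulate,4,false,rest
posterior_cingulate_L,left,posterior_cingulate,4,false,temporoparietal
posterior_cingulate_R,right,posterior_cingulate,4,false,temporoparietal
isthmus_cingulate_L,left,isthmus_cingulate,4,false,temporoparietal
isthmus_cingulate_R,right,isthmus_cingulate,4,false,temporoparietal
insula_L,left,insula,4,false,rest
insula_R,right,insula,4,false,rest
inferior_temporal_L,left,inferior_temporal,4,false,meta_temporal;temporoparietal
inferior_temporal_R,right,inferior_temporal,4,false,meta_temporal;temporoparietal
temporal_pole_L,left,temporal_pole,4,false,none
temporal_pole_R,right,temporal_pole,4,false,none
superior_frontal_L,left,superior_frontal,5,false,rest
superior_frontal_R,right,superior_frontal,5,false,rest
lateral_orbitofrontal_L,left,lateral_orbitofrontal,5,false,rest
lateral_orbitofrontal_R,right,lateral_orbitofrontal,5,false,rest
medial_orbitofrontal_L,left,medial_orbitofrontal,5,false,rest
medial_orbitofrontal_R,right,medial_orbitofrontal,5,false,rest
frontal_pole_L,left,frontal_pole,5,false,rest
frontal_pole_R,right,frontal_pole,5,false,rest
caudal_middle_frontal_L,left,caudal_middle_frontal,5,false,rest
caudal_middle_frontal_R,right,caudal_middle_frontal,5,false,rest
rostral_middle_frontal_L,left,rostral_middle_frontal,5,false,rest
rostral_middle_frontal_R,right,rostral_middle_frontal,5,false,rest
pars_opercularis_L,left,pars_opercularis,5,false,rest
pars_opercularis_R,right,pars_opercularis,5,false,rest
pars_orbitalis_L,left,pars_orbitalis,5,false,rest
pars_orbitalis_R,right,pars_orbitalis,5,false,rest
pars_triangularis_L,left,pars_triangularis,5,false,rest
pars_triangularis_R,right,pars_triangularis,5,false,rest
lateral_occipital_L,left,lateral_occipital,5,false,temporoparietal
lateral_occipital_R,right,lateral_occipital,5,false,temporoparietal
supramarginal_L,left,supramarginal,5,false,temporoparietal
supramarginal_R,right,supramarginal,5,false,temporoparietal
inferior_parietal_L,left,inferior_parietal,5,false,temporoparietal
inferior_parietal_R,right,inferior_parietal,5,false,temporoparietal
superior_temporal_L,left,superior_temporal,5,false,temporoparietal
superior_temporal_R,right,superior_temporal,5,false,temporoparietal
superior_parietal_L,left,superior_parietal,5,false,temporoparietal
superior_parietal_R,right,superior_parietal,5,false,temporoparietal
precuneus_L,left,precuneus,5,false,temporoparietal
precuneus_R,right,precuneus,5,false,temporoparietal
banks_sts_L,left,banks_sts,5,false,rest
banks_sts_R,right,banks_sts,5,false,rest
transverse_temporal_L,left,transverse_temporal,5,false,rest
transverse_temporal_R,right,transverse_temporal,5,false,rest
pericalcarine_L,left,pericalcarine,6,false,rest
pericalcarine_R,right,pericalcarine,6,false,rest
postcentral_L,left,postcentral,6,false,rest
postcentral_R,right,postcentral,6,false,rest
cuneus_L,left,cuneus,6,false,rest
cuneus_R,right,cuneus,6,false,rest
precentral_L,left,precentral,6,false,rest
precentral_R,right,precentral,6,false,rest
paracentral_L,left,paracentral,6,false,rest
paracentral_R,right,paracentral,6,false,rest
whole_cerebellum,midline,none,none,true,whole_cerebellum;composite_reference
cerebellum_cortex,midline,none,none,true,cerebellum_cortex
inferior_cerebellum_gm,midline,none,none,true,inferior_cerebellum_gm
brainstem,midline,none,none,true,brainstem;composite_reference
eroded_subcortical_wm,midline,none,none,true,eroded_subcortical_wm;composite_reference
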