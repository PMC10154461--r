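name,class,family
ff_energy,FF,first_order
ff_total_energy,FF,first_order
ff_entropy,FF,first_order
ff_minimum,FF,first_order
ff_p10,FF,first_order
ff_p90,FF,first_order
ff_maximum,FF,first_order
ff_mean,FF,first_order
ff_median,FF,first_order
ff_iqr,FF,first_order
ff_range,FF,first_order
ff_mad,FF,first_order
ff_rmad,FF,first_order
ff_rms,FF,first_order
ff_skewness,FF,first_order
ff_kurtosis,FF,first_order
ff_variance,FF,first_order
ff_uniformity,FF,first_order
mf_mesh_volume,MF,shape
mf_voxel_volume,MF,shape
mf_surface_area,MF,shape
mf_surface_volume_ratio,MF,shape
mf_sphericity,MF,shape
mf_max_3d_diameter,MF,shape
mf_max_2d_diameter_axial,MF,shape
mf_max_2d_diameter_coronal,MF,shape
mf_max_2d_diameter_sagittal,MF,shape
mf_major_axis_length,MF,shape
mf_minor_axis_length,MF,shape
mf_least_axis_length,MF,shape
mf_elongation,MF,shape
mf_flatness,MF,shape
tf_glcm_autocorrelation,TF,glcm
tf_glcm_joint_average,TF,glcm
tf_glcm_cluster_prominence,TF,glcm
tf_glcm_cluster_shade,TF,glcm
tf_glcm_cluster_tendency,TF,glcm
tf_glcm_contrast,TF,glcm
tf_glcm_correlation,TF,glcm
tf_glcm_difference_average,TF,glcm
tf_glcm_difference_entropy,TF,glcm
tf_glcm_difference_variance,TF,glcm
tf_glcm_joint_energy,TF,glcm
tf_glcm_joint_entropy,TF,glcm
tf_glcm_imc1,TF,glcm
tf_glcm_imc2,TF,glcm
tf_glcm_id,TF,glcm
tf_glcm_idm,TF,glcm
tf_glcm_idmn,TF,glcm
tf_glcm_idn,TF,glcm
tf_glcm_inverse_variance,TF,glcm
tf_glcm_max_probability,TF,glcm
tf_glcm_sum_entropy,TF,glcm
tf_glrlm_sre,TF,glrlm
tf_glrlm_lre,TF,glrlm
tf_glrlm_gln,TF,glrlm
tf_glrlm_glnn,TF,glrlm
tf_glrlm_rln,TF,glrlm
tf_glrlm_rlnn,TF,glrlm
tf_glrlm_rp,TF,glrlm
tf_glrlm_glv,TF,glrlm
tf_glrlm_rv,TF,glrlm
tf_glrlm_re,TF,glrlm
tf_glrlm_lglre,TF,glrlm
tf_glrlm_hglre,TF,glrlm
tf_glrlm_srlgle,TF,glrlm
tf_glrlm_srhgle,TF,glrlm
tf_glrlm_lrlgle,TF,glrlm
tf_glrlm_lrhgle,TF,glrlm
tf_glszm_sae,TF,glszm
tf_glszm_lae,TF,glszm
tf_glszm_gln,TF,glszm
tf_glszm_glnn,TF,glszm
tf_glszm_szn,TF,glszm
tf_glszm_sznn,TF,glszm
tf_glszm_zp,TF,glszm
tf_glszm_glv,TF,glszm
tf_glszm_zv,TF,glszm
tf_glszm_ze,TF,glszm
tf_glszm_lglze,TF,glszm
tf_glszm_hglze,TF,glszm
tf_glszm_salgle,TF,glszm
tf_glszm_sahgle,TF,glszm
tf_glszm_lalgle,TF,glszm
tf_glszm_lahgle,TF,glszm
tf_gldm_sde,TF,gldm
tf_gldm_lde,TF,gldm
tf_gldm_gln,TF,gldm
tf_gldm_dn,TF,gldm
tf_gldm_dnn,TF,gldm
tf_gldm_glv,TF,gldm
tf_gldm_dv,TF,gldm
tf_gldm_de,TF,gldm
tf_gldm_lgle,TF,gldm
tf_gldm_hgle,TF,gldm
tf_gldm_sdlgle,TF,gldm
tf_gldm_sdhgle,TF,gldm
tf_gldm_ldlgle,TF,gldm
tf_gldm_ldhgle,TF,gldm
tf_ngtdm_coarseness,TF,ngtdm
tf_ngtdm_contrast,TF,ngtdm
tf_ngtdm_busyness,TF,ngtdm
tf_ngtdm_complexity,TF,ngtdm
tf_ngtdm_strength,TF,ngtdm
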