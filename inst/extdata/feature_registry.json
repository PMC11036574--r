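{
  "registry_version": "1.0",
  "n_bins_default": 64,
  "quantization": "equal-width over in-mask HU range",
  "glcm": "13 lattice directions, distance 1, symmetric, merged",
  "features": {
    "name": ["fo_mean", "fo_median", "fo_minimum", "fo_maximum", "fo_range", "fo_p10", "fo_p25", "fo_p75", "fo_p90", "fo_iqr", "fo_variance", "fo_sd", "fo_skewness", "fo_kurtosis", "fo_energy", "fo_total_energy", "fo_rms", "fo_mad", "fo_robust_mad", "fo_medad", "fo_entropy", "fo_uniformity", "fo_cv", "fo_sum", "shape_voxel_volume", "shape_surface_area", "shape_surface_to_volume", "shape_sphericity", "shape_compactness1", "shape_compactness2", "shape_spherical_disproportion", "shape_max_3d_diameter", "shape_max_diameter_axial", "shape_max_diameter_coronal", "shape_max_diameter_sagittal", "shape_major_axis_length", "shape_minor_axis_length", "shape_least_axis_length", "shape_elongation", "shape_flatness", "shape_bbox_volume", "shape_extent", "shape_equivalent_sphere_diameter", "shape_centroid_offset", "glcm_autocorrelation", "glcm_joint_average", "glcm_cluster_prominence", "glcm_cluster_shade", "glcm_cluster_tendency", "glcm_contrast", "glcm_correlation", "glcm_difference_average", "glcm_difference_entropy", "glcm_difference_variance", "glcm_dissimilarity", "glcm_joint_energy", "glcm_joint_entropy", "glcm_imc1", "glcm_imc2", "glcm_idm", "glcm_idmn", "glcm_id", "glcm_idn", "glcm_inverse_variance", "glcm_maximum_probability", "glcm_sum_average", "glcm_sum_entropy", "glcm_sum_squares", "glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_glnn", "glrlm_rln", "glrlm_rlnn", "glrlm_rp", "glrlm_lglre", "glrlm_hglre", "glrlm_srlgle", "glrlm_srhgle", "glrlm_lrlgle", "glrlm_lrhgle", "glrlm_glv", "glrlm_rv", "glrlm_re", "glszm_sae", "glszm_lae", "glszm_gln", "glszm_glnn", "glszm_szn", "glszm_sznn", "glszm_zp", "glszm_lglze", "glszm_hglze", "glszm_salgle", "glszm_sahgle", "glszm_lalgle", "glszm_lahgle"],
    "category": ["intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "intensity", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "geometric", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural", "textural"],
    "formula": ["\u0001.mean", "\u0001.median", "\u0001.minimum", "\u0001.maximum", "\u0001.range", "\u0001.p10", "\u0001.p25", "\u0001.p75", "\u0001.p90", "\u0001.iqr", "\u0001.variance", "\u0001.sd", "\u0001.skewness", "\u0001.kurtosis", "\u0001.energy", "\u0001.total_energy", "\u0001.rms", "\u0001.mad", "\u0001.robust_mad", "\u0001.medad", "\u0001.entropy", "\u0001.uniformity", "\u0001.cv", "\u0001.sum", "\u0001.voxel_volume", "\u0001.surface_area", "\u0001.surface_to_volume", "\u0001.sphericity", "\u0001.compactness1", "\u0001.compactness2", "\u0001.spherical_disproportion", "\u0001.max_3d_diameter", "\u0001.max_diameter_axial", "\u0001.max_diameter_coronal", "\u0001.max_diameter_sagittal", "\u0001.major_axis_length", "\u0001.minor_axis_length", "\u0001.least_axis_length", "\u0001.elongation", "\u0001.flatness", "\u0001.bbox_volume", "\u0001.extent", "\u0001.equivalent_sphere_diameter", "\u0001.centroid_offset", "\u0001.autocorrelation", "\u0001.joint_average", "\u0001.cluster_prominence", "\u0001.cluster_shade", "\u0001.cluster_tendency", "\u0001.contrast", "\u0001.correlation", "\u0001.difference_average", "\u0001.difference_entropy", "\u0001.difference_variance", "\u0001.dissimilarity", "\u0001.joint_energy", "\u0001.joint_entropy", "\u0001.imc1", "\u0001.imc2", "\u0001.idm", "\u0001.idmn", "\u0001.id", "\u0001.idn", "\u0001.inverse_variance", "\u0001.maximum_probability", "\u0001.sum_average", "\u0001.sum_entropy", "\u0001.sum_squares", "\u0001.sre", "\u0001.lre", "\u0001.gln", "\u0001.glnn", "\u0001.rln", "\u0001.rlnn", "\u0001.rp", "\u0001.lglre", "\u0001.hglre", "\u0001.srlgle", "\u0001.srhgle", "\u0001.lrlgle", "\u0001.lrhgle", "\u0001.glv", "\u0001.rv", "\u0001.re", "\u0001.sae", "\u0001.lae", "\u0001.gln", "\u0001.glnn", "\u0001.szn", "\u0001.sznn", "\u0001.zp", "\u0001.lglze", "\u0001.hglze", "\u0001.salgle", "\u0001.sahgle", "\u0001.lalgle", "\u0001.lahgle"]
  }
}
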