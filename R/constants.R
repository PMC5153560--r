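#' Names of the 13 Haralick texture features
#' @export
HARALICK_FEATURES <- c("energy", "entropy", "correlation", "contrast",
                       "variance", "sum_mean", "agreement", "cluster_shade",
                       "cluster_tendency", "homogeneity", "max_probability",
                       "inverse_variance", "dissimilarity")
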