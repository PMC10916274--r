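# Registration plugin: SIFT-like gradient-histogram features, kNN + ratio
# matching, RANSAC homography. Discovered by histreg's algorithm manager.
plugin_name <- "sift_flann"
plugin_entry <- function(fixed, moving, options) {
  histreg::register_sift(fixed, moving, options)
}
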