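# Registration plugin: ORB-like oriented binary features, Hamming kNN +
# ratio matching, RANSAC homography.
plugin_name <- "orb_flann"
plugin_entry <- function(fixed, moving, options) {
  histreg::register_orb(fixed, moving, options)
}
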