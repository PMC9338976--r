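# Small image constructors used across the imaging tests.

uniform_image <- function(h, w, r, g, b) {
  rgb_image(matrix(as.integer(r), h, w), matrix(as.integer(g), h, w),
            matrix(as.integer(b), h, w))
}

# random 8-bit image, all three channels independent uniform draws
random_image <- function(h, w) {
  rgb_image(matrix(sample(0:255, h * w, TRUE), h, w),
            matrix(sample(0:255, h * w, TRUE), h, w),
            matrix(sample(0:255, h * w, TRUE), h, w))
}

# brute-force per-pixel reference for the green-dominance rule and the
# pooled segment mean: plain loops, no vectorisation shared with the
# implementation under test
naive_pooled_mean <- function(img) {
  vals <- c()
  for (i in seq_len(nrow(img$G))) {
    for (j in seq_len(ncol(img$G))) {
      if (img$G[i, j] > img$R[i, j] && img$G[i, j] > img$B[i, j]) {
        vals <- c(vals, img$G[i, j])
      }
    }
  }
  vals
}
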