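# shared fixtures, all built in code

# 64x64 dark field with a 20x20 bright square; returns image + boundary mask
square_phantom <- function(lo = 10, hi = 200) {
  m <- matrix(lo, 64, 64)
  m[23:42, 23:42] <- hi
  sq <- matrix(FALSE, 64, 64); sq[23:42, 23:42] <- TRUE
  inner <- matrix(FALSE, 64, 64); inner[24:41, 24:41] <- TRUE
  list(image = GrayImage(m, range = c(0, 255)), boundary = sq & !inner)
}

noise_free_spec <- function(k, size = 128L) {
  phantomSpec(image_size = size, tumor_class = k,
              noise = list(salt_pepper_fraction = 0, gaussian_sigma = 0))
}

tiny_stage_spec <- function() {
  list(list(width = c(4, 4, 8), blocks = 1L),
       list(width = c(6, 6, 12), blocks = 1L),
       list(width = c(6, 6, 12), blocks = 2L),
       list(width = c(8, 8, 16), blocks = 1L))
}
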