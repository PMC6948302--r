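# Shared fixtures: tiny phantoms, random masks, and an independent
# connected-component labeller used as an oracle for blob counts.

tiny_pair <- function(grid = 32, contrast = 1, noise = 0, seed = 1,
                      n_blobs = 1) {
  ph <- generate_phantom(phantom_spec(grid_size = grid, n_blobs = n_blobs,
                                      contrast = contrast, noise_sd = noise,
                                      seed = seed))
  list(image = normalize_gray(ph$image), mask = ph$mask, phantom = ph)
}

random_mask <- function(h = 16, w = 16, p = 0.3) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# flood-fill component count over 4-connectivity (independent oracle)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask > 0)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (lab[q] != 0L) next
      lab[q] <- comp
      i <- (q - 1) %% nrow(mask) + 1
      j <- (q - 1) %/% nrow(mask) + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] > 0 && lab[ii, jj] == 0L)
          queue <- c(queue, (jj - 1) * nrow(mask) + ii)
      }
    }
  }
  comp
}

small_net_config <- function(input_size = 32, base_width = 8,
                             n_down_stages = 3, stem_branch_width = 4) {
  network_config(input_size = input_size, base_width = base_width,
                 n_down_stages = n_down_stages,
                 stem_branch_width = stem_branch_width)
}
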