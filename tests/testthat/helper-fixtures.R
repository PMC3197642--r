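# Shared in-code fixtures.

make_occ <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(species = r[[1]], lon = as.numeric(r[[2]]),
               lat = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}

# two species exactly co-distributed on a planted 3x2 cell block, plus noise
# species scattered uniformly over a 20x20 cell region
planted_occurrences <- function(n_noise = 10, seed = 1) {
  block <- expand.grid(col = 5:7, row = 5:6)
  centre <- function(m) {
    data.frame(lon = -80 + (m$col + 0.5) * 0.75,
               lat = 5 - (m$row + 0.5) * 0.75)
  }
  planted <- do.call(rbind, lapply(c("end1", "end2"), function(sp) {
    cbind(species = sp, centre(block))
  }))
  noise <- ancarea:::with_seed(seed, {
    do.call(rbind, lapply(paste0("noise", seq_len(n_noise)), function(sp) {
      cells <- data.frame(col = sample(0:19, 30, TRUE),
                          row = sample(0:19, 30, TRUE))
      cbind(species = sp, centre(cells))
    }))
  })
  rbind(planted, noise)
}
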