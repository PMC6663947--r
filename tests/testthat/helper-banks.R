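# Shared generators for simulation-based tests. Thresholds keep a minimum
# gap so every category stays observable at moderate n.
random_bank <- function(m, C = 5, seed = 1, a_range = c(1.2, 3.2),
                        b1_range = c(-1.8, -0.3), gap_range = c(0.5, 1.0),
                        prefix = "i") {
  set.seed(seed)
  grm_bank(lapply(seq_len(m), function(j) {
    b1 <- stats::runif(1, b1_range[1], b1_range[2])
    gaps <- stats::runif(C - 2L, gap_range[1], gap_range[2])
    grm_item(paste0(prefix, j), stats::runif(1, a_range[1], a_range[2]),
             cumsum(c(b1, gaps)))
  }))
}

toy_bank3 <- function() {
  grm_bank(list(grm_item("t1", 1.8, c(-1.0, 0.2)),
                grm_item("t2", 1.2, c(-0.4, 0.9)),
                grm_item("t3", 2.4, c(0.0, 1.1))))
}

# Calibration settings for simulation tests: coarser grid than the
# package default (these banks are short, their posteriors wide).
test_ctrl <- function(...) {
  grm_control(grid_points = 51L, grid_range = c(-5, 5), tol = 3e-4,
              max_cycles = 300L, ...)
}
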