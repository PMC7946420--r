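# Shared fixtures and independent oracles for the test suite.

# Brute-force oracle for the ISI burst criteria: explicit enumeration over
# the ISI sequence, written independently of label_bursts(). For every
# spike, membership is decided by walking the ISI list with two explicit
# states and recording index ranges.
oracle_burst_labels <- function(times, onset = 80, offset = 160) {
  n <- length(times)
  lab <- rep("non_burst", n)
  if (n < 2) return(lab)
  isi <- diff(times)
  i <- 1
  while (i <= n - 1) {
    if (isi[i] <= onset) {
      j <- i + 1
      while (j <= n - 1 && isi[j] <= offset) j <- j + 1
      lab[i:j] <- "burst"
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  lab
}

# Random spike train with ISIs that straddle both thresholds, including
# exact boundary values 80 and 160 ms.
random_train <- function(len) {
  if (len == 0) return(numeric(0))
  pool <- c(stats::runif(len, 1, 300), rep(c(80, 160), length.out = len))
  isis <- sample(pool, len, replace = TRUE)
  cumsum(isis)
}

# Small deterministic-seed session shared across tests (built once).
tiny_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- task_config()
      neurons <- list(
        neuron_ground_truth(1L, baseline_rate = 4,
                            tonic_gain_increase = 15, cs_phasic_gain = 2,
                            stop_phasic_gain = 2,
                            tonic_mode = "non_burst_dominant"),
        neuron_ground_truth(2L, baseline_rate = 3.5, tonic_mode = "mixed"))
      for (i in seq_along(neurons)) neurons[[i]]$class <-
          c("tonic_increaser", "null")[i]
      cache <<- simulate_population(cfg, neurons = neurons, n_blocks = 1,
                                    seed = 424242)
    }
    cache
  }
})
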