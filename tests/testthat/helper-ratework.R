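# shared helpers for the ratework test suite

rel_err <- function(x, ref) {
  ifelse(ref == 0, abs(x), abs(x / ref - 1))
}

expect_rel <- function(x, ref, rtol) {
  expect_lt(max(rel_err(x, ref)), rtol)
}

# random valid Hill parameter draws for property tests
random_hill <- function(n, seed = 421) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    hill_params(fmax = runif(1, 1, 500),
                a = runif(1, 0.5, 100),
                b = runif(1, 0.01, 2))
  })
}
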