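# shared fixtures: the small simulated tissue and a quick registry tissue
fig_tissue <- function() fig_fixture("fig2")$tissue
fig_mut <- function() fig_fixture("fig2")$mut

# random small valid parameter draws for property-style tests
random_tissue <- function() {
  N0 <- sample(1:20, 1)
  NL <- N0 + sample(0:200, 1)
  tissue_params(N0, NL, r = runif(1, 0.01, 2), a_d = runif(1, 0.01, 2),
                b = runif(1, 0.001, 1))
}
random_mut <- function() {
  mutation_params(runif(1, 0, 0.5), runif(1, 0, 0.1), 0)
}
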