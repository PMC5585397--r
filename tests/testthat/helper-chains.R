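# Build a minimal chain-like object from explicit radial samples, for
# observable tests that need exact control over the sampled configurations.
fake_chain <- function(model, r_samples, energies = NULL) {
  n <- nrow(r_samples)
  r_star <- model$R * exp(model$delta / 2)
  if (is.null(energies)) energies <- rep(0, n)
  structure(list(
    samples = tibble::tibble(
      sample = seq_len(n), sweep = seq_len(n), energy = energies,
      n_condensed = as.integer(rowSums(r_samples <= r_star))),
    r_samples = r_samples,
    model = model), class = "cylcond_chain")
}
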