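# Fixture builders and paths. All data fixtures are either generated here
# in code or shipped as small plain-text files under inst/extdata.

extdata <- function(f) {
  p <- system.file("extdata", f, package = "rfet")
  if (p == "") stop("missing extdata fixture: ", f)
  p
}

# tiny deterministic expression matrix
toy_matrix <- function(n_genes = 3, n_samples = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(round(rnorm(n_genes * n_samples, 8, 1), 4), n_genes, n_samples)
  rownames(m) <- sprintf("g%02d_at", seq_len(n_genes))
  colnames(m) <- sprintf("S%02d", seq_len(n_samples))
  expression_matrix(m)
}

# a ranked list straight from an ordered probe vector (best first) with
# given criteria (aligned to that order)
make_list <- function(probes_best_first, criteria) {
  G <- length(probes_best_first)
  ranked_list(probes_best_first, seq(G, 1), criteria)
}
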