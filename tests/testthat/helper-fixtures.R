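# Shared small fixtures, generated in code.

# small NB count matrix with named dims
small_counts <- function(ng = 20, ns = 4, seed = 1, mu = 50, phi = 0.1) {
  set.seed(seed)
  m <- matrix(rnbinom(ng * ns, mu = mu, size = 1 / phi), ng, ns,
              dimnames = list(sprintf("g%02d", 1:ng), sprintf("s%d", 1:ns)))
  storage.mode(m) <- "integer"
  m
}

# two-group sample table in the LMP/VI grade coding
two_group_samples <- function(n_per = 10) {
  data.frame(sample_id = sprintf("s%02d", seq_len(2 * n_per)),
             grade = rep(c("LMP", "VI"), each = n_per),
             stringsAsFactors = FALSE)
}

# minimal spot grid on an integer lattice with given labels
toy_grid <- function(labels, pitch = 100, ng = 30, seed = 1,
                     sample_id = "s1") {
  set.seed(seed)
  n <- length(labels)
  side <- ceiling(sqrt(n))
  counts <- matrix(rpois(ng * n, 20), ng, n,
                   dimnames = list(sprintf("g%02d", 1:ng),
                                   sprintf("%s_sp%03d", sample_id, 1:n)))
  storage.mode(counts) <- "integer"
  spots <- data.frame(spot_id = colnames(counts),
                      x_um = ((seq_len(n) - 1) %% side) * pitch,
                      y_um = ((seq_len(n) - 1) %/% side) * pitch,
                      label = labels, sample_id = sample_id,
                      stringsAsFactors = FALSE)
  spot_grid(counts, spots)
}
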