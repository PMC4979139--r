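# Shared helpers: tiny HSP tables and simulator configs built in code.

make_hsp <- function(qseqid, sseqid, pident, length, sstart, send,
                     evalue = 1e-60, qstart = 1) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = 0, gapopen = 0,
             qstart = qstart, qend = qstart + length - 1,
             sstart = sstart, send = send, evalue = evalue,
             bitscore = 2 * length,
             strand = ifelse(send >= sstart, "+", "-"),
             stringsAsFactors = FALSE)
}

# single uniform chromosome, clean calls unless stated otherwise
uniform_config <- function(length_mb = 50, rr = 2, n_progeny = 200,
                           markers = 10, seed = 42, error = 0, missing = 0,
                           frac_testcross = 1, model = "poisson") {
  sim_config(chromosomes = list(sim_chromosome(1, length_mb, rr = rr)),
             n_progeny = n_progeny, markers_per_chromosome = markers,
             frac_testcross = frac_testcross, genotyping_error = error,
             missing_rate = missing, crossover_model = model, seed = seed)
}

# brute-force grid maximiser of the F2 dominant-pair likelihood (oracle)
grid_rf_f2 <- function(counts, step = 1e-4) {
  grid <- seq(0, 0.5, by = step)
  best <- list(loglik = -Inf)
  for (ph in c("coupling", "repulsion")) {
    p <- if (ph == "coupling") (1 - grid)^2 else grid^2
    ll <- counts[1] * log((2 + p) / 4) + (counts[2] + counts[3]) * log(pmax((1 - p) / 4, 1e-300)) +
      counts[4] * log(pmax(p / 4, 1e-300))
    i <- which.max(ll)
    if (ll[i] > best$loglik) best <- list(r_hat = grid[i], phase = ph, loglik = ll[i])
  }
  best
}
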