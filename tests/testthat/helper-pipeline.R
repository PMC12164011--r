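# Shared builders: small simulated panels run through the full qPCR chain.

panel_populations <- function(block_probs, n_cells = 10000,
                              f_true = 0.5, ct_noise_sd = 0.15,
                              residence_minutes = 1e9,
                              layout = default_layout()) {
  cfg <- sim_config(n_cells = n_cells, f_true = f_true,
                    ct_noise_sd = ct_noise_sd, block_probs = block_probs,
                    residence_minutes = residence_minutes)
  cfg_ref <- cfg; cfg_ref$block_probs <- numeric(0)
  cfg_nod <- cfg_ref; cfg_nod$f_true <- 0
  list(config = cfg,
       pops = list(test = simulate_population(cfg, layout),
                   reference = simulate_population(cfg_ref, layout),
                   glucose = simulate_population(cfg_nod, layout)))
}

# One full simulate -> Ct plate -> analysis pass; returns the blocking
# efficiency at the requested SphI site for the test strain.
measure_blocking <- function(block_probs, site = "SphI-3", ...) {
  layout <- default_layout()
  built <- panel_populations(block_probs, ...)
  pq <- simulate_ct_plate(built$pops, built$config, layout)
  res <- analyze_experiment(pq$plate, pq$standards, layout,
                            reference_sample = "reference",
                            no_dsb_sample = "glucose")
  res$table$blocking_efficiency[res$table$sample_id == "test" &
                                res$table$site == site]
}

# The measurement as reported: mean over independent biological replicates
# (each replicate is a fresh population and plate).
measure_blocking_mean <- function(block_probs, n_bio = 6, ...) {
  mean(vapply(seq_len(n_bio), function(i) measure_blocking(block_probs, ...),
              numeric(1)))
}

# Minimal hand-built pileup: counts for a run of positions with given
# reference bases and per-base counts.
make_pileup <- function(pos, ref, A = 0, C = 0, G = 0, T = 0) {
  data.frame(pos = pos, ref = ref, A = A, C = C, G = G, T = T,
             stringsAsFactors = FALSE)
}
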