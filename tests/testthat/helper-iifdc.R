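# shared helpers for the suite

# a vital-rates bundle with no predation and no perception thresholds:
# fitness then reduces to growth over background mortality
vr_growth_only <- function(age = "juvenile") {
  vr <- default_vital_rates(age, "II", predator_density = 0)
  vr$perception <- perception_params(ae_food = 0, ae_light = 0)
  vr
}

# paired per-replicate mean depths for two configurations sharing a root
# seed (replicate r of both uses the same derived seed)
paired_depths <- function(cfg_a, cfg_b, reps = 20L, seed = 1L) {
  cfg_a$n_replicates <- reps; cfg_b$n_replicates <- reps
  cfg_a$seed <- seed; cfg_b$seed <- seed
  list(a = run_replicates(cfg_a)$per_replicate_mean_depth,
       b = run_replicates(cfg_b)$per_replicate_mean_depth)
}

# one-sided sign test that 'deeper' exceeds 'shallower' per replicate
sign_test_p <- function(deeper, shallower) {
  stats::binom.test(sum(deeper > shallower), length(deeper),
                    alternative = "greater")$p.value
}
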