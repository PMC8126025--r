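# Shared fixtures: one small noisy run and one noise-free run, generated
# once per test session.

tiny_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- simulate_ffe_run(
        sim_config(n_proteins_per_compartment = 4, seed = 101)
      )
    }
    val
  }
})

clean_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- simulate_ffe_run(
        sim_config(n_proteins_per_compartment = 3, dual_fraction = 0,
                   noise_cv = 0, missing_rate = 0, od280_noise_cv = 0,
                   seed = 202)
      )
    }
    val
  }
})

# single-protein westerns tibble from a plain numeric profile
profile_tbl <- function(x, samples = seq_along(x), id = "p1") {
  tibble::tibble(protein_id = id, sample = as.integer(samples),
                 rel_abundance = x)
}
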