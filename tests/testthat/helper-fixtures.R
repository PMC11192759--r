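# Shared fixtures, built once per test run.

chain_network <- function() {
  signaling_network(
    tibble::tibble(id = c("A", "B", "C")),
    tibble::tibble(source = c("A", "B"), target = c("B", "C"),
                   sign = 1, weight = 1)
  )
}

# default fixture bundle and a light simulation configuration for tests
the_bundle <- make_fixture_bundle(fixture_spec())
the_filtered <- filter_bioactivity(the_bundle$bioactivity)
fast_cfg <- sim_config(n_replicates = 10, rng_seed = 11)

profile_of <- function(drug) target_profile(the_filtered, drug)
avatar_of <- function(cl) fixture_avatar(the_bundle, cl)
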