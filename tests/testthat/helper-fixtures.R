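# shared fixture builders (all data generated in code at test time)

# small single-site config with a null effect unless overridden
null_config <- function(n = 200L, n_sites = 1L, seed = 1L, ...) {
  zero <- stats::setNames(rep(0, 25), roi_registry()$roi)
  generator_config(n_sites = n_sites, n_controls = n, n_patients = n,
                   true_d = zero, tau_between_site = 0,
                   site_location_sd = 0, seed = seed, ...)
}

# synthetic per-site records for meta tests: yi ~ N(mu, tau) with known sei
make_records <- function(k, mu = -0.4, tau = 0, se = 0.1, seed = 1L,
                         roi = "AverageFA", model_id = "casecontrol_FA") {
  set.seed(seed)
  data.frame(site_id = sprintf("site%02d", seq_len(k)), roi = roi,
             metric = "FA", model_id = model_id,
             estimate = stats::rnorm(k, mu, tau) + stats::rnorm(k, 0, se),
             se = rep(se, k), stat = NA_real_, df = 100L,
             n1 = 50L, n2 = 50L, stringsAsFactors = FALSE)
}

# tiny hand-built atlas: explicit labels, rest periphery
tiny_atlas <- function(labels, n_periphery = 0L) {
  atlas_labels(c(labels, rep("PERIPHERY", n_periphery)))
}
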