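# Simulated hierarchical data for the mixed-model engine: sites with a
# site-level predictor, random site intercepts, residual noise.
simulate_lmm_data <- function(n_sites = 18, walks_per_site = 4, beta = -2e-4,
                              intercept = 1, site_sd = 0.2, resid_sd = 0.3,
                              seed = 1) {
  withr::with_seed(seed, {
    elev <- seq(1000, 4400, length.out = n_sites)
    site_eff <- rnorm(n_sites, 0, site_sd)
    tibble::tibble(
      site_id = rep(sprintf("s%02d", 1:n_sites), each = walks_per_site),
      elevation = rep(elev, each = walks_per_site),
      lui = rep(-(elev - mean(elev)) / sd(elev) + rnorm(n_sites, 0, 0.8),
        each = walks_per_site
      ),
      y = intercept + beta * rep(elev, each = walks_per_site) +
        rep(site_eff, each = walks_per_site) +
        rnorm(n_sites * walks_per_site, 0, resid_sd)
    )
  })
}
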