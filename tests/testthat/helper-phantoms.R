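# Shared phantom fixtures, generated once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small noisy tube phantom with all channels
ph_small <- function() cached("ph_small", {
  generate_phantom(phantom_spec(n_cells = 12), seed = 7)
})

# clean phantom (no noise / PSF / attenuation) for exact recovery checks
ph_clean <- function() cached("ph_clean", {
  generate_phantom(phantom_spec(n_cells = 15, noise_sd = 0, psf_sigma_um = 0),
                   seed = 9)
})

# single isolated cell with clean channels
ph_single <- function() cached("ph_single", {
  generate_phantom(phantom_spec(n_cells = 1, noise_sd = 0, psf_sigma_um = 0,
                                edu = FALSE, arrangement = "scatter",
                                radius_jitter = 0),
                   seed = 3)
})

guide_small <- function() cached("guide_small", {
  ph <- ph_small()
  make_guide_worm(ph$membrane, 4, 0.25)
})

# dense clean grid phantom (epithelium-like; every x-slice averages many cells)
ph_grid <- function() cached("ph_grid", {
  generate_phantom(phantom_spec(n_cells = 64, arrangement = "grid",
                                noise_sd = 0, psf_sigma_um = 0, edu = FALSE),
                   seed = 9)
})
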