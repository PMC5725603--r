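# Shared fixtures: small grids keep the unit tests fast; the acceptance
# tests use the production resolution.

tiny_uniform <- function(sigma = 0.35, h = 5, half = 60)
  uniform_box_model(sigma = sigma, grid_spacing = h, box_half_width = half)

coarse_model <- function()
  abdomen_model(grid_spacing = 10, box_half_width = 120)

default_band <- function() dipole_band_params()

# all monomials x^i y^j with i + j <= deg
monomial_grid <- function(deg) {
  out <- list()
  for (i in 0:deg) for (j in 0:(deg - i)) out[[length(out) + 1]] <- c(i, j)
  out
}

# electrode spec tuned for exactness checks: ideal line rings, point centre
ideal_spec <- function(kind, r = 5)
  electrode_spec(kind, r = r, ring_width = 0, v0_mode = "point",
                 disc_radius = 0.1 * r)
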