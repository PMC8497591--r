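# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small curved wing-disc-like phantom used across modules
small_phantom <- function() fixture("small", function() {
  phantom(phantom_config(nx = 120, ny = 120, nz = 40,
                         surface_kind = "quadratic",
                         surface_params = list(zmin = 3, zmax = 16.5),
                         cell_diameter = 2.5, seed = 3L))
})

# pure-background phantom (one huge cell -> no internal contour)
background_phantom <- function(nx = 100, ny = 100, nz = 100, seed = 2L,
                               noise_cv = 0.15) {
  phantom(phantom_config(nx = nx, ny = ny, nz = nz, surface_kind = "flat",
                         cell_diameter = nx * 0.27 * 3, noise_cv = noise_cv,
                         seed = seed))
}

# flat synthetic shell on a constant surface, no phantom required
flat_shell <- function(nx = 20, ny = 20, nz = 50, z_um = 12, epsilon = 3,
                       dz = 0.5) {
  sm <- structure(list(Z_hat = matrix(z_um, nx, ny),
                       support = matrix(TRUE, nx, ny)),
                  class = "surface_model")
  build_shell(sm, epsilon = epsilon, dz = dz, nz = nz)
}

# sample_set constructor for hand-built cases
sample_set <- function(x, y, z, value = 0, normalized = NA_real_,
                       iteration = 0L) {
  data.frame(x = as.integer(x), y = as.integer(y), z = as.integer(z),
             value = value, normalized = normalized,
             iteration = as.integer(iteration))
}
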