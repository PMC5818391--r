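# Shared fixtures, built once per test run and cached in a local
# environment. Everything is generated in code; no files are read.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- force(expr)
  .fx_env[[name]]
}

fx_geom <- function() fx("geom", default_nema_geometry())
fx_pet <- function() fx("pet", preset("pet-ga68"))
fx_spect <- function() fx("spect", preset("spect-in111"))

fx_fm_pet <- function() fx("fm_pet", voxelize(fx_geom(), fx_pet()$grid))
fx_fm_spect <- function() fx("fm_spect", voxelize(fx_geom(), fx_spect()$grid))

fx_acq_pet_noiseless <- function() {
  acq <- fx_pet()$acq
  acq$noise <- noise_model("none")
  acq
}

# Noiseless PET-like images at the standard SBR levels (sphere 20 kBq/mL).
fx_pet_noiseless <- function(sbr) {
  key <- paste0("pet_nl_", sbr)
  fx(key, simulate_phantom(fx_geom(), fx_pet()$grid, activity_from_sbr(sbr, 20),
                           fx_acq_pet_noiseless(), fractions = fx_fm_pet()))
}

fx_activity <- function(sbr) activity_from_sbr(sbr, 20)
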