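# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small synthetic library (fast; used by module-level tests)
small_library <- function() {
  cached("small_lib", {
    generate_library(synthetic_library_spec(
      n_actives = 12, n_moderate = 60, n_inactive = 16, seed = 2718))
  })
}

# the full pipeline fitted on the small library
small_pipeline <- function() {
  cached("small_pipe", {
    suppressMessages(run_qsar_pipeline(small_library()$records, seed = 2718))
  })
}

# a rigid planted-scaffold molecule (no alternates, no rigid motion)
template_benzamide <- function(id = "tmpl", aryl = "phenyl", para = "H",
                               meta = "H", ortho = "H") {
  pharmqsar:::build_benzamide(id, aryl, para, meta, ortho)
}

# single-conformer ensemble at the template geometry
rigid_ensemble <- function(built) {
  conformer_ensemble(built$mol, list(pharmqsar:::coords(built$mol)), 0)
}

# 3D molecules parsed from SMILES, cached (Open Babel embedding)
mol3d <- function(smiles) {
  cached(paste0("smi_", smiles), smiles_to_molgraph(smiles)[[1]])
}
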