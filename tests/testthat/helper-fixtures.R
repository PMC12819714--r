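## Shared fixtures, built once per test session and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

case1_mesh <- function() memo("case1_mesh", function()
  build_lv_geometry(lv_case_spec(1)))

case1_fibers <- function() memo("case1_fibers", function()
  generate_fibers(case1_mesh()))

## potential map calibrated from the single-cell peak (patch protocol)
calibrated_ep <- function() memo("calibrated_ep", function() {
  cell <- simulate_single_cell(phi0 = 0.7, duration = 150)
  cal <- calibrate_potential_mapping(0, attr(cell, "phi_max"))
  ep_params(delta_phi = cal$delta_phi, beta_phi = cal$beta_phi)
})

## annulus mesh with endo/epi tags for transmural-field tests
annulus_mesh <- function() memo("annulus_mesh", function() {
  ann <- mesh_cylinder_shell(20, 27, 8, n_r = 6, n_theta = 48, n_z = 2)
  ann$surfaces$endocardium <- ann$surfaces$inner
  ann$surfaces$epicardium <- ann$surfaces$outer
  ann
})

## slab (box) with endo at x = 1, epi at x = 0
slab_mesh <- function() memo("slab_mesh", function() {
  b <- mesh_box(6, 4, 4, 1, 1, 1)
  b$surfaces$epicardium <- b$surfaces$x0
  b$surfaces$endocardium <- b$surfaces$x1
  b
})

## short coupled run shared between driver tests
short_run <- function() memo("short_run", function()
  run_systolic_case(sim_config(case_id = 1, duration = 120, dt = 1)))
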