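base <- node_chain()

test_that("the identity scenario leaves the chain untouched and builders are pure", {
  ident <- build_scenario(scenario_spec("normal"), base)
  expect_equal(ident, base)
  a <- build_scenario(scenario_spec("crush_detach"), base)
  b <- build_scenario(scenario_spec("crush_detach"), base)
  expect_identical(a, b)
})

test_that("crush stretches the bare width (capacitance) but not the Na span", {
  crush <- build_scenario(scenario_spec("crush"), base)
  inj <- 8:20 + 1
  expect_equal(crush$s_j[inj], rep(3 * base$geometry$s, 13))
  expect_equal(crush$C_j[inj], 3 * base$C_j[inj])
  expect_equal(crush$s_star_j, base$s_star_j)       # channels stay put
  expect_equal(crush$R_p_j, base$R_p_j)             # paranodes intact
  expect_equal(crush$s_j[-inj], base$s_j[-inj])     # uninjured untouched
})

test_that("detachment and blockade modify R_p and the K waveform as specified", {
  detach <- build_scenario(scenario_spec("crush_detach"), base)
  inj <- 8:20 + 1
  expect_equal(detach$R_p_j[inj], rep(0.1 * base$electrical$R_p, 13))
  expect_equal(detach$R_p_j[-inj], base$R_p_j[-inj])
  blocked <- build_scenario(scenario_spec("block"), base)
  expect_equal(blocked$R_p_j[inj], rep(0.01 * base$electrical$R_p, 13))
  treated <- build_scenario(scenario_spec("treated"), base)
  expect_equal(treated$kinetics_k$block_factor, 0.2)
  # blockade acts globally and scales the waveform's peak
  expect_equal(conductance(treated$kinetics_k, 5e-4), 0.2 * 0.013)
  expect_equal(treated$kinetics_na$block_factor, 1)
})

test_that("malformed scenario inputs are rejected", {
  expect_error(build_scenario(scenario_spec("crush", injured_nodes = 0:20),
                              base), "1..20")
  expect_error(build_scenario(scenario_spec("crush", injured_nodes = 21),
                              base), "1..20")
  expect_error(scenario_spec("crush", stretch_factor = -1), "positive")
  expect_error(scenario_spec("treated", k_block_factor = 1.5), "blockade")
})

test_that("a single-width sweep row equals a plain run", {
  ch <- node_chain()
  tab <- sweep_node_width(ch$geometry$s, base = ch, t_max = 1e-3)
  sim <- simulate_axon(ch, t_max = 1e-3, trace = FALSE)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$velocity_m_per_s, conduction_velocity(sim, 4, 5))
  expect_equal(tab$node_width_um, 0.65)
})

test_that("velocity decreases with node width over a short sweep", {
  tab <- sweep_node_width(c(0.5, 1.0, 2.0) * 1e-4, t_max = 1.2e-3)
  expect_false(any(tab$blocked))
  expect_true(all(diff(tab$velocity_m_per_s) < 0))
})

test_that("configs round-trip through YAML and honour unit suffixes", {
  cfg <- axon_config("crush_detach", dt_us = 0.2, tmax_ms = 1.5,
                     node_width_um = 0.7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_axon_config(cfg, path)
  back <- read_axon_config(path)
  expect_equal(back, cfg)
  ch <- build_chain(back)
  expect_equal(ch$geometry$s, 0.7e-4)
  expect_equal(ch$s_j[10], 3 * 0.7e-4)            # scenario applied
  expect_equal(ch$R_p_j[10], 3.2e9)
  expect_equal(ch$electrical$V_rest, -0.085)
  expect_error(axon_config(bogus_key = 1), "unknown config key")
})

test_that("raw (a, b) kinetics keys override peak-coordinate keys", {
  cfg <- axon_config("normal", na_a = 2.1e7, na_b = 2e4)
  ch <- build_chain(cfg)
  expect_equal(ch$kinetics_na$a, 2.1e7)
  expect_equal(ch$kinetics_na$t_star, 1e-4)
})

test_that("all canonical fixtures are written, load, and build runnable chains", {
  dir <- withr::local_tempdir()
  paths <- generate_fixtures(dir)
  expect_length(paths, 6)
  expect_true(all(file.exists(paths)))
  for (p in paths) {
    cfg <- read_axon_config(p)
    expect_s3_class(build_chain(cfg), "node_chain")
  }
  treated <- read_axon_config(file.path(dir, "treated.yaml"))
  expect_equal(treated$k_block_factor, 0.2)
  expect_equal(treated$rp_factor, 0.01)
  # smoke-run one fixture end to end at a short window
  cfg <- read_axon_config(file.path(dir, "normal.yaml"))
  cfg$tmax_ms <- 0.5
  sim <- simulate_axon(build_chain(cfg), dt = cfg$dt_us * 1e-6,
                       t_max = cfg$tmax_ms * 1e-3, trace = FALSE)
  expect_true(sim$activated[6])
})

test_that("trace CSV and summary JSON exports are well formed", {
  sim <- simulate_axon(node_chain(n_nodes = 5), t_max = 4e-4)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(sim, csv)
  df <- utils::read.csv(csv)
  expect_identical(names(df), c("time_s", paste0("V_node", 0:4)))
  expect_equal(nrow(df), length(sim$times))
  expect_equal(df$V_node0, sim$V[1, ], tolerance = 1e-9)
  js <- withr::local_tempfile(fileext = ".json")
  suppressWarnings(write_summary_json(sim, js, normal_pair = c(1L, 2L),
                                      injured_pair = c(2L, 3L)))
  out <- jsonlite::read_json(js)
  expect_equal(out$n_nodes, 5)
  expect_length(out$tau_s, 5)
  expect_equal(out$v_normal_m_per_s,
               conduction_velocity(sim, 1, 2), tolerance = 1e-9)
})
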