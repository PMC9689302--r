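test_that("sim_control and presets carry the expected settings", {
  ctrl <- sim_control()
  expect_s3_class(ctrl, "sim_control")
  expect_equal(ctrl$nx, 200L)
  expect_equal(ctrl$perturb, 0)

  desk <- preset_control("desk")
  expect_equal(c(desk$nx, desk$ny), c(200L, 16L))
  expect_false(desk$turbulence)
  expect_equal(desk$end_time, 3)
  expect_equal(desk$perturb, 0.02)

  paper <- preset_control("paper")
  expect_equal(c(paper$nx, paper$ny), c(400L, 30L))
  expect_true(paper$turbulence)
  expect_equal(paper$end_time, 6)

  over <- preset_control("desk", end_time = 1, seed = 9L)
  expect_equal(over$end_time, 1)
  expect_equal(over$seed, 9L)
})

test_that("case_config validates the stenosis/valve layout", {
  expect_s3_class(case_config("x", vessel_geometry(f = 0.3)), "case_config")
  expect_error(
    case_config("x", vessel_geometry(f = 0.3, xs = 0.12),
                valve = valve_spec(anchor_x = 0.110)),
    "overlaps")
  expect_error(
    case_config("x", vessel_geometry(),
                valve = valve_spec(anchor_x = 0.197)),
    "outlet")
})

test_that("standard_cases defines the four stenosis fractions", {
  cases <- standard_cases()
  expect_named(cases, c("A", "B", "C", "D"))
  expect_equal(vapply(cases, function(cc) cc$geometry$f, numeric(1)),
               c(A = 0, B = 0.30, C = 0.60, D = 0.75))
  expect_equal(cases$D$geometry$d1, 0.25 * 0.015)
})

test_that("configurations round-trip through YAML with a stable hash", {
  cfg <- case_config("B", vessel_geometry(f = 0.3),
                     control = sim_control(nx = 50, ny = 10, end_time = 0.5))
  path <- tempfile(fileext = ".yml")
  on.exit(unlink(path))
  write_case_config(cfg, path)
  back <- read_case_config(path)
  expect_equal(back$geometry$f, 0.3)
  expect_equal(back$control$nx, 50L)
  expect_equal(config_hash(back), config_hash(cfg))

  cfg2 <- cfg; cfg2$geometry <- vessel_geometry(f = 0.6)
  expect_false(config_hash(cfg2) == config_hash(cfg))
  # hash is deterministic across calls
  expect_equal(config_hash(cfg), config_hash(cfg))
})

test_that("export_run writes a complete, traceable output set", {
  cfg <- case_config(
    "mini", vessel_geometry(f = 0.5, xs = 0.02, ls = 0.005),
    valve = valve_spec(n_nodes = 8),
    control = sim_control(nx = 60, ny = 10, end_time = 0.02,
                          snapshot_times = 0.02, metric_dt = 0.01))
  out <- tempfile("ijv-out-")
  on.exit(unlink(out, recursive = TRUE))
  res <- run_case(cfg, out_dir = out)

  expect_true(file.exists(file.path(out, "metrics.csv")))
  expect_true(file.exists(file.path(out, "profile_final.csv")))
  expect_true(file.exists(file.path(out, "leaflets.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  vtk <- list.files(out, pattern = "^fields_.*\\.vtk$")
  expect_gte(length(vtk), 1)

  m <- read.csv(file.path(out, "metrics.csv"))
  expect_true(all(c("time", "umax", "reverse_area", "asymmetry") %in%
                    names(m)))
  expect_equal(max(m$time), 0.02)

  manifest <- jsonlite::read_json(file.path(out, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$case, "mini")
  expect_true(all(c("metrics.csv", "manifest.json") %in%
                    c(manifest$files, "manifest.json")))
  # provenance: the recorded hash matches a config rebuilt from the
  # manifest alone
  ypath <- tempfile(fileext = ".yml")
  on.exit(unlink(ypath), add = TRUE)
  yaml::write_yaml(manifest$config, ypath)
  rebuilt <- read_case_config(ypath)
  expect_equal(config_hash(rebuilt), manifest$provenance$config_hash)
  expect_equal(res$provenance$config_hash, manifest$provenance$config_hash)
})

test_that("write_vtk_image produces a parseable legacy header", {
  grid <- flow_grid(6, 4)
  path <- tempfile(fileext = ".vtk")
  on.exit(unlink(path))
  f <- matrix(seq_len(24) / 10, 6, 4)
  write_vtk_image(path, grid, list(speed = f))
  lines <- readLines(path)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true("DATASET STRUCTURED_POINTS" %in% lines)
  expect_true(sprintf("DIMENSIONS %d %d 1", 6, 4) %in% lines)
  i <- which(lines == "LOOKUP_TABLE default")
  vals <- as.numeric(lines[(i + 1):(i + 24)])
  # x varies fastest in VTK order; our column-major [i, j] matches
  expect_equal(vals, as.vector(f))
  expect_error(write_vtk_image(path, grid, list()))
})
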