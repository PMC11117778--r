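test_that("the four presets encode the published geometries", {
  e1 <- scenario_factory("example1")
  expect_equal(nrow(e1$sprouts), 1L)
  expect_equal(e1$sprouts[1, 2], 0.1)           # on the lower monolayer
  expect_equal(e1$nodes_per_side, 51L)
  expect_equal(e1$D_base, 1.16e-6)
  expect_equal(e1$conc_lumen, 2.35e-13)
  expect_equal(e1$conc_release, 6.43e-13)
  expect_equal(nrow(scenario_factory("example2")$sprouts), 2L)
  e3 <- scenario_factory("example3")
  expect_equal(nrow(e3$sprouts), 1L)
  r3 <- e3$release_rects[[1]]
  expect_true(r3[1] >= 3.9 && r3[2] >= 3.9)     # upper-right corner
  e4 <- scenario_factory("example4")
  expect_equal(nrow(e4$sprouts), 4L)
  expect_equal(length(e4$lumen_rects), 2L)      # two parent vessels
  r4 <- e4$release_rects[[1]]
  expect_true(r4[2] < 2.5 && r4[4] > 2.5)       # mid-domain release
  expect_error(scenario_factory("example9"), class = "invalid_argument")
})

test_that("network metrics count lengths and branch points exactly", {
  two_seg <- structure(list(
    segments = data.frame(x1 = c(0, 1), y1 = c(0, 0),
                          x2 = c(1, 2), y2 = c(0, 0),
                          order = c(1, 1), step = 1:2),
    branch_points = data.frame(x = numeric(0), y = numeric(0),
                               step = numeric(0)),
    tips = data.frame(), rng_seed = 1L, bounds = c(0, 0, 5, 5),
    iterations = 2L, truncated = FALSE), class = "capillary_network")
  m <- network_metrics(two_seg)
  expect_equal(m$total_length, 2.0)
  expect_equal(m$n_branches, 0L)

  y_net <- two_seg
  y_net$segments <- data.frame(x1 = c(0, 1, 1), y1 = c(0, 0, 0),
                               x2 = c(1, 2, 1), y2 = c(0, 1, -1),
                               order = c(1, 2, 2), step = 1:3)
  y_net$branch_points <- data.frame(x = 1, y = 0, step = 1)
  expect_equal(network_metrics(y_net)$n_branches, 1L)
  expect_equal(network_metrics(y_net)$n_segments, 3L)

  # percent-of-control arithmetic
  ctrl <- two_seg
  loaded <- two_seg
  loaded$segments$x2 <- loaded$segments$x1 + 1.68
  pm <- network_metrics(loaded, control = ctrl)
  expect_equal(pm$percent_of_control$total_length, 68, tolerance = 1e-12)
})

test_that("pressure conversion is linear, invertible and prints 0.0067 MPa", {
  expect_equal(signif(convert_pressure(50), 2), 0.0067)
  expect_equal(convert_pressure(0), 0)
  expect_equal(convert_pressure(760), 0.1013, tolerance = 1e-3)
  expect_equal(convert_pressure(2 * 50), 2 * convert_pressure(50))
  expect_equal(convert_pressure(50) / 133.322e-6, 50)
  expect_error(convert_pressure(Inf), class = "invalid_argument")
})

test_that("networks survive a CSV round trip with identical metrics", {
  cfg <- coarse_example1(seed = 5L, theta_mode = "uniform")
  net <- run_simulation(cfg)$network
  path <- tempfile(fileext = ".csv")
  write_network_csv(net, path)
  back <- read_network_csv(path)
  m0 <- network_metrics(net)
  m1 <- network_metrics(back)
  expect_equal(m1$total_length, m0$total_length, tolerance = 1e-7)
  expect_equal(m1$n_segments, m0$n_segments)
  expect_equal(m1$n_branches, m0$n_branches)
})

test_that("experiment reports are deterministic given the seed list", {
  cfg <- coarse_example1()
  r1 <- run_experiment(cfg, loading = "compression", alpha = 1.0,
                       seeds = c(11, 12))
  r2 <- run_experiment(cfg, loading = "compression", alpha = 1.0,
                       seeds = c(11, 12))
  expect_identical(r1$per_seed, r2$per_seed)
  expect_true(all(is.finite(r1$per_seed$pct_length)))
})

test_that("field and VTK exports write well-formed files", {
  cl <- build_regular_nodal_cloud(1, 3)
  vals <- list(a = seq_len(9) / 9)
  p1 <- tempfile(fileext = ".csv")
  write_field_csv(cl$coords, vals, p1)
  df <- read.csv(p1)
  expect_equal(nrow(df), 9L)
  expect_equal(names(df), c("x", "y", "a"))
  p2 <- tempfile(fileext = ".vtk")
  write_vtk_points(cl$coords, vals, p2)
  lines <- readLines(p2)
  expect_equal(lines[4], "DATASET POLYDATA")
  expect_equal(lines[5], "POINTS 9 float")
})

test_that("the command line front end runs its subcommands", {
  out <- tempfile()
  code <- cli_main(c("simulate", "--preset", "example1",
                     "--nodes-per-side", "11", "--seed", "4",
                     "-o", out))
  expect_equal(code, 0L)
  expect_true(file.exists(file.path(out, "network.csv")))
  expect_true(file.exists(file.path(out, "network.json")))
  expect_true(file.exists(file.path(out, "network.vtk")))

  out2 <- tempfile()
  code2 <- cli_main(c("fields", "--preset", "example1",
                      "--nodes-per-side", "11",
                      "--loading", "traction", "--alpha", "1.5",
                      "-o", out2))
  expect_equal(code2, 0L)
  dmap <- read.csv(file.path(out2, "diffusivity.csv"))
  # traction at alpha = 1.5: near-centre diffusivity approaches 2.5x base
  expect_equal(max(dmap$diffusivity), 2.9e-6, tolerance = 0.02)
  expect_equal(min(dmap$diffusivity), 1.16e-6, tolerance = 1e-9)

  expect_equal(suppressMessages(cli_main(c("bogus"))), 2L)
  expect_equal(suppressMessages(cli_main(character(0))), 2L)
})

test_that("yaml configuration files override preset values", {
  yml <- tempfile(fileext = ".yml")
  writeLines(c("nodes_per_side: 11", "d0: 0.5"), yml)
  opts <- angiomech:::cli_parse(c("--preset", "example1", "--config", yml,
                                  "--seed", "7"))
  cfg <- angiomech:::cli_config(opts)
  expect_equal(cfg$nodes_per_side, 11L)
  expect_equal(cfg$d0, 0.5)
  expect_equal(cfg$seed, 7L)
})
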