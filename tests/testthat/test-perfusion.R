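test_that("zero porosity outside the inlet confines the tracer", {
  por <- matrix(0, 9, 9); por[5, 5] <- 1
  p <- make_por(por, pixel_size = 0.1)
  f <- simulate_tracer(p, data.frame(row = 5, col = 5),
                       sim_config(duration = 1))
  expect_identical(f$arrival[5, 5], 0)
  expect_identical(sum(is.finite(f$arrival)), 1L)
})

test_that("arrival time grows ring by ring in a uniform medium", {
  p <- make_por(matrix(1, 21, 21), pixel_size = 0.1)
  f <- simulate_tracer(p, data.frame(row = 11, col = 11),
                       sim_config(D0 = 1, duration = 3))
  ring <- pmax(abs(row(p$porosity) - 11), abs(col(p$porosity) - 11))
  mean_arrival <- tapply(f$arrival[is.finite(f$arrival)],
                         ring[is.finite(f$arrival)], mean)
  expect_true(all(diff(mean_arrival) > 0))
  # maximum principle: concentration bounded by the source
  expect_true(all(f$final_concentration >= -1e-12))
  expect_true(all(f$final_concentration <= 1 + 1e-12))
})

test_that("an unstable explicit time step is rejected naming the bound", {
  p <- make_por(matrix(1, 8, 8), pixel_size = 0.1)
  bound <- 0.1^2 / (4 * 2)
  expect_error(
    simulate_tracer(p, data.frame(row = 1, col = 1),
                    sim_config(D0 = 2, time_step = bound * 1.5)),
    "stability bound")
  expect_error(
    simulate_tracer(make_por(matrix(0.001, 4, 4)),
                    data.frame(row = 1, col = 1), sim_config()),
    "blocked")
})

test_that("total mass is conserved once sources are released", {
  withr::with_seed(201, {
    por <- matrix(runif(30 * 30, 0.2, 1), 30)
    por[sample.int(900, 60)] <- 0
    por[15, 15] <- 1
    p <- make_por(por, pixel_size = 0.08)
    f <- simulate_tracer(p, data.frame(row = 15, col = 15),
                         sim_config(duration = 2, source_duration = 0.4))
    after <- f$mass[f$times > 0.4]
    expect_lt(max(abs(diff(after))) / after[1], 1e-12)
    # before release the source keeps injecting: mass non-decreasing
    before <- f$mass[f$times <= 0.4]
    expect_true(all(diff(before) >= -1e-12))
  })
})

test_that("arrival contours agree with map bands in the uniform limit", {
  p <- make_por(matrix(1, 31, 31), pixel_size = 0.1)
  m <- weighted_geodesic_map(p, c(16, 16))
  f <- simulate_tracer(p, data.frame(row = 16, col = 16),
                       sim_config(D0 = 1, duration = 6))
  mutual <- m$reachable & is.finite(f$arrival)
  rho <- cor(m$cost[mutual], f$arrival[mutual], method = "spearman")
  expect_gt(rho, 0.97)
})

test_that("refining the grid changes arrival times by a bounded, shrinking amount", {
  probe <- function(h) {
    n <- as.integer(round(2.4 / h))           # fixed 2.4 mm square domain
    p <- make_por(matrix(1, n, n), pixel_size = h)
    f <- simulate_tracer(p, data.frame(row = 1, col = 1),
                         sim_config(D0 = 1, duration = 4))
    # arrival at the physical centre and far corner
    c(f$arrival[round(n / 2), round(n / 2)], f$arrival[n, n])
  }
  a1 <- probe(0.2); a2 <- probe(0.1); a3 <- probe(0.05)
  d12 <- max(abs(a1 - a2)); d23 <- max(abs(a2 - a3))
  expect_lt(d23, d12)
  expect_lt(d23 / max(a3), 0.2)
})

test_that("comparison report responds to monotone transforms of cost", {
  p <- make_por(matrix(1, 15, 15), pixel_size = 0.2)
  m <- weighted_geodesic_map(p, c(8, 8))
  fake <- function(arr) {
    structure(list(arrival = arr, final_concentration = arr * 0,
                   mass = 0, times = 0, config = sim_config(),
                   inlets = data.frame(row = 8, col = 8), pixel_size = 0.2),
              class = "arrival_field")
  }
  up <- compare_map_to_sim(m, fake(sqrt(m$cost) + 0.1 * m$cost))
  expect_equal(up$spearman, 1)
  down <- compare_map_to_sim(m, fake(exp(-m$cost)))
  expect_equal(down$spearman, -1)
  tiny <- fake(m$cost)
  tiny$arrival[] <- Inf; tiny$arrival[8, 8] <- 0
  expect_error(compare_map_to_sim(m, tiny), "fewer than 10")
})
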