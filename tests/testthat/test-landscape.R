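test_that("snapshots recover initial conditions and stationary means", {
  net <- birth_death_net(10, 1)
  ens <- ssa(net, c(X = 0), t_final = 60, times = seq(0, 60, by = 1),
             method = "direct", n_samples = 60, seed = 120)
  expect_true(all(ensemble_snapshot(ens, 0) == 0))
  late <- pool_snapshots(ens, c(40, 50, 60))
  expect_lt(abs(mean(late) - 10), 1)   # Poisson(alpha/d) mean

  frozen <- ssa(frozen_net(4), t_final = 5, times = c(0, 5),
                method = "direct", n_samples = 5, seed = 1)
  snap <- ensemble_snapshot(frozen, 5)
  expect_true(all(snap == 4))
})

test_that("uniform samples give a flat potential", {
  set.seed(5)
  xy <- cbind(A = runif(1e5), B = runif(1e5))
  g <- estimate_landscape(xy, c("A", "B"), n_bins = 10)
  expect_equal(sum(g$P), 1)
  expect_lt(max(g$U) - min(g$U), 0.5)
})

test_that("two separated clusters give exactly two interior minima", {
  set.seed(6)
  n <- 5000
  xy <- rbind(cbind(rnorm(n, 25, 6), rnorm(n, 25, 6)),
              cbind(rnorm(n, 75, 6), rnorm(n, 75, 6)))
  colnames(xy) <- c("A", "B")
  g <- estimate_landscape(xy, c("A", "B"), n_bins = 10,
                          ranges = list(c(0, 100), c(0, 100)))
  m <- landscape_minima(g)
  expect_equal(nrow(m), 2L)
  # the minima sit at the cluster centers, deepest first ordering holds
  expect_true(all(abs(sort(m$x) - c(25, 75)) < 10))
  expect_true(all(diff(m$U) >= 0))
})

test_that("potential is a monotone relabeling of frequency", {
  set.seed(7)
  xy <- cbind(A = rnorm(4000, 50, 15), B = rnorm(4000, 50, 15))
  g <- estimate_landscape(xy, c("A", "B"), n_bins = 12,
                          ranges = list(c(0, 100), c(0, 100)))
  expect_equal(rank(g$U), rank(-g$P))
  expect_equal(which.min(g$U), which.max(g$P))
  expect_true(all(is.finite(g$U)))
})

test_that("degenerate axes collapse to a single bin with a warning", {
  xy <- cbind(A = rep(3, 50), B = rnorm(50))
  expect_warning(g <- estimate_landscape(xy, c("A", "B"), n_bins = 5),
                 "zero range")
  expect_equal(nrow(g$P), 1L)
  expect_equal(sum(g$P), 1)
})

test_that("landscape grids export as TSV", {
  set.seed(8)
  xy <- cbind(F = rnorm(500, 10, 2), S = rnorm(500, 5, 1))
  g <- estimate_landscape(xy, c("F", "S"), n_bins = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(g, path)
  df <- read.delim(path)
  expect_equal(nrow(df), 36L)
  expect_named(df, c("F", "S", "P", "U"))
  expect_equal(sum(df$P), 1)
})

test_that("attractor counting finds the toggle's two states, seed-stably", {
  rhs <- function(t, y, parms) {
    list(c(50 / (1 + (y[2] / 20)^2) - y[1],
           50 / (1 + (y[1] / 20)^2) - y[2]))
  }
  box <- list(lower = c(0, 0), upper = c(60, 60))
  r1 <- count_attractors(rhs, n_starts = 30, init_box = box, t_long = 200,
                         merge_radius = 5, seed = 1)
  r2 <- count_attractors(rhs, n_starts = 30, init_box = box, t_long = 200,
                         merge_radius = 5, seed = 2)
  expect_equal(nrow(r1$attractors), 2L)
  expect_equal(nrow(r2$attractors), 2L)
  # same attractor set across seeds (up to ordering/basin counts)
  a1 <- r1$attractors[order(r1$attractors[, 1]), ]
  a2 <- r2$attractors[order(r2$attractors[, 1]), ]
  expect_equal(a1, a2, tolerance = 0.05)
  expect_equal(sum(r1$basin_counts), r1$n_used)
})

test_that("attractor counting validates its inputs", {
  rhs <- function(t, y, parms) list(-y)
  expect_error(count_attractors(rhs, n_starts = 5,
                                init_box = list(lower = 0, upper = 1),
                                merge_radius = 0.1), "at least 10")
  expect_error(count_attractors(rhs, n_starts = 10,
                                init_box = list(lower = 0, upper = 1),
                                merge_radius = -1), "positive")
})
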