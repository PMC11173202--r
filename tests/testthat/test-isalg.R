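single_edge_rates <- function(omega = 0.5) {
  contagion_rates(tibble::tibble(from = "i", to = "j", omega = omega))
}

test_that("the single-edge instance solves in closed form", {
  sc <- run_is(single_edge_rates())
  tb <- tidy(sc)
  expect_equal(tb$influence[tb$user_id == "i"], 0.5)
  expect_equal(tb$susceptibility[tb$user_id == "j"], 1.0)
  expect_equal(tb$influence[tb$user_id == "j"], 0)
  expect_equal(tb$susceptibility[tb$user_id == "i"], 0)
  expect_equal(fixed_point_residual(single_edge_rates(), sc), 0)
  expect_true(glance(sc)$converged)
})

test_that("the simultaneous (jacobi) scheme 2-cycles on a single edge", {
  expect_warning(
    sc <- run_is(single_edge_rates(), scheme = "jacobi", max_iter = 200),
    "did not converge"
  )
  expect_false(glance(sc)$converged)
  # the alternating scheme converges from the same data
  expect_true(glance(run_is(single_edge_rates()))$converged)
})

test_that("hand residuals match: all-ones scores on a single 0.5 edge", {
  sc <- spreadis:::new_is_scores(
    tibble::tibble(user_id = c("i", "j"), influence = c(1, 0),
                   susceptibility = c(0, 1)),
    meta = list(scheme = "manual", iterations = 0L, converged = NA,
                residual = NA_real_)
  )
  # I = 1 but f/(A S) = 0.5: both equations violated by 50%
  expect_equal(fixed_point_residual(single_edge_rates(), sc), 0.5)
})

test_that("residual is gauge-invariant", {
  for (s in 1:5) {
    rates <- random_rates(6, p = 0.4, seed = s)
    sc <- run_is(rates, max_iter = 20, quiet = TRUE)
    base <- fixed_point_residual(rates, sc)
    for (c_ in c(0.2, 5)) {
      sc2 <- sc
      sc2$scores$influence <- sc2$scores$influence * c_
      sc2$scores$susceptibility <- sc2$scores$susceptibility / c_
      expect_lt(abs(fixed_point_residual(rates, sc2) - base), 1e-12)
    }
  }
})

test_that("zero-rate nodes are pinned at zero and others stay positive", {
  for (s in 1:10) {
    rates <- random_rates(12, p = 0.25, seed = 100 + s)
    sc <- tidy(run_is(rates, quiet = TRUE))
    nodes <- tidy(rates)
    expect_identical(sc$influence == 0, nodes$f_hat == 0)
    expect_identical(sc$susceptibility == 0, nodes$g_hat == 0)
    expect_true(all(is.finite(sc$influence) & is.finite(sc$susceptibility)))
  }
})

test_that("gauge normalization rescales to unit-mean influence and is idempotent", {
  rates <- contagion_rates(tibble::tibble(
    from = c("a", "b"), to = c("c", "c"), omega = c(0.4, 0.8)
  ))
  sc <- run_is(rates)
  sc$scores$influence <- c(2, 4, 0)[match(sc$scores$user_id, c("a", "b", "c"))]
  sc$scores$susceptibility <- c(0, 0, 0.5)[match(sc$scores$user_id, c("a", "b", "c"))]
  norm <- gauge_normalize(sc)
  tb <- tidy(norm)
  expect_equal(tb$influence[tb$user_id == "a"], 2 / 3)
  expect_equal(tb$influence[tb$user_id == "b"], 4 / 3)
  expect_equal(tb$susceptibility[tb$user_id == "c"], 1.5)
  expect_equal(tidy(gauge_normalize(norm)), tb)
  # edge products and rankings unchanged
  expect_equal(edge_products(norm, rates$edges), edge_products(sc, rates$edges))
  expect_equal(rank(tb$influence), rank(sc$scores$influence))
})

test_that("initial-condition scaling acts as a pure gauge transformation", {
  rates <- random_rates(10, p = 0.3, seed = 77)
  base_j <- run_is(rates, scheme = "jacobi", max_iter = 60, quiet = TRUE)
  base_a <- gauge_normalize(run_is(rates))
  for (c_ in c(0.1, 10)) {
    scaled <- run_is(rates, scheme = "jacobi", max_iter = 60,
                     init_influence = c_, init_susceptibility = 1 / c_,
                     quiet = TRUE)
    expect_equal(scaled$scores$influence, base_j$scores$influence * c_,
                 tolerance = 1e-12)
    expect_equal(scaled$scores$susceptibility,
                 base_j$scores$susceptibility / c_, tolerance = 1e-12)
    # alternating scheme: same normalized output regardless of the init scale
    alt <- gauge_normalize(run_is(rates, init_influence = c_,
                                  init_susceptibility = c_))
    expect_equal(alt$scores$influence, base_a$scores$influence,
                 tolerance = 1e-10)
    expect_equal(alt$scores$susceptibility, base_a$scores$susceptibility,
                 tolerance = 1e-10)
  }
})

test_that("the brute-force oracle solves pinned instances", {
  # single edge: pinning I_i = 0.5 forces S_j = omega / 0.5 = 1
  bf <- brute_force_fixed_point(single_edge_rates(), pin = "i",
                                pin_value = 0.5, seed = 1)
  tb <- tidy(bf)
  expect_equal(tb$susceptibility[tb$user_id == "j"], 1.0, tolerance = 1e-7)

  # two disjoint edges: each component is pinned at its lowest active node
  rates2 <- contagion_rates(tibble::tibble(
    from = c("a", "c"), to = c("b", "d"), omega = c(0.3, 0.6)
  ))
  bf2 <- brute_force_fixed_point(rates2, seed = 2)
  tb2 <- tidy(bf2)
  expect_equal(tb2$influence[tb2$user_id %in% c("a", "c")], c(1, 1),
               tolerance = 1e-7)
  expect_equal(tb2$susceptibility[tb2$user_id == "b"], 0.3, tolerance = 1e-7)
  expect_equal(tb2$susceptibility[tb2$user_id == "d"], 0.6, tolerance = 1e-7)

  expect_error(brute_force_fixed_point(random_rates(20, seed = 1)),
               "limited to")
})

test_that("iteration and oracle agree on random small instances (edge products)", {
  for (s in 1:10) {
    n <- sample(3:5, 1)
    rates <- random_connected_rates(n, seed = 400 + s)
    it <- run_is(rates, tol = 1e-10)
    bf <- brute_force_fixed_point(rates, seed = s)
    expect_lt(max(abs(edge_products(it, rates$edges) -
                      edge_products(bf, rates$edges))), 1e-6)
  }
})

test_that("sources firing into busier targets score lower influence", {
  # Two sources with identical per-edge rates and out-degree 3, but B's
  # targets also receive events from a third party (they are genuinely more
  # susceptible: ground truth S_b = 0.4 vs S_a = 0.2), so B needs only half
  # of A's influence to generate the same outgoing rate. Rates below are the
  # exact products of ground truth I = (A: 1, B: 0.5, x: 0.75, z: 0.5).
  edges <- tibble::tibble(
    from = c(rep("A", 3), rep("B", 3), rep("x", 3), "z", "z"),
    to = c("a1", "a2", "a3", "b1", "b2", "b3", "b1", "b2", "b3", "a1", "b1"),
    omega = c(rep(0.2, 6), rep(0.3, 3), 0.1, 0.2)
  )
  rates <- contagion_rates(edges)
  sc <- tidy(run_is(rates, tol = 1e-12))
  I_A <- sc$influence[sc$user_id == "A"]
  I_B <- sc$influence[sc$user_id == "B"]
  expect_gt(I_A, I_B)
  expect_equal(I_A / I_B, 2, tolerance = 1e-6)
  # cross-check with the independent oracle
  bf <- tidy(brute_force_fixed_point(rates, seed = 3, max_nodes = 12))
  expect_equal(bf$influence[bf$user_id == "A"] /
                 bf$influence[bf$user_id == "B"], 2, tolerance = 1e-6)
})

test_that("influence responds monotonically to stronger outgoing rates", {
  star <- function(w) {
    contagion_rates(tibble::tibble(
      from = c("hub", "hub", "hub", "u", "v"),
      to = c("l1", "l2", "l3", "l1", "l2"),
      omega = c(w, w, w, 0.2, 0.2)
    ))
  }
  lo <- tidy(gauge_normalize(run_is(star(0.2))))
  hi <- tidy(gauge_normalize(run_is(star(0.4))))
  expect_gte(hi$influence[hi$user_id == "hub"] /
               hi$influence[hi$user_id == "u"],
             lo$influence[lo$user_id == "hub"] /
               lo$influence[lo$user_id == "u"])
})

test_that("the alternating scheme converges across random ER instances", {
  fails <- 0L
  for (s in 1:20) {
    net <- generate_network(100, mean_degree = 6, seed = 500 + s)
    traits <- generate_traits(network_nodes(net), seed = 600 + s)
    log <- simulate_cascades(net, traits, 150, seed = 700 + s)
    rates <- estimate_contagion_rates(log)
    sc <- run_is(rates, tol = 1e-10, quiet = TRUE)
    if (!glance(sc)$converged || glance(sc)$residual >= 1e-8) fails <- fails + 1L
  }
  expect_lte(fails, 1L)
})

test_that("degenerate inputs raise errors", {
  empty <- contagion_rates(tibble::tibble(from = character(),
                                          to = character(),
                                          omega = numeric()),
                           nodes = c("a", "b"))
  expect_error(run_is(empty), "empty network")
  expect_error(run_is(single_edge_rates(), damping = 1), "damping")
  expect_error(run_is(single_edge_rates(), init_influence = 0), "positive")
})
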