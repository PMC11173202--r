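test_that("centralities are exact on symmetric toy graphs", {
  cyc <- diffusion_network(tibble::tibble(from = c("a", "b", "c"),
                                          to = c("b", "c", "a")))
  ce <- centralities(cyc)
  expect_true(all(ce$k_in == 1) && all(ce$k_out == 1))
  expect_equal(ce$pagerank, rep(1 / 3, 3))
  expect_true(all(ce$kcore == 2))

  star <- diffusion_network(tibble::tibble(from = "r", to = paste0("l", 1:5)))
  cs <- centralities(star)
  expect_equal(cs$k_out[cs$user_id == "r"], 5L)
  expect_true(all(cs$k_in[cs$user_id != "r"] == 1L))
  expect_true(all(cs$kcore == 1L))

  net <- generate_network(200, mean_degree = 5, seed = 61)
  cn <- centralities(net)
  expect_equal(sum(cn$pagerank), 1, tolerance = 1e-10)
  expect_equal(sum(cn$k_out), nrow(net))
})

test_that("node correlations follow the nonzero-pair convention", {
  scores <- spreadis:::new_is_scores(
    tibble::tibble(user_id = paste0("u", 1:8),
                   influence = c(1, 2, 3, 4, 5, 6, 7, 8),
                   susceptibility = c(8, 7, 6, 5, 4, 3, 2, 1)),
    meta = list(scheme = "manual", iterations = 0L, converged = TRUE,
                residual = 0)
  )
  cents <- tibble::tibble(user_id = paste0("u", 1:8),
                          k_in = rep(1L, 8), k_out = 1:8,
                          pagerank = rep(1 / 8, 8), kcore = rep(1L, 8))
  nc <- node_correlations(scores, cents)
  expect_equal(nc$rho[nc$var1 == "k_out" & nc$var2 == "influence"], 1)
  expect_equal(nc$rho[nc$var1 == "influence" & nc$var2 == "susceptibility"], -1)
  # degenerate variable: rho undefined, reported NA (never 0)
  expect_true(is.na(nc$rho[nc$var1 == "k_in" & nc$var2 == "k_out"]))
  expect_equal(nc$n_pairs[nc$var1 == "k_in" & nc$var2 == "influence"], 8L)
})

test_that("neighbor averages and assortativity match direct enumeration", {
  pair <- diffusion_network(tibble::tibble(from = "i", to = "j"))
  scores <- spreadis:::new_is_scores(
    tibble::tibble(user_id = c("i", "j"), influence = c(0.7, 0),
                   susceptibility = c(0, 0.4)),
    meta = list(scheme = "manual", iterations = 0L, converged = TRUE,
                residual = 0)
  )
  na <- neighbor_averages(pair, scores)
  expect_equal(na$S_nn_out[na$user_id == "i"], 0.4)
  expect_equal(na$I_nn_in[na$user_id == "j"], 0.7)
  expect_true(is.na(na$I_nn_in[na$user_id == "i"]))

  # 6-node instance checked against brute-force rank-then-Pearson
  set.seed(71)
  edges <- tibble::tibble(
    from = c("a", "a", "b", "b", "c", "d", "e", "f"),
    to = c("b", "c", "c", "d", "e", "e", "f", "a")
  )
  net <- diffusion_network(edges)
  sc <- spreadis:::new_is_scores(
    tibble::tibble(user_id = sort(unique(c(edges$from, edges$to))),
                   influence = runif(6, 0.1, 1),
                   susceptibility = runif(6, 0.1, 1)),
    meta = list(scheme = "manual", iterations = 0L, converged = TRUE,
                residual = 0)
  )
  asst <- neighbor_assortativity(net, sc)
  tbl <- spreadis:::node_table(net, sc)
  expect_equal(asst$rho[asst$statistic == "rho_susceptibility_Inn_in"],
               spearman_brute(tbl$susceptibility, tbl$I_nn_in))
  expect_equal(asst$rho[asst$statistic == "rho_influence_Snn_out"],
               spearman_brute(tbl$influence, tbl$S_nn_out))
})

test_that("double-edge swaps preserve every degree and the outgoing rates", {
  rates <- benchmark_planted_assortativity(n = 60, seed = 81)
  net0 <- diffusion_network(rates$edges[c("from", "to")],
                            nodes = rates$nodes$user_id)
  deg0 <- centralities(net0)[c("user_id", "k_in", "k_out")]
  for (s in 1:5) {
    rw <- rewire_rates(rates, seed = 80 + s)
    net1 <- diffusion_network(rw$rates$edges[c("from", "to")],
                              nodes = rw$rates$nodes$user_id)
    deg1 <- centralities(net1)[c("user_id", "k_in", "k_out")]
    expect_identical(deg1, deg0)
    # rate mass carried with source stubs: f_hat exactly preserved
    expect_equal(tidy(rw$rates)$f_hat, tidy(rates)$f_hat)
    expect_gt(rw$n_swaps_done, 0)
  }
})

test_that("the null p-value is 1 for an invariant statistic and small for a planted one", {
  rates <- benchmark_planted_assortativity(n = 80, k_out = 4, seed = 91)
  # a statistic the rewiring preserves by construction: the degree total
  const <- randomized_null(rates, function(tbl) sum(tbl$k_out),
                           n_reps = 20, seed = 92)
  expect_equal(const$p_value, 1)

  planted <- randomized_null(rates, "rho_influence_Snn_out", n_reps = 49,
                             seed = 93)
  expect_lte(planted$p_value, 0.05)
  expect_gt(planted$observed, max(abs(planted$null)))
})

test_that("stylized-fact statistics behave at their logical extremes", {
  # perfectly anticorrelated scores: no top-decile overlap
  n <- 100
  sc <- spreadis:::new_is_scores(
    tibble::tibble(user_id = sprintf("u%03d", 1:n),
                   influence = seq(0.01, 1, length.out = n),
                   susceptibility = seq(1, 0.01, length.out = n)),
    meta = list(scheme = "manual", iterations = 0L, converged = TRUE,
                residual = 0)
  )
  net <- diffusion_network(
    tibble::tibble(from = sprintf("u%03d", 1:99), to = sprintf("u%03d", 2:100)),
    nodes = sprintf("u%03d", 1:n)
  )
  sf <- stylized_facts(sc, net)
  expect_equal(sf$value[sf$fact == "i"], 0)
  expect_equal(sf$baseline[sf$fact == "i"], 0.01)

  # independent random scores: overlap near q^2
  set.seed(101)
  n2 <- 2000
  sc2 <- spreadis:::new_is_scores(
    tibble::tibble(user_id = sprintf("v%04d", 1:n2),
                   influence = runif(n2), susceptibility = runif(n2)),
    meta = list(scheme = "manual", iterations = 0L, converged = TRUE,
                residual = 0)
  )
  net2 <- diffusion_network(
    tibble::tibble(from = sprintf("v%04d", 1:(n2 - 1)),
                   to = sprintf("v%04d", 2:n2)),
    nodes = sprintf("v%04d", 1:n2)
  )
  sf2 <- stylized_facts(sc2, net2)
  expect_lt(abs(sf2$value[sf2$fact == "i"] - 0.01), 0.008)

  # planted influencer clustering: top influencers chained together
  infl <- c(seq(0.9, 0.8, length.out = 10), runif(90, 0.05, 0.5))
  sc3 <- spreadis:::new_is_scores(
    tibble::tibble(user_id = sprintf("w%03d", 1:100),
                   influence = infl, susceptibility = runif(100, 0.1, 0.9)),
    meta = list(scheme = "manual", iterations = 0L, converged = TRUE,
                residual = 0)
  )
  # edges mostly among the top-10 influencers
  net3 <- diffusion_network(dplyr::bind_rows(
    tibble::tibble(from = sprintf("w%03d", 1:9), to = sprintf("w%03d", 2:10)),
    tibble::tibble(from = sprintf("w%03d", 10:98), to = sprintf("w%03d", 12:100))
  ), nodes = sprintf("w%03d", 1:100))
  sf3 <- stylized_facts(sc3, net3)
  expect_gt(sf3$value[sf3$fact == "iv"], sf3$baseline[sf3$fact == "iv"])
})
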