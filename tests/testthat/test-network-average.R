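test_that("bootstrap strengths are frequencies and detect strong relations", {
  withr::with_seed(51, {
    x <- rnorm(200)
    d <- data.frame(x = x, y = 1.5 * x + rnorm(200, sd = 0.2), z = rnorm(200))
    ar <- bootstrap_arcs(d, n_boot = 50, seed = 3)
    expect_true(all(ar$strength >= 0 & ar$strength <= 1))
    expect_true(all(ar$direction_probability >= 0 & ar$direction_probability <= 1))
    xy <- ar[(ar$from == "x" & ar$to == "y") | (ar$from == "y" & ar$to == "x"), ]
    expect_gte(xy$strength, 0.95)
  })
  expect_error(bootstrap_arcs(data.frame(a = 1:10), n_boot = 0), "at least 1")
})

test_that("pure-noise pairs have low strength at large n", {
  withr::with_seed(52, {
    d <- as.data.frame(matrix(rnorm(800 * 3), 800, 3))
    colnames(d) <- c("a", "b", "c")
    ar <- bootstrap_arcs(d, n_boot = 40, seed = 5)
    if (nrow(ar)) expect_lte(max(ar$strength), 0.5)
  })
})

test_that("bootstrap averaging is reproducible given a seed", {
  withr::with_seed(53, {
    dag <- random_dag(6, edge_prob = 0.3)
    d <- simulate_sem(dag, 150)
    a1 <- bootstrap_arcs(d, n_boot = 25, seed = 7)
    a2 <- bootstrap_arcs(d, n_boot = 25, seed = 7)
    expect_identical(as.data.frame(a1), as.data.frame(a2))
  })
})

test_that("thresholding retains only strong arcs and keeps boundaries", {
  fake <- tibble::tibble(
    from = c("a", "b"), to = c("b", "c"),
    strength = c(0.9, 0.3), direction_probability = c(1, 1)
  )
  attr(fake, "nodes") <- c("a", "b", "c")
  class(fake) <- c("hen_arc_strength", class(fake))
  net <- threshold_network(fake, 0.6)
  expect_identical(nrow(net$arcs), 1L)
  expect_identical(net$arcs$from, "a")
  all_in <- threshold_network(fake, 0)
  expect_identical(nrow(all_in$arcs), 2L)
  none <- threshold_network(fake, 1)
  expect_identical(nrow(none$arcs), 0L)
  expect_identical(glance(none)$n_edges, 0L)
})

test_that("residual cycles are broken by dropping the weakest arc", {
  fake <- tibble::tibble(
    from = c("a", "b", "c"), to = c("b", "c", "a"),
    strength = c(0.9, 0.8, 0.7), direction_probability = 1
  )
  attr(fake, "nodes") <- c("a", "b", "c")
  class(fake) <- c("hen_arc_strength", class(fake))
  net <- threshold_network(fake, 0.5)
  expect_identical(nrow(net$arcs), 2L)
  expect_false(any(net$arcs$from == "c" & net$arcs$to == "a"))
  expect_identical(net$n_cycle_arcs_dropped, 1L)
})

test_that("markov blankets cover parents, children and co-parents", {
  mk_net <- function(arcs, nodes) {
    amat <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    amat[as.matrix(arcs)] <- TRUE
    structure(list(nodes = nodes, amat = amat, arcs = tibble::tibble(
      from = arcs[, 1], to = arcs[, 2]
    )), class = "hen_network")
  }
  chain <- mk_net(cbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_identical(markov_blanket(chain, "B"), c("A", "C"))
  collider <- mk_net(cbind(c("A", "B"), c("C", "C")), c("A", "B", "C"))
  expect_identical(markov_blanket(collider, "A"), c("B", "C"))
  iso <- mk_net(cbind(character(), character()), c("A", "B"))
  expect_identical(markov_blanket(iso, "A"), character(0))
  expect_error(markov_blanket(chain, "Z"), "unknown node")

  # summary semantics: chain A->B->C has blankets of sizes 1, 2, 1
  g <- glance(chain)
  expect_identical(g$n_nodes, 3L)
  expect_identical(g$n_edges, 2L)
  expect_equal(g$mean_markov_blanket_size, 4 / 3)
})

test_that("local models recover generating coefficients and match normal equations", {
  withr::with_seed(54, {
    x <- rnorm(300)
    y <- 3 * x + rnorm(300)
    d <- data.frame(x = x, y = y)
    dag <- hill_climb(d)
    fits <- fit_local_models(dag, d)
    fy <- fits[fits$node == "y" & fits$term == "x", ]
    expect_lt(abs(fy$estimate - 3), 3 * fy$std_error)

    # independent solver: normal equations by hand
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(unname(fy$estimate), unname(beta[2, 1]), tolerance = 1e-9)

    # parentless node: intercept equals the sample mean
    fx <- fits[fits$node == "x" & fits$term == "(Intercept)", ]
    expect_equal(unname(fx$estimate), mean(x), tolerance = 1e-12)
  })
})

test_that("dot serialisation lists every node and arc", {
  withr::with_seed(55, {
    d <- data.frame(x = rnorm(100), y = rnorm(100))
    dag <- hill_climb(d)
    tmp <- withr::local_tempfile(fileext = ".dot")
    write_dot(dag, tmp)
    txt <- readLines(tmp)
    expect_identical(txt[1], "digraph hennet {")
    expect_true(any(grepl("\"x\"", txt)))
  })
})
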