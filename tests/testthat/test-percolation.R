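fig1_nets <- function() {
  list(net1 = ppi_network(rbind(c("u1", "i1"), c("u1", "j1"), c("u1", "v1"))),
       net2 = ppi_network(rbind(c("u2", "i2"), c("u2", "j2"))))
}

test_that("couple score counts matched common neighbours", {
  f <- fig1_nets()
  aln <- make_alignment(c("i1", "j1"), c("i2", "j2"))
  expect_equal(couple_score("u1", "u2", aln, f$net1, f$net2), 2L)
  expect_equal(couple_score("v1", "u2", aln, f$net1, f$net2), 0L)
  expect_equal(couple_score("u1", "u2", make_alignment(), f$net1, f$net2), 0L)

  tri1 <- triangle(); tri2 <- triangle(c("x", "y", "z"))
  aln <- make_alignment(c("a", "b"), c("x", "y"))
  expect_equal(couple_score("c", "z", aln, tri1, tri2), 2L)
  expect_error(couple_score("nope", "z", aln, tri1, tri2), "unknown protein")
})

test_that("percolation walks along a path from a single seed", {
  g <- path_net(c("a", "b", "c"))
  h <- path_net(c("x", "y", "z"))
  aln <- map_percolation(g, h, make_alignment("a", "x"), r = 1)
  expect_equal(aln$protein1, c("a", "b", "c"))
  expect_equal(aln$protein2, c("x", "y", "z"))
  expect_equal(aln$origin, c("seed", "percolated", "percolated"))
  expect_equal(aln$match_score, c(NA_integer_, 1L, 1L))
})

test_that("no seeds means nothing percolates, and r gates low degrees", {
  g <- path_net(c("a", "b", "c"))
  h <- path_net(c("x", "y", "z"))
  expect_equal(nrow(map_percolation(g, h, make_alignment(), r = 1)), 0L)

  s1 <- star_net("c1", c("l1", "l2", "l3"))
  s2 <- star_net("c2", c("m1", "m2", "m3"))
  aln <- map_percolation(s1, s2, make_alignment("c1", "c2"), r = 2)
  expect_equal(nrow(aln), 1L)  # leaves have degree 1 < r
  aln1 <- map_percolation(s1, s2, make_alignment("c1", "c2"), r = 1)
  expect_equal(nrow(aln1), 4L)
})

test_that("runs are deterministic for a fixed RNG state", {
  set.seed(3); inst <- random_instance()
  set.seed(17); a <- map_percolation(inst$net1, inst$net2, inst$seeds, r = 1)
  set.seed(17); b <- map_percolation(inst$net1, inst$net2, inst$seeds, r = 1)
  expect_identical(a, b)
})

test_that("output contains the seeds, stays injective, respects r", {
  set.seed(21)
  for (k in 1:15) {
    inst <- random_instance()
    aln <- map_percolation(inst$net1, inst$net2, inst$seeds, r = inst$r)
    expect_true(all(inst$seeds$protein1 %in% aln$protein1))
    expect_equal(anyDuplicated(aln$protein1), 0L)
    expect_equal(anyDuplicated(aln$protein2), 0L)
    perc <- aln[aln$origin == "percolated", ]
    expect_true(all(perc$match_score >= inst$r))
    expect_true(check_termination(inst$net1, inst$net2, aln, inst$r))
  }
})

test_that("heap engine matches the full-rescan oracle couple for couple", {
  set.seed(123)
  for (k in 1:40) {
    inst <- random_instance()
    rs <- sample.int(10000, 1)
    set.seed(rs)
    got <- map_percolation(inst$net1, inst$net2, inst$seeds, r = inst$r)
    set.seed(rs)
    want <- naive_percolation(inst$net1, inst$net2, inst$seeds, r = inst$r)
    expect_identical(got, want)
    set.seed(k + 50000)  # fresh stream for the next instance draw
  }
})

test_that("self-alignment is recovered from one seed on a distinctive graph", {
  # connected graph with nearly all degrees distinct
  g <- ppi_network(rbind(
    c("a", "b"), c("a", "c"), c("a", "d"), c("a", "e"), c("a", "f"),
    c("b", "c"), c("b", "d"), c("b", "e"),
    c("c", "d"), c("d", "f")))
  set.seed(2)
  aln <- map_percolation(g, g, make_alignment("a", "a"), r = 1)
  expect_equal(nrow(aln), n_nodes(g))
  expect_equal(aln$protein1, aln$protein2)
})

test_that("seed couples outside the networks warn and cannot percolate", {
  g <- path_net(c("a", "b"))
  h <- path_net(c("x", "y"))
  seeds <- make_alignment(c("a", "ghost"), c("x", "y"))
  expect_warning(aln <- map_percolation(g, h, seeds, r = 1), "absent")
  expect_true(all(c("a", "ghost") %in% aln$protein1))
  # y is consumed by the half-present seed, so b cannot take it
  expect_false("b" %in% aln$protein1)
})

test_that("runtime grows near-linearly with edge count on sparse graphs", {
  set.seed(8)
  g1 <- erdos_renyi(500, 10 / 500)
  g2 <- erdos_renyi(2000, 10 / 2000)
  seed_of <- function(g) {
    hub <- g$nodes[which.max(net_degree(g))]
    make_alignment(hub, hub)
  }
  t1 <- system.time(map_percolation(g1, g1, seed_of(g1), r = 1))[["elapsed"]]
  t2 <- system.time(map_percolation(g2, g2, seed_of(g2), r = 1))[["elapsed"]]
  # 4x the edges should cost far less than the ~16x of a quadratic scan
  expect_lt(t2, max(8 * t1, 0.5))
})
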