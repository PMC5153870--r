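test_that("node correctness and precision count correct couples", {
  truth <- c(a = "w", b = "x", c = "y", d = "z")
  full <- make_alignment(names(truth), unname(truth))
  expect_equal(node_correctness(full, truth, 4), 1)
  expect_equal(alignment_precision(full, truth), 1)

  part <- make_alignment(c("a", "b", "c"), c("w", "x", "z"))  # 2 right, 1 wrong
  expect_equal(node_correctness(part, truth, 4), 0.5)
  expect_equal(alignment_precision(part, truth), 2 / 3)

  wrong <- make_alignment(c("a", "b"), c("x", "w"))
  expect_equal(alignment_precision(wrong, truth), 0)
  expect_equal(node_correctness(make_alignment(), truth, 4), 0)
  expect_true(is.na(alignment_precision(make_alignment(), truth)))
  expect_error(node_correctness(full, truth, 0), "positive")
})

test_that("conserved interactions, EC, ICS and S3 match hand counts", {
  tri1 <- triangle(); tri2 <- triangle(c("x", "y", "z"))
  idal <- make_alignment(c("a", "b", "c"), c("x", "y", "z"))
  expect_equal(conserved_interactions(idal, tri1, tri2), 3L)
  expect_equal(edge_correctness(idal, tri1, tri2), 1)
  expect_equal(induced_conserved_structure(idal, tri1, tri2), 1)
  expect_equal(symmetric_substructure(idal, tri1, tri2), 1)

  # triangle into path: two of three edges conserved
  p <- path_net(c("x", "y", "z"))
  expect_equal(conserved_interactions(idal, tri1, p), 2L)
  expect_equal(edge_correctness(idal, tri1, p), 2 / 3)

  # path into triangle: image induces all three triangle edges
  pp <- path_net(c("a", "b", "c"))
  expect_equal(conserved_interactions(idal, pp, tri2), 2L)
  expect_equal(induced_conserved_structure(idal, pp, tri2), 2 / 3)
  expect_equal(symmetric_substructure(idal, pp, tri2), 2 / (2 + 3 - 2))

  expect_equal(conserved_interactions(make_alignment(), tri1, tri2), 0L)
  expect_equal(edge_correctness(make_alignment(), tri1, tri2), 0)

  # zero denominators are NA, not zero
  edgeless <- ppi_network(nodes = c("a", "b"))
  sparse2 <- ppi_network(rbind(c("x", "y")), nodes = "z")
  expect_true(is.na(edge_correctness(idal[0, ], edgeless, tri2)))
  expect_true(is.na(induced_conserved_structure(
    make_alignment(c("a", "b"), c("x", "z")), edgeless, sparse2)))
})

test_that("S3 defines a disjoint-mapping penalty", {
  # two disjoint edges mapped onto an overlapping image: nothing conserved
  g1 <- ppi_network(rbind(c("a", "b"), c("c", "d")))
  g2 <- ppi_network(rbind(c("w", "x"), c("x", "y"), c("y", "z"), c("w", "z")))
  aln <- make_alignment(c("a", "b", "c", "d"), c("w", "y", "x", "z"))
  expect_equal(conserved_interactions(aln, g1, g2), 0L)
  expect_equal(symmetric_substructure(aln, g1, g2), 0)
})

test_that("LCSC finds the largest conserved component", {
  tri1 <- triangle()
  expect_equal(lcsc(identity_alignment(tri1), tri1, tri1),
               list(size = 3L, share = 1))

  # two conserved triangles + unaligned filler in a 10-node network
  edges <- rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                 c("d", "e"), c("e", "f"), c("d", "f"))
  g1 <- ppi_network(edges, nodes = c("g", "h", "i", "j"))
  g2 <- ppi_network(edges)
  aln <- make_alignment(c("a", "b", "c", "d", "e", "f"),
                        c("a", "b", "c", "d", "e", "f"))
  got <- lcsc(aln, g1, g2)
  expect_equal(got$size, 3L)
  expect_equal(got$share, 0.3)
  expect_equal(lcsc(make_alignment(), g1, g2)$size, 0L)
})

test_that("GO consistency is the Jaccard coefficient, summed over couples", {
  ann1 <- annotation_set(c("u", "u", "p"), c("A", "B", "A"),
                         c("IDA", "IEA", "IDA"))
  ann2 <- annotation_set(c("v", "v", "q"), c("B", "C", "A"),
                         c("IMP", "IEA", "IMP"))
  expect_equal(goc_couple("u", "v", ann1, ann2), 1 / 3)
  expect_equal(goc_couple("p", "q", ann1, ann2), 1)
  expect_equal(goc_couple("nobody", "nothing", ann1, ann2), 0)

  aln <- make_alignment(c("u", "p"), c("v", "q"))
  expect_equal(goc_total(aln, ann1, ann2), 1 / 3 + 1)
  expect_equal(goc_total(make_alignment(), ann1, ann2), 0)

  # experimental-evidence filter drops the IEA terms
  f <- experimental_evidence_codes
  expect_equal(goc_couple("u", "v", ann1, ann2, evidence_filter = f), 0)
  expect_equal(goc_total(aln, ann1, ann2, evidence_filter = f), 1)
})

test_that("ANBS normalizes cross-scores by geometric mean of self-scores", {
  ids <- c("p1", "p2", "p3", "p4")
  self <- stats::setNames(c(100, 400, 250, 900), ids)
  sim <- similarity_table(ids, ids, unname(self), self_scores = self)
  aln <- make_alignment(ids, ids)
  expect_equal(anbs(aln, sim, 4), 1)

  sim2 <- similarity_table(c("p1", "p2"), c("p1", "p2"), c(100, 400),
                           self_scores = self)
  expect_equal(anbs(aln, sim2, 4), 0.5)  # (1 + 1 + 0 + 0) / 4
  expect_equal(anbs(make_alignment(), sim, 4), 0)

  bad <- similarity_table("p1", "p2", 50,
                          self_scores = c(p1 = 100))
  expect_error(anbs(make_alignment("p1", "p2"), bad, 2), "p2")
})

test_that("measure identities hold on random alignments", {
  set.seed(77)
  for (k in 1:40) {
    g1 <- erdos_renyi(sample(5:12, 1), runif(1, 0.25, 0.7), prefix = "a")
    g2 <- erdos_renyi(sample(5:12, 1), runif(1, 0.25, 0.7), prefix = "b")
    aln <- random_alignment(g1, g2)
    ec <- edge_correctness(aln, g1, g2)
    ics <- induced_conserved_structure(aln, g1, g2)
    s3 <- symmetric_substructure(aln, g1, g2)
    if (!is.na(s3)) {
      expect_gte(s3, 0)
      if (!is.na(ec)) expect_lte(s3, ec + 1e-12)
      if (!is.na(ics)) expect_lte(s3, ics + 1e-12)
    }
    # conserved count is symmetric under swapping networks + inverting pi
    inv <- make_alignment(aln$protein2, aln$protein1)
    expect_identical(conserved_interactions(aln, g1, g2),
                     conserved_interactions(inv, g2, g1))
  }
})

test_that("identity self-alignment scores perfectly on every measure", {
  set.seed(5)
  g <- erdos_renyi(15, 0.3)
  aln <- identity_alignment(g)
  truth <- stats::setNames(g$nodes, g$nodes)
  rep <- evaluate_alignment(aln, g, g, truth = truth)
  expect_equal(rep$nc, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$ec, 1)
  expect_equal(rep$ics, 1)
  expect_equal(rep$s3, 1)
  expect_equal(rep$delta_pi, n_edges(g))
})

test_that("evaluation reorients so the smaller network is G1", {
  small <- path_net(c("x", "y"))
  big <- path_net(c("a", "b", "c"))
  aln <- make_alignment(c("a", "b"), c("x", "y"))  # big -> small as given
  rep <- evaluate_alignment(aln, big, small,
                            truth = c(a = "x", b = "y"))
  expect_true(rep$swapped)
  expect_equal(rep$nc, 1)          # both smaller-network nodes correct
  expect_equal(rep$ec, 1)          # the single small-network edge conserved
  expect_equal(rep$delta_pi, 1L)
})
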