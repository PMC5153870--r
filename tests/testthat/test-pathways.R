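# Fixture shaped after the worked toy example: a pathway with six proteins in
# species 1 and five in species 2, four of them correctly mapped, and five
# in-pathway interactions conserved under the alignment.
toy_pathway <- function() {
  pw <- list(sp1 = paste0("p", 1:6), sp2 = paste0("q", 1:5))
  net1 <- ppi_network(rbind(
    c("p1", "p2"), c("p2", "p3"), c("p3", "p4"), c("p1", "p3"),
    c("p1", "p4"), c("p5", "p6"), c("p4", "p5")),
    nodes = c("o1", "o2"))
  net2 <- ppi_network(rbind(
    c("q1", "q2"), c("q2", "q3"), c("q3", "q4"), c("q1", "q3"),
    c("q1", "q4"), c("q4", "q5")),
    nodes = "z1")
  # p1..p4 correctly into the pathway; p5 mapped outside it
  aln <- make_alignment(c("p1", "p2", "p3", "p4", "p5"),
                        c("q1", "q2", "q3", "q4", "z1"))
  list(pw = pw, net1 = net1, net2 = net2, aln = aln)
}

test_that("pathway accuracy is 2x correct over the two set sizes", {
  f <- toy_pathway()
  expect_equal(pathway_accuracy(f$aln, f$pw), 2 * 4 / (6 + 5))

  pw_eq <- list(sp1 = c("p1", "p2"), sp2 = c("q1", "q2"))
  expect_equal(pathway_accuracy(make_alignment(c("p1", "p2"), c("q2", "q1")),
                                pw_eq), 1)
  expect_equal(pathway_accuracy(make_alignment(), pw_eq), 0)
  expect_true(is.na(pathway_accuracy(f$aln,
                                     list(sp1 = character(),
                                          sp2 = character()))))
})

test_that("in-pathway conserved interactions are counted within both sets", {
  f <- toy_pathway()
  expect_equal(pathway_conserved(f$aln, f$net1, f$net2, f$pw), 5L)
  expect_equal(pathway_conserved(make_alignment(), f$net1, f$net2, f$pw), 0L)
  ghost <- list(sp1 = c("nope1", "nope2"), sp2 = c("nah1", "nah2"))
  expect_equal(pathway_conserved(f$aln, f$net1, f$net2, ghost), 0L)
})

test_that("pathway recall thresholds eligibility and success at delta", {
  # three eligible pathways, two with >= delta conserved interactions
  tri_ids <- function(p) paste0(p, 1:3)
  e3 <- function(p) rbind(c(paste0(p, 1), paste0(p, 2)),
                          c(paste0(p, 2), paste0(p, 3)),
                          c(paste0(p, 1), paste0(p, 3)))
  net1 <- ppi_network(rbind(e3("a"), e3("b"), e3("c")))
  net2 <- ppi_network(rbind(e3("x"), e3("y"), e3("z")))
  pwt <- pathway_table(
    pathway = rep(c("PW1", "PW2", "PW3"), each = 6),
    species = rep(rep(1:2, each = 3), 3),
    protein = c(tri_ids("a"), tri_ids("x"), tri_ids("b"), tri_ids("y"),
                tri_ids("c"), tri_ids("z")))
  # PW1, PW2 aligned perfectly; PW3 scrambled across pathways
  aln <- make_alignment(
    c(tri_ids("a"), tri_ids("b"), "c1"),
    c(tri_ids("x"), tri_ids("y"), "z1"))
  rep <- pathway_recall(aln, net1, net2, pwt, delta = 2)
  expect_equal(rep$n_eligible, 3L)
  expect_equal(rep$n_success, 2L)
  expect_equal(rep$recall, 2 / 3)
  expect_equal(rep$mean_acc_success, 1)

  # success count is non-increasing in delta
  succ <- vapply(1:4, function(d)
    pathway_recall(aln, net1, net2, pwt, delta = d)$n_success, integer(1))
  expect_true(all(diff(succ) <= 0))

  # identity self-alignment: every eligible pathway succeeds with accuracy 1
  self <- pathway_table(
    pathway = rep(c("PW1", "PW2"), each = 6),
    species = rep(rep(1:2, each = 3), 2),
    protein = c(tri_ids("a"), tri_ids("a"), tri_ids("b"), tri_ids("b")))
  idal <- identity_alignment(net1)
  srep <- pathway_recall(idal, net1, net1, self, delta = 3)
  expect_equal(srep$recall, 1)
  expect_true(all(srep$per_pathway$acc == 1))

  # empty alignment aligns nothing
  erep <- pathway_recall(make_alignment(), net1, net2, pwt, delta = 2)
  expect_equal(erep$recall, 0)
})

test_that("non-overlapping subset keeps pairwise-disjoint pathways", {
  pwt <- pathway_table(
    pathway = c("A", "A", "A", "A", "B", "B", "B", "B", "C", "C"),
    species = c(1, 1, 2, 2, 1, 1, 2, 2, 1, 2),
    protein = c("p1", "p2", "q1", "q2", "p3", "p4", "q3", "q4", "p5", "q5"))
  expect_equal(sort(names(nonoverlap_subset(pwt))), c("A", "B", "C"))

  overlapping <- pathway_table(
    pathway = c("A", "A", "B", "B"),
    species = c(1, 2, 1, 2),
    protein = c("p1", "q1", "p1", "q2"))  # share p1 on side 1
  kept <- nonoverlap_subset(overlapping)
  expect_equal(length(kept), 1L)
  expect_length(nonoverlap_subset(pathway_table()), 0)
})

test_that("pathways present in only one species are dropped on load", {
  expect_message(
    pwt <- pathway_table(pathway = c("A", "A", "B"),
                         species = c(1, 2, 1),
                         protein = c("p1", "q1", "p2")),
    "only one species")
  expect_equal(names(pwt), "A")
})
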