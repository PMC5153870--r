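# Small graph builders used across the tests.

triangle <- function(ids = c("a", "b", "c")) {
  ppi_network(rbind(ids[c(1, 2)], ids[c(2, 3)], ids[c(1, 3)]))
}

path_net <- function(ids) {
  ppi_network(cbind(ids[-length(ids)], ids[-1]))
}

star_net <- function(center, leaves) {
  ppi_network(cbind(center, leaves))
}

# identity alignment of a network onto a relabeled copy
identity_alignment <- function(net, map = NULL) {
  if (is.null(map)) map <- stats::setNames(net$nodes, net$nodes)
  make_alignment(names(map), unname(map))
}

# random instance for oracle-equivalence checks: two small ER networks and a
# random injective seed set over present nodes
random_instance <- function(max_nodes = 12) {
  n1 <- sample(4:max_nodes, 1)
  n2 <- sample(4:max_nodes, 1)
  g1 <- erdos_renyi(n1, stats::runif(1, 0.2, 0.6), prefix = "a")
  g2 <- erdos_renyi(n2, stats::runif(1, 0.2, 0.6), prefix = "b")
  k <- sample(1:3, 1)
  s1 <- sample(g1$nodes, k)
  s2 <- sample(g2$nodes, k)
  list(net1 = g1, net2 = g2, seeds = make_alignment(s1, s2),
       r = sample(1:2, 1))
}

# random (not necessarily sensible) injective alignment between two networks
random_alignment <- function(net1, net2, k = NULL) {
  kmax <- min(n_nodes(net1), n_nodes(net2))
  if (is.null(k)) k <- sample(0:kmax, 1)
  make_alignment(sample(net1$nodes, k), sample(net2$nodes, k))
}
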