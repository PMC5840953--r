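# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# Construct a weighted_network directly from an edge table. Root children are
# inferred from the edges leaving ROOT.
make_wnet <- function(edges, terminals, phenotype = "case", region = "test",
                      params = weight_params()) {
  edges <- tibble::as_tibble(edges)
  if (!"weight" %in% names(edges)) edges$weight <- 0.9
  if (!"sign" %in% names(edges)) edges$sign <- 1L
  edges$sign <- as.integer(edges$sign)
  edges$cost <- -log(edges$weight)
  edges$origin <- "fixture"
  structure(
    list(
      edges = edges[, c("source", "target", "sign", "weight", "cost", "origin")],
      root = root_node(),
      root_children = sort(unique(edges$target[edges$source == root_node()])),
      terminals = sort(terminals),
      phenotype = phenotype,
      region = region,
      params = params
    ),
    class = "weighted_network"
  )
}

# Random instance within the desk caps of both exact solver and brute-force
# oracle: <= 12 nodes (incl. ROOT), <= 18 edges, <= 3 terminals, all
# terminals reachable by construction (spanning in-edges from the root side).
random_wnet <- function(seed) {
  set.seed(seed)
  n_nodes <- sample(6:12, 1)
  genes <- sprintf("g%02d", seq_len(n_nodes - 1))
  terminals <- sample(genes, sample(1:3, 1))
  children <- sample(genes, sample(1:2, 1))

  two_weights <- function(n) sample(c(0.9, 0.1), n, replace = TRUE)
  edges <- tibble::tibble(
    source = root_node(), target = children, sign = 1L,
    weight = two_weights(length(children))
  )
  connected <- children
  for (v in sample(setdiff(genes, children))) {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      source = sample(connected, 1), target = v,
      sign = sample(c(1L, -1L), 1), weight = two_weights(1)
    ))
    connected <- c(connected, v)
  }
  n_extra <- sample(0:(18 - nrow(edges)), 1)
  key <- paste(edges$source, edges$target, edges$sign)
  while (n_extra > 0) {
    st <- sample(genes, 2)
    sg <- sample(c(1L, -1L), 1)
    k <- paste(st[1], st[2], sg)
    if (!k %in% key) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        source = st[1], target = st[2], sign = sg, weight = two_weights(1)
      ))
      key <- c(key, k)
      n_extra <- n_extra - 1
    }
  }
  make_wnet(edges, terminals)
}

# Disjoint-path star: ROOT -> R_i -> T_i, one terminal per spoke.
star_wnet <- function(seed, k = NULL) {
  set.seed(seed)
  k <- k %||% sample(2:4, 1)
  recs <- sprintf("r%02d", seq_len(k))
  tfs <- sprintf("t%02d", seq_len(k))
  edges <- dplyr::bind_rows(
    tibble::tibble(source = root_node(), target = recs, sign = 1L,
                   weight = sample(c(0.9, 0.1), k, replace = TRUE)),
    tibble::tibble(source = recs, target = tfs, sign = sample(c(1L, -1L), k, replace = TRUE),
                   weight = sample(c(0.9, 0.1), k, replace = TRUE))
  )
  make_wnet(edges, terminals = tfs)
}

# Toy with two alternative routes to one terminal: a 3-edge all-0.9 chain
# (cost ~0.3161) and a 2-edge route with one 0.1 edge (cost ~2.4079).
two_route_wnet <- function() {
  make_wnet(
    tibble::tribble(
      ~source,      ~target, ~sign, ~weight,
      root_node(),  "r1",     1L,    0.9,
      "r1",         "x",      1L,    0.9,
      "x",          "tf1",    1L,    0.9,
      "r1",         "tf1",    1L,    0.1
    ),
    terminals = "tf1"
  )
}

# Small full pipeline inputs built from the canonical example tables.
toy_pipeline_inputs <- function() {
  net <- parse_interactions(
    data.frame(
      source = c("R1", "X", "R2", "X", "L1"),
      target = c("X", "T1", "T2", "T2", "X"),
      sign = c("1", "1", "-1", "1", "1")
    ),
    interaction_dialect(origin = "toy")
  )
  calls <- data.frame(
    gene = c("R1", "X", "T1", "T2", "L1"),
    direction = c("up", "up", "up", "down", "up")
  )
  universe <- c("R1", "R2", "L1", "X", "T1", "T2")
  roles <- classify_roles(universe, tfs = c("T1", "T2"),
                          receptors = c("R1", "R2"), ligands = "L1")
  profile <- booleanize(calls, universe, region = "toyregion")
  list(net = net, calls = calls, universe = universe, roles = roles,
       profile = profile)
}

`%||%` <- rlang::`%||%`
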