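test_that("a forced chain is solved at its closed-form cost", {
  wnet <- make_wnet(
    tibble::tribble(
      ~source,     ~target, ~weight,
      root_node(), "r1",    0.9,
      "r1",        "x",     0.9,
      "x",         "tf1",   0.9
    ),
    terminals = "tf1"
  )
  for (solve in list(exact_steiner, brute_force_steiner, heuristic_steiner)) {
    sol <- solve(wnet)
    expect_equal(sol$total_cost, 3 * -log(0.9), tolerance = 1e-12)
    expect_equal(nrow(sol$tree_edges), 3)
    expect_true(all(validate_solution(wnet, sol)$pass))
  }
})

test_that("more edges at high probability beat fewer edges at low probability", {
  wnet <- two_route_wnet()
  exact <- exact_steiner(wnet)
  expect_equal(exact$total_cost, 3 * -log(0.9), tolerance = 1e-12)
  expect_true("x" %in% exact$tree_edges$target) # took the 3-edge route
  expect_equal(brute_force_steiner(wnet)$total_cost, exact$total_cost)
  heur <- heuristic_steiner(wnet)
  expect_equal(sort(paste(heur$tree_edges$source, heur$tree_edges$target)),
               sort(paste(exact$tree_edges$source, exact$tree_edges$target)))
})

test_that("terminals sharing a prefix pay for shared edges once", {
  wnet <- make_wnet(
    tibble::tribble(
      ~source,     ~target, ~weight,
      root_node(), "r1",    0.9,
      "r1",        "x",     0.9,
      "x",         "tf1",   0.9,
      "x",         "tf2",   0.9,
      root_node(), "r2",    0.9,
      "r2",        "tf2",   0.1
    ),
    terminals = c("tf1", "tf2")
  )
  exact <- exact_steiner(wnet)
  brute <- brute_force_steiner(wnet)
  expect_equal(exact$total_cost, brute$total_cost, tolerance = 1e-9)
  # tree, not union of independent paths: 4 edges, not 2 paths x 3 edges
  expect_equal(nrow(exact$tree_edges), 4)
  expect_equal(exact$total_cost, 4 * -log(0.9), tolerance = 1e-12)
})

test_that("degenerate instances behave per contract", {
  single <- make_wnet(
    tibble::tibble(source = root_node(), target = "r1", weight = 0.9),
    terminals = "r1"
  )
  sol <- brute_force_steiner(single)
  expect_equal(sol$total_cost, -log(0.9), tolerance = 1e-12)
  expect_equal(nrow(sol$tree_edges), 1)

  no_term <- make_wnet(
    tibble::tibble(source = root_node(), target = "r1", weight = 0.9),
    terminals = character()
  )
  for (solve in list(exact_steiner, brute_force_steiner, heuristic_steiner)) {
    empty <- solve(no_term)
    expect_equal(nrow(empty$tree_edges), 0)
    expect_equal(empty$total_cost, 0)
  }
})

test_that("size caps and unreachable terminals raise informative errors", {
  wnet <- random_wnet(5)
  expect_error(brute_force_steiner(wnet, max_edges = 3), "max_edges")
  expect_error(exact_steiner(wnet, max_terminals = 0), "max_terminals")

  unreach <- make_wnet(
    tibble::tribble(
      ~source,     ~target, ~weight,
      root_node(), "r1",    0.9,
      "tf9",       "x",     0.9   # tf9 has no in-edge: unreachable terminal
    ),
    terminals = "tf9"
  )
  expect_error(exact_steiner(unreach), "tf9")
  expect_error(heuristic_steiner(unreach), "tf9")
  expect_error(brute_force_steiner(unreach), "tf9")
})

test_that("prize-collecting mode trades coverage against the penalty", {
  # tf_far costs ~2.41 to reach; tf_near ~0.21
  wnet <- make_wnet(
    tibble::tribble(
      ~source,     ~target,  ~weight,
      root_node(), "r1",     0.9,
      "r1",        "tf_near", 0.9,
      "r1",        "tf_far",  0.1
    ),
    terminals = c("tf_far", "tf_near")
  )
  full <- exact_steiner(wnet)
  expect_length(full$uncovered_terminals, 0)

  cheap <- exact_steiner(wnet, pc_penalty = 0.5)
  expect_equal(cheap$uncovered_terminals, "tf_far")
  expect_equal(cheap$total_cost, 2 * -log(0.9), tolerance = 1e-12)

  generous <- exact_steiner(wnet, pc_penalty = 100)
  expect_length(generous$uncovered_terminals, 0)

  heur <- heuristic_steiner(wnet, pc_penalty = 0.5)
  expect_equal(heur$uncovered_terminals, "tf_far")

  # unreachable terminal allowed under the relaxation
  unreach <- make_wnet(
    tibble::tribble(
      ~source,     ~target, ~weight,
      root_node(), "r1",    0.9,
      "r1",        "tf1",   0.9,
      "tf9",       "x",     0.9
    ),
    terminals = c("tf1", "tf9")
  )
  relaxed <- exact_steiner(unreach, pc_penalty = 1)
  expect_equal(relaxed$uncovered_terminals, "tf9")
  expect_true(all(validate_solution(unreach, relaxed)$pass))
})

test_that("exact solver matches the brute-force oracle on random instances", {
  for (seed in 1:10) {
    wnet <- random_wnet(seed)
    exact <- exact_steiner(wnet)
    brute <- brute_force_steiner(wnet)
    expect_equal(exact$total_cost, brute$total_cost, tolerance = 1e-9)
    expect_true(all(validate_solution(wnet, exact)$pass))
    expect_true(all(validate_solution(wnet, brute)$pass))
  }
})

test_that("the heuristic is admissible and exact on disjoint-path stars", {
  for (seed in 1:10) {
    wnet <- random_wnet(seed + 100)
    heur <- heuristic_steiner(wnet)
    exact <- exact_steiner(wnet)
    expect_gte(heur$total_cost + 1e-9, exact$total_cost)
    expect_true(all(validate_solution(wnet, heur)$pass))
    expect_false(heur$optimal)
  }
  for (seed in 1:5) {
    star <- star_wnet(seed)
    expect_equal(heuristic_steiner(star)$total_cost,
                 exact_steiner(star)$total_cost, tolerance = 1e-12)
  }
})

test_that("solvers are deterministic and scale-invariant in the costs", {
  wnet <- random_wnet(77)
  a <- exact_steiner(wnet)
  b <- exact_steiner(wnet)
  expect_identical(tidy(a), tidy(b))

  scaled <- wnet
  scaled$edges$cost <- wnet$edges$cost * 3.5
  s <- exact_steiner(scaled)
  expect_equal(s$total_cost, a$total_cost * 3.5, tolerance = 1e-9)
  key <- function(sol) sort(paste(sol$tree_edges$source, sol$tree_edges$target,
                                  sol$tree_edges$sign))
  expect_equal(key(s), key(a))
})

test_that("adding an edge never increases the optimal cost", {
  for (seed in c(21, 22, 23)) {
    wnet <- random_wnet(seed)
    base <- exact_steiner(wnet)$total_cost
    nodes <- setdiff(unique(c(wnet$edges$source, wnet$edges$target)), root_node())
    set.seed(seed)
    st <- sample(nodes, 2)
    extra <- wnet
    extra$edges <- dplyr::bind_rows(extra$edges, tibble::tibble(
      source = st[1], target = st[2], sign = 1L, weight = 0.9,
      cost = -log(0.9), origin = "extra"
    ))
    extra$edges <- dplyr::distinct(extra$edges, source, target, sign,
                                   .keep_all = TRUE)
    expect_lte(exact_steiner(extra)$total_cost, base + 1e-9)
  }
})

test_that("validation catches fabricated cycles and dropped terminals", {
  wnet <- two_route_wnet()
  sol <- exact_steiner(wnet)

  cyclic <- sol
  cyclic$tree_edges <- tibble::tibble(
    source = c("r1", "x", "tf1"), target = c("x", "tf1", "r1"),
    sign = 1L, weight = 0.9, cost = -log(0.9)
  )
  cyclic$total_cost <- sum(cyclic$tree_edges$cost)
  v <- validate_solution(wnet, cyclic)
  expect_false(v$pass[v$check == "arborescence"])

  missing <- sol
  missing$tree_edges <- sol$tree_edges[sol$tree_edges$target != "tf1", ]
  missing$total_cost <- sum(missing$tree_edges$cost)
  v2 <- validate_solution(wnet, missing)
  expect_false(v2$pass[v2$check == "terminal_coverage"])

  alien <- sol
  alien$tree_edges <- dplyr::bind_rows(sol$tree_edges, tibble::tibble(
    source = "mars", target = "tf1", sign = 1L, weight = 0.9, cost = -log(0.9)
  ))
  v3 <- validate_solution(wnet, alien)
  expect_false(v3$pass[v3$check == "edges_exist"])
})

test_that("parallel opposite-sign edges coexist but a tree uses at most one", {
  wnet <- make_wnet(
    tibble::tribble(
      ~source,     ~target, ~sign, ~weight,
      root_node(), "r1",    1L,    0.9,
      "r1",        "tf1",   1L,    0.9,
      "r1",        "tf1",   -1L,   0.1
    ),
    terminals = "tf1"
  )
  sol <- exact_steiner(wnet)
  used <- sol$tree_edges[sol$tree_edges$target == "tf1", ]
  expect_equal(nrow(used), 1)
  expect_equal(used$sign, 1L)
})

test_that("solution manifests record solver, cost and validation", {
  wnet <- two_route_wnet()
  sol <- exact_steiner(wnet)
  path <- withr::local_tempfile(fileext = ".json")
  write_solution_manifest(sol, wnet, path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(m$solver, "exact_dw")
  expect_equal(m$total_cost, sol$total_cost, tolerance = 1e-9)
  expect_true(all(m$validation$pass))
})
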