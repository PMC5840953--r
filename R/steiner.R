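# Rooted directed Steiner arborescence solvers.
#
# Three routes to the same objective (connect ROOT to every terminal TF at
# minimum total -ln(weight) cost):
#   exact_steiner       dynamic programming over terminal subsets
#                       (directed Dreyfus-Wagner on the shortest-path metric)
#   brute_force_steiner exhaustive enumeration of per-node in-edge
#                       assignments (the testing oracle)
#   heuristic_steiner   deterministic cheapest-path terminal attachment
#
# All tie-breaking is lexicographic on node symbols: nodes are processed in
# sorted order and the first minimum wins, so every solver is fully
# deterministic. Floating-point cost comparisons use a 1e-12 tolerance.

COST_TOL <- 1e-12

# internal indexed-graph view of a weighted_network ---------------------------

graph_index <- function(wnet) {
  stopifnot(inherits(wnet, "weighted_network"))
  edges <- wnet$edges
  if (any(edges$target == wnet$root)) {
    abort("The weighted network has an edge into the root; it must not.")
  }
  if (any(edges$cost <= 0) || any(!is.finite(edges$cost))) {
    abort("All edge costs must be strictly positive and finite.")
  }
  nodes <- sort(unique(c(edges$source, edges$target)))
  ord <- order(match(edges$source, nodes), match(edges$target, nodes), edges$sign)
  edges <- edges[ord, , drop = FALSE]
  src <- match(edges$source, nodes)
  tgt <- match(edges$target, nodes)
  adj <- split(seq_len(nrow(edges)), factor(src, levels = seq_along(nodes)))
  list(
    nodes = nodes, edges = edges, src = src, tgt = tgt,
    cost = edges$cost, adj = adj,
    root = match(wnet$root, nodes),
    terminals = match(sort(wnet$terminals), nodes)
  )
}

# Dijkstra from a set of sources (distance 0 at each). Returns distances and
# the in-edge of each node on its best path. Deterministic: among equal
# frontier distances the smallest node index (lexicographically smallest
# symbol) is settled first; among equal-cost relaxations the predecessor
# with the smaller node index is kept.
dijkstra_from <- function(g, sources) {
  n <- length(g$nodes)
  dist <- rep(Inf, n)
  pedge <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[sources] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    for (e in g$adj[[u]]) {
      v <- g$tgt[e]
      nd <- dist[u] + g$cost[e]
      if (nd < dist[v] - COST_TOL) {
        dist[v] <- nd
        pedge[v] <- e
      } else if (nd <= dist[v] + COST_TOL && !is.na(pedge[v]) &&
                 u < g$src[pedge[v]]) {
        pedge[v] <- e
      }
    }
  }
  list(dist = dist, pedge = pedge)
}

# all-pairs shortest-path distances and parent edges
apsp <- function(g) {
  n <- length(g$nodes)
  D <- matrix(Inf, n, n)
  P <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    r <- dijkstra_from(g, s)
    D[s, ] <- r$dist
    P[s, ] <- r$pedge
  }
  list(D = D, P = P)
}

# edge ids of the shortest path s -> v recorded in parent matrix P
path_edge_ids <- function(g, P, s, v) {
  out <- integer(0)
  while (v != s) {
    e <- P[s, v]
    if (is.na(e)) abort("Internal: no recorded path during backtrack.")
    out <- c(out, e)
    v <- g$src[e]
  }
  rev(out)
}

new_solution <- function(g, wnet, eids, solver, optimal, uncovered = character(0)) {
  eids <- sort(unique(eids))
  tree <- g$edges[eids, c("source", "target", "sign", "weight", "cost")]
  structure(
    list(
      tree_edges = as_tibble(tree),
      total_cost = sum(tree$cost),
      solver = solver,
      optimal = optimal,
      uncovered_terminals = sort(uncovered),
      terminals = sort(wnet$terminals),
      root = wnet$root,
      region = wnet$region,
      phenotype = wnet$phenotype
    ),
    class = "steiner_solution"
  )
}

#' @export
print.steiner_solution <- function(x, ...) {
  cat("Steiner arborescence (", x$solver, ")\n", sep = "")
  cat("  ", nrow(x$tree_edges), " edges | total cost ",
      format(x$total_cost, digits = 8), " | ",
      length(x$terminals) - length(x$uncovered_terminals), "/",
      length(x$terminals), " terminals covered | optimal: ",
      x$optimal, "\n", sep = "")
  invisible(x)
}

#' Tidy the edges of a solution or weighted network
#'
#' @param x A `steiner_solution` or `weighted_network`.
#' @param ... Unused.
#' @return A tibble of edges (`source`, `target`, `sign`, `weight`, `cost`).
#' @method tidy steiner_solution
#' @export
tidy.steiner_solution <- function(x, ...) {
  x$tree_edges
}

#' One-row summary of a solution or weighted network
#'
#' @param x A `steiner_solution` or `weighted_network`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance steiner_solution
#' @export
glance.steiner_solution <- function(x, ...) {
  tibble(
    solver = x$solver, optimal = x$optimal,
    total_cost = x$total_cost, n_edges = nrow(x$tree_edges),
    n_terminals = length(x$terminals),
    n_uncovered = length(x$uncovered_terminals),
    region = x$region %||% NA_character_,
    phenotype = x$phenotype %||% NA_character_
  )
}

check_reachable <- function(g, pc) {
  reach <- dijkstra_from(g, g$root)$dist
  unreachable <- g$terminals[!is.finite(reach[g$terminals])]
  if (length(unreachable) > 0 && is.null(pc)) {
    abort(paste0(
      "Terminal(s) unreachable from the root: ",
      paste(g$nodes[unreachable], collapse = ", "),
      ". Use `pc_penalty` to allow exclusion, or fix the network."
    ))
  }
  unreachable
}

#' Exact minimum-cost Steiner arborescence
#'
#' Dynamic programming over terminal subsets on the shortest-path metric
#' (directed Dreyfus-Wagner): exponential in the number of terminals,
#' polynomial in network size, so exact answers are practical up to roughly
#' a dozen terminal TFs. Returns the provably cheapest arborescence rooted
#' at the dummy node that covers every terminal.
#'
#' @param wnet A `weighted_network` from [build_weighted_network()].
#' @param max_terminals Refuse instances with more terminals than this
#'   (default 12); use [heuristic_steiner()] beyond it.
#' @param pc_penalty Optional prize-collecting relaxation: a per-terminal
#'   exclusion penalty (same units as edge cost). When set, the solver
#'   minimizes tree cost + penalty * (number of excluded terminals) and
#'   reports exclusions in `uncovered_terminals`; when `NULL` (default),
#'   every terminal is mandatory and unreachable terminals are an error.
#' @return A `steiner_solution`: `tree_edges`, `total_cost` (sum of tree
#'   edge costs), `solver`, `optimal = TRUE`, `uncovered_terminals`.
#' @export
#' @examples
#' # see vignette("sustained-signaling") for a worked run
exact_steiner <- function(wnet, max_terminals = 12, pc_penalty = NULL) {
  g <- graph_index(wnet)
  k <- length(g$terminals)
  if (k > max_terminals) {
    abort(paste0(
      k, " terminals exceed max_terminals = ", max_terminals,
      "; use heuristic_steiner() for instances of this size."
    ))
  }
  if (k == 0) {
    return(new_solution(g, wnet, integer(0), "exact_dw", TRUE))
  }
  unreachable <- check_reachable(g, pc_penalty)

  n <- length(g$nodes)
  sp <- apsp(g)
  D <- sp$D

  nmask <- bitwShiftL(1L, k) - 1L
  gdp <- matrix(Inf, n, nmask) # gdp[v, mask]: best tree rooted at v covering mask
  Fdp <- matrix(Inf, n, nmask) # pre-relaxation merge values (masks with >=2 bits)
  bits <- vapply(seq_len(nmask), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) > 0), 0L)

  for (i in seq_len(k)) {
    gdp[, bitwShiftL(1L, i - 1L)] <- D[, g$terminals[i]]
  }
  if (k >= 2) {
    for (m in seq_len(nmask)[bits >= 2]) {
      low <- bitwAnd(m, -m)
      best <- rep(Inf, n)
      sub <- bitwAnd(m - 1L, m)
      while (sub > 0L) {
        if (bitwAnd(sub, low) > 0L) {
          best <- pmin(best, gdp[, sub] + gdp[, bitwXor(m, sub)])
        }
        sub <- bitwAnd(sub - 1L, m)
      }
      Fdp[, m] <- best
      gdp[, m] <- apply(D + rep(best, each = n), 1, min)
    }
  }

  # choose covered terminal subset (all terminals unless prize-collecting)
  if (is.null(pc_penalty)) {
    best_mask <- nmask
    if (!is.finite(gdp[g$root, best_mask])) {
      abort("Internal: full terminal set unreachable despite reachability check.")
    }
  } else {
    obj <- c(pc_penalty * k, gdp[g$root, ] + pc_penalty * (k - bits))
    best_mask <- which.min(obj) - 1L
    if (best_mask == 0L) {
      return(new_solution(g, wnet, integer(0), "exact_dw", TRUE,
                          uncovered = g$nodes[g$terminals]))
    }
  }

  # backtrack: re-derive the argmins with the same tolerance
  eids <- integer(0)
  expand <- function(v, mask) {
    if (bits[mask] == 1L) {
      t <- g$terminals[which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0)]
      eids <<- c(eids, path_edge_ids(g, sp$P, v, t))
      return(invisible(NULL))
    }
    vals <- D[v, ] + Fdp[, mask]
    u <- which(vals <= gdp[v, mask] + COST_TOL)[1]
    if (is.na(u)) abort("Internal: DP backtrack failed (merge node).")
    eids <<- c(eids, path_edge_ids(g, sp$P, v, u))
    low <- bitwAnd(mask, -mask)
    sub <- bitwAnd(mask - 1L, mask)
    while (sub > 0L) {
      if (bitwAnd(sub, low) > 0L &&
          gdp[u, sub] + gdp[u, bitwXor(mask, sub)] <= Fdp[u, mask] + COST_TOL) {
        expand(u, sub)
        expand(u, bitwXor(mask, sub))
        return(invisible(NULL))
      }
      sub <- bitwAnd(sub - 1L, mask)
    }
    abort("Internal: DP backtrack failed (split).")
  }
  expand(g$root, best_mask)

  covered_idx <- g$terminals[bitwAnd(best_mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0]
  uncovered <- setdiff(g$nodes[g$terminals], g$nodes[covered_idx])
  eids <- prune_arborescence(g, unique(eids), covered_idx)
  sol <- new_solution(g, wnet, eids, "exact_dw", TRUE, uncovered = uncovered)
  if (abs(sol$total_cost - gdp[g$root, best_mask]) > 1e-9) {
    abort("Internal: backtracked tree cost disagrees with the DP optimum.")
  }
  sol
}

# Reduce a union of optimal-path edges to a proper arborescence covering
# `term_i` from the root: resolve duplicate in-edges (keeping reachability),
# then iteratively drop edges that no root->terminal path uses.
prune_arborescence <- function(g, eids, term_i) {
  reaches_all <- function(ids) {
    ok <- rep(FALSE, length(g$nodes))
    ok[g$root] <- TRUE
    repeat {
      add <- ids[ok[g$src[ids]] & !ok[g$tgt[ids]]]
      if (length(add) == 0) break
      ok[g$tgt[add]] <- TRUE
    }
    all(ok[term_i])
  }
  repeat {
    tgt <- g$tgt[eids]
    dup_nodes <- unique(tgt[duplicated(tgt)])
    if (length(dup_nodes) == 0) break
    v <- dup_nodes[1]
    cand <- eids[g$tgt[eids] == v]
    cand <- cand[order(-g$cost[cand], -cand)] # try dropping expensive edges first
    dropped <- FALSE
    for (e in cand) {
      if (reaches_all(setdiff(eids, e))) {
        eids <- setdiff(eids, e)
        dropped <- TRUE
        break
      }
    }
    if (!dropped) abort("Internal: could not reduce path union to a tree.")
  }
  # drop branches no terminal needs (non-terminal leaves)
  repeat {
    keep_nodes <- unique(c(g$src[eids], g$root))
    leaf_edges <- eids[!(g$tgt[eids] %in% keep_nodes) & !(g$tgt[eids] %in% term_i)]
    if (length(leaf_edges) == 0) break
    eids <- setdiff(eids, leaf_edges)
  }
  eids
}

#' Brute-force Steiner oracle
#'
#' Exhaustively enumerates candidate arborescences by assigning to every
#' node at most one in-edge (edge subsets in which some node has two
#' in-edges can never form an arborescence, so nothing is lost), keeps the
#' assignments that form a root-rooted tree covering all terminals, and
#' returns the cheapest. Cost-bound pruning is applied during enumeration;
#' it cannot discard a strictly cheaper completion, so the result is the
#' exact optimum. Intended as an independent test oracle on small networks.
#'
#' @param wnet A `weighted_network`.
#' @param max_edges Refuse instances with more edges than this (default 18).
#' @return A `steiner_solution` with `solver = "brute_force"`,
#'   `optimal = TRUE`.
#' @export
brute_force_steiner <- function(wnet, max_edges = 18) {
  g <- graph_index(wnet)
  if (nrow(g$edges) > max_edges) {
    abort(paste0(nrow(g$edges), " edges exceed max_edges = ", max_edges,
                 " for the brute-force oracle."))
  }
  if (length(g$terminals) == 0) {
    return(new_solution(g, wnet, integer(0), "brute_force", TRUE))
  }
  check_reachable(g, NULL)

  n <- length(g$nodes)
  is_term <- rep(FALSE, n)
  is_term[g$terminals] <- TRUE
  in_edges <- split(seq_len(nrow(g$edges)), factor(g$tgt, levels = seq_len(n)))

  env <- new.env(parent = emptyenv())
  env$best <- Inf
  env$best_choice <- NULL
  choice <- rep(NA_integer_, n) # in-edge id per node

  valid_cost <- function(choice) {
    # every node with an in-edge must chain to the root without cycles
    state <- integer(n) # 0 unseen, 1 on stack, 2 ok
    state[g$root] <- 2L
    for (v in seq_len(n)) {
      if (state[v] != 0L || is.na(choice[v])) next
      path <- integer(0)
      u <- v
      while (state[u] == 0L && !is.na(choice[u])) {
        state[u] <- 1L
        path <- c(path, u)
        u <- g$src[choice[u]]
      }
      ok <- state[u] == 2L
      state[path] <- if (ok) 2L else 3L
      if (!ok) return(NULL)
    }
    sum(g$cost[choice[!is.na(choice)]])
  }

  recurse <- function(v, acc) {
    if (acc >= env$best - COST_TOL) return(invisible(NULL))
    if (v > n) {
      cost <- valid_cost(choice)
      if (!is.null(cost) && cost < env$best - COST_TOL) {
        env$best <- cost
        env$best_choice <- choice
      }
      return(invisible(NULL))
    }
    if (v == g$root) {
      recurse(v + 1L, acc)
      return(invisible(NULL))
    }
    if (!is_term[v]) {
      choice[v] <<- NA_integer_
      recurse(v + 1L, acc)
    }
    for (e in in_edges[[v]]) {
      choice[v] <<- e
      recurse(v + 1L, acc + g$cost[e])
    }
    choice[v] <<- NA_integer_
    invisible(NULL)
  }
  recurse(1L, 0)

  if (is.null(env$best_choice)) {
    abort("No arborescence covering all terminals exists in this network.")
  }
  new_solution(g, wnet, env$best_choice[!is.na(env$best_choice)],
               "brute_force", TRUE)
}

#' Shortest-path attachment heuristic
#'
#' Grows the tree from the root by repeatedly attaching the terminal whose
#' cheapest path from the current tree is cheapest (ties broken by node
#' symbol order), then pruning non-terminal leaves. Deterministic; fast on
#' networks far beyond the exact solver's terminal budget; never better
#' than the exact optimum and usually equal on sparse instances.
#'
#' @param wnet A `weighted_network`.
#' @param pc_penalty Optional prize-collecting relaxation: terminals whose
#'   cheapest attachment path costs more than this are left uncovered
#'   instead of attached.
#' @return A `steiner_solution` with `solver = "heuristic_sp"`,
#'   `optimal = FALSE`.
#' @export
heuristic_steiner <- function(wnet, pc_penalty = NULL) {
  g <- graph_index(wnet)
  if (length(g$terminals) == 0) {
    return(new_solution(g, wnet, integer(0), "heuristic_sp", FALSE))
  }
  check_reachable(g, pc_penalty)

  in_tree <- rep(FALSE, length(g$nodes))
  in_tree[g$root] <- TRUE
  eids <- integer(0)
  uncovered <- g$terminals

  while (length(uncovered) > 0) {
    r <- dijkstra_from(g, which(in_tree))
    d <- r$dist[uncovered]
    pick <- which.min(d) # first minimum = smallest node symbol among ties
    if (!is.finite(d[pick]) ||
        (!is.null(pc_penalty) && d[pick] > pc_penalty + COST_TOL)) {
      break
    }
    t <- uncovered[pick]
    v <- t
    while (!in_tree[v]) {
      e <- r$pedge[v]
      eids <- c(eids, e)
      in_tree[v] <- TRUE
      v <- g$src[e]
    }
    uncovered <- uncovered[-pick]
  }
  if (length(uncovered) > 0 && is.null(pc_penalty)) {
    abort("Internal: terminals left uncovered despite reachability check.")
  }
  covered <- setdiff(g$terminals, uncovered)
  eids <- prune_arborescence(g, unique(eids), covered)
  new_solution(g, wnet, eids, "heuristic_sp", FALSE,
               uncovered = g$nodes[uncovered])
}

#' Validate a Steiner solution against its network
#'
#' Re-checks every structural contract: tree edges exist in the network,
#' the tree is an arborescence rooted at the dummy node (in-degree one, no
#' cycles, all tree nodes reachable), every non-excluded terminal is
#' covered, the reported cost matches the recomputed edge-cost sum (1e-9),
#' and every root-to-terminal path enters the network through a root child
#' (an upregulated receptor/ligand).
#'
#' @param wnet The `weighted_network` the solution was computed on.
#' @param sol A `steiner_solution`.
#' @return A tibble (`check`, `pass`, `detail`); all-pass means valid.
#' @export
validate_solution <- function(wnet, sol) {
  stopifnot(inherits(wnet, "weighted_network"), inherits(sol, "steiner_solution"))
  te <- sol$tree_edges
  key <- function(df) paste(df$source, df$target, df$sign)
  checks <- list()

  net_keys <- key(wnet$edges)
  missing_edges <- setdiff(key(te), net_keys)
  checks$edges_exist <- list(
    pass = length(missing_edges) == 0,
    detail = if (length(missing_edges)) paste(missing_edges, collapse = "; ") else ""
  )

  indeg_ok <- !any(duplicated(te$target)) && !(wnet$root %in% te$target)
  reach <- wnet$root
  rest <- te
  repeat {
    hit <- rest$source %in% reach
    if (!any(hit)) break
    reach <- c(reach, rest$target[hit])
    rest <- rest[!hit, , drop = FALSE]
  }
  acyclic <- nrow(rest) == 0
  checks$arborescence <- list(
    pass = indeg_ok && acyclic,
    detail = if (!indeg_ok) "duplicate in-edge or edge into root"
             else if (!acyclic) "edges unreachable from root (cycle or orphan)"
             else ""
  )

  must_cover <- setdiff(sol$terminals, sol$uncovered_terminals)
  not_covered <- setdiff(must_cover, reach)
  checks$terminal_coverage <- list(
    pass = length(not_covered) == 0,
    detail = paste(not_covered, collapse = "; ")
  )

  cost_lookup <- wnet$edges$cost[match(key(te), net_keys)]
  recomputed <- sum(cost_lookup)
  checks$cost <- list(
    pass = length(missing_edges) == 0 && abs(recomputed - sol$total_cost) <= 1e-9,
    detail = sprintf("reported %.12g recomputed %.12g", sol$total_cost, recomputed)
  )

  first_hops <- te$target[te$source == wnet$root]
  checks$first_hop_root_children <- list(
    pass = all(first_hops %in% wnet$root_children) &&
      (length(must_cover) == 0 || length(first_hops) > 0),
    detail = paste(setdiff(first_hops, wnet$root_children), collapse = "; ")
  )

  tibble(
    check = names(checks),
    pass = vapply(checks, `[[`, logical(1), "pass"),
    detail = vapply(checks, `[[`, character(1), "detail")
  )
}

#' Write a JSON run manifest for a solution
#'
#' Records solver, cost, terminal coverage, tie-break rule and a hash of
#' the weighting parameters, so a run can be audited without re-solving.
#'
#' @param sol A `steiner_solution`.
#' @param wnet The `weighted_network` it was computed on.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_solution_manifest <- function(sol, wnet, path) {
  manifest <- list(
    solver = sol$solver,
    optimal = sol$optimal,
    total_cost = sol$total_cost,
    n_tree_edges = nrow(sol$tree_edges),
    terminals = sol$terminals,
    uncovered_terminals = sol$uncovered_terminals,
    region = wnet$region,
    phenotype = wnet$phenotype,
    tie_break = "lexicographic node symbols",
    params_hash = rlang::hash(wnet$params),
    validation = validate_solution(wnet, sol)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
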