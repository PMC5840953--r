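# Differential edge weighting and weighted-network construction.
#
# Two fixed probabilities: an edge compatible with the phenotype's
# expression states scores p_high (default 0.9), every other edge p_low
# (default 0.1). Costs are -ln(weight), so probability maximization becomes
# additive cost minimization for the Steiner solver.

#' Parameters of the differential edge-weighting scheme
#'
#' @param p_high,p_low The two fixed probabilities for compatible /
#'   incompatible edges. Defaults 0.9 and 0.1; must satisfy
#'   `0 < p_low < p_high < 1`.
#' @param scheme Which reading of "compatible" to use:
#'   * `"differential_activity"` (default): an edge is high-probability iff
#'     its source is differentially expressed, its target is upregulated in
#'     the phenotype, and the sign agrees (`sign * state_src == +1`) — the
#'     target is then more active in this phenotype than in the other.
#'   * `"sign_consistency"`: high-probability iff both endpoints are
#'     differentially expressed and `sign * state_src == state_tgt`.
#' @param root_edge_weight Weight of the dummy-root-to-receptor edges.
#'   Defaults to `p_high` so the solver's receptor choice is driven by
#'   downstream topology, not by the root hop.
#' @return A `weight_params` list.
#' @export
#' @examples
#' weight_params()
#' weight_params(scheme = "sign_consistency")
weight_params <- function(p_high = 0.9, p_low = 0.1,
                          scheme = c("differential_activity", "sign_consistency"),
                          root_edge_weight = p_high) {
  scheme <- match.arg(scheme)
  stopifnot(
    is.numeric(p_high), is.numeric(p_low), length(p_high) == 1,
    length(p_low) == 1, is.numeric(root_edge_weight),
    length(root_edge_weight) == 1
  )
  if (!(0 < p_low && p_low < p_high && p_high < 1)) {
    abort("Need 0 < p_low < p_high < 1.")
  }
  if (!(root_edge_weight > 0 && root_edge_weight < 1)) {
    abort("`root_edge_weight` must be in (0, 1).")
  }
  structure(
    list(p_high = p_high, p_low = p_low, scheme = scheme,
         root_edge_weight = root_edge_weight),
    class = "weight_params"
  )
}

#' @export
print.weight_params <- function(x, ...) {
  cat("Differential edge weights: p_high =", x$p_high, "| p_low =", x$p_low,
      "| scheme =", x$scheme, "| root edge =", x$root_edge_weight, "\n")
  invisible(x)
}

#' Differential weight of one signaling edge
#'
#' Scores the compatibility between an interaction's sign and the
#' booleanized expression states of its endpoints, for the phenotype the
#' states are oriented to. Compatible edges score `p_high`, all others
#' `p_low`; vectorized over the three arguments.
#'
#' @param state_src,state_tgt Booleanized states in \{-1, 0, +1\}, already
#'   oriented to the phenotype being weighted.
#' @param sign Interaction sign: +1 activation, -1 inhibition.
#' @param params A [weight_params()].
#' @return Numeric vector of probabilities (`p_high` or `p_low`).
#' @export
#' @examples
#' # activating edge, both endpoints upregulated in the phenotype -> 0.9
#' edge_weight(1, 1, 1)
#' # inhibiting edge between two upregulated genes -> 0.1
#' edge_weight(1, 1, -1)
edge_weight <- function(state_src, state_tgt, sign, params = weight_params()) {
  stopifnot(inherits(params, "weight_params"))
  n <- max(length(state_src), length(state_tgt), length(sign))
  state_src <- rep_len(as.integer(state_src), n)
  state_tgt <- rep_len(as.integer(state_tgt), n)
  sign <- rep_len(as.integer(sign), n)
  if (!all(state_src %in% c(-1L, 0L, 1L)) || !all(state_tgt %in% c(-1L, 0L, 1L))) {
    abort("Booleanized states must be -1, 0, or +1.")
  }
  if (!all(sign %in% c(-1L, 1L))) {
    abort("Interaction sign must be +1 (activation) or -1 (inhibition).")
  }
  high <- switch(params$scheme,
    differential_activity =
      state_src != 0L & state_tgt == 1L & sign * state_src == 1L,
    sign_consistency =
      state_src != 0L & state_tgt != 0L & sign * state_src == state_tgt
  )
  ifelse(high, params$p_high, params$p_low)
}

#' Exhaustive decision table of the edge-weighting scheme
#'
#' Enumerates all 18 combinations of source state, target state and
#' interaction sign and the probability each receives under `params`.
#'
#' @param params A [weight_params()].
#' @return An 18-row tibble (`state_src`, `state_tgt`, `sign`, `weight`).
#' @export
#' @examples
#' weight_table()
weight_table <- function(params = weight_params()) {
  grid <- tidyr::expand_grid(
    state_src = c(-1L, 0L, 1L),
    state_tgt = c(-1L, 0L, 1L),
    sign = c(-1L, 1L)
  )
  grid %>%
    mutate(weight = edge_weight(.data$state_src, .data$state_tgt,
                                .data$sign, params))
}

#' Build the weighted network a Steiner run consumes
#'
#' Weights every interactome edge by [edge_weight()] under the profile's
#' orientation, injects the dummy root node with an edge to every
#' upregulated receptor/ligand, converts weights to additive costs
#' (`-ln(weight)`), and records the terminal set (differentially expressed
#' TFs). Root edges carry `root_edge_weight` and sign +1.
#'
#' @param net An interactome tibble.
#' @param profile A booleanized profile, oriented to the phenotype to be
#'   analyzed (see [orient_for_phenotype()]).
#' @param roles Role tibble from [classify_roles()].
#' @param params A [weight_params()].
#' @param root_children Passed to [select_root_children()].
#' @return A `weighted_network` object: list with `edges` (tibble: `source`,
#'   `target`, `sign`, `weight`, `cost`, `origin`), `root`, `root_children`,
#'   `terminals`, `phenotype`, `region`, `params`.
#' @export
build_weighted_network <- function(net, profile, roles,
                                   params = weight_params(),
                                   root_children = c("receptors+ligands", "receptors")) {
  assert_df_cols(net, c("source", "target", "sign"), "net")
  if (any(net$target == ROOT_NODE) || any(net$source == ROOT_NODE)) {
    abort("The interactome must not mention the reserved root identifier.")
  }
  children <- select_root_children(profile, roles, root_children)
  terminals <- select_terminals(profile, roles)

  signaling <- as_tibble(net) %>%
    mutate(
      weight = edge_weight(profile_state(profile, .data$source),
                           profile_state(profile, .data$target),
                           .data$sign, params),
      cost = -log(.data$weight),
      origin = if ("origin" %in% names(net)) .data$origin else "interactome"
    ) %>%
    select("source", "target", "sign", "weight", "cost", "origin")

  root_edges <- tibble(
    source = ROOT_NODE, target = children, sign = 1L,
    weight = params$root_edge_weight,
    cost = -log(params$root_edge_weight),
    origin = "root"
  )

  structure(
    list(
      edges = bind_rows(root_edges, signaling) %>%
        arrange(.data$source != ROOT_NODE, .data$source, .data$target, .data$sign),
      root = ROOT_NODE,
      root_children = children,
      terminals = terminals,
      phenotype = profile_phenotype(profile),
      region = profile_region(profile),
      params = params
    ),
    class = "weighted_network"
  )
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("Weighted signaling network (", x$region, ", ", x$phenotype,
      "-oriented)\n", sep = "")
  cat("  ", nrow(x$edges), " edges | ", length(network_nodes(x)), " nodes | ",
      length(x$root_children), " root children | ",
      length(x$terminals), " terminal TFs\n", sep = "")
  invisible(x)
}

#' Nodes of a weighted network (including the root)
#'
#' @param wnet A `weighted_network`.
#' @return Sorted character vector of node names; the root comes first.
#' @export
network_nodes <- function(wnet) {
  stopifnot(inherits(wnet, "weighted_network"))
  genes <- sort(unique(c(wnet$edges$source, wnet$edges$target)))
  c(ROOT_NODE, setdiff(genes, ROOT_NODE))
}

#' @rdname tidy.steiner_solution
#' @method tidy weighted_network
#' @export
tidy.weighted_network <- function(x, ...) {
  x$edges
}

#' @rdname glance.steiner_solution
#' @method glance weighted_network
#' @export
glance.weighted_network <- function(x, ...) {
  tibble(
    region = x$region, phenotype = x$phenotype,
    n_nodes = length(network_nodes(x)), n_edges = nrow(x$edges),
    n_root_children = length(x$root_children),
    n_terminals = length(x$terminals),
    p_high = x$params$p_high, p_low = x$params$p_low,
    scheme = x$params$scheme
  )
}

#' Write a weighted network or solution edge list as TSV
#'
#' @param wnet A `weighted_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(wnet, path) {
  readr::write_tsv(tidy(wnet), path, progress = FALSE)
  invisible(path)
}
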