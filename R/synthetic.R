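# Synthetic instance generator: random signed interactomes with planted
# receptor -> TF pathways and expression states consistent with them, so the
# whole pipeline can be scored by receptor recovery without external data.

#' Configuration of the synthetic instance generator
#'
#' Defaults describe the desk-scale study condition: a 60-gene interactome
#' with 120 random background edges and 3 planted pathways, small enough
#' for the exact solver and the brute-force oracle yet structured like the
#' real inputs (dedicated receptor/ligand/TF pools, mixed activating and
#' inhibiting edges).
#'
#' @param n_genes Total number of genes.
#' @param n_receptors,n_ligands,n_tfs Sizes of the role pools; the rest of
#'   the genes are signaling intermediates.
#' @param extra_edges Number of random background edges.
#' @param inhibition_fraction Probability that an edge is inhibitory.
#' @param k_planted Number of planted receptor-to-TF pathways.
#' @param path_len Integer range (min, max) of interior chain length.
#' @param tfs_per_pathway Integer range (min, max) of TFs per pathway.
#' @param noise_flip_rate Probability that a non-planted gene's state is set
#'   to +/-1 (spurious differential-expression calls).
#' @param planted_corrupt_rate Probability that a planted gene's state is
#'   zeroed (missed calls).
#' @param seed Integer seed; the instance is a pure function of the config.
#' @return A `synthetic_config` list.
#' @export
#' @examples
#' synthetic_config(seed = 7)
synthetic_config <- function(n_genes = 60, n_receptors = 8, n_ligands = 4,
                             n_tfs = 10, extra_edges = 120,
                             inhibition_fraction = 0.3, k_planted = 3,
                             path_len = c(1, 3), tfs_per_pathway = c(1, 2),
                             noise_flip_rate = 0, planted_corrupt_rate = 0,
                             seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_receptors = as.integer(n_receptors),
    n_ligands = as.integer(n_ligands), n_tfs = as.integer(n_tfs),
    extra_edges = as.integer(extra_edges),
    inhibition_fraction = inhibition_fraction,
    k_planted = as.integer(k_planted),
    path_len = as.integer(path_len), tfs_per_pathway = as.integer(tfs_per_pathway),
    noise_flip_rate = noise_flip_rate,
    planted_corrupt_rate = planted_corrupt_rate,
    seed = as.integer(seed)
  )
  n_inter <- cfg$n_genes - cfg$n_receptors - cfg$n_ligands - cfg$n_tfs
  rates <- c(cfg$inhibition_fraction, cfg$noise_flip_rate, cfg$planted_corrupt_rate)
  if (n_inter < 0) abort("Role pools exceed n_genes.")
  if (any(rates < 0 | rates > 1)) abort("All rates must be in [0, 1].")
  if (length(cfg$path_len) != 2 || cfg$path_len[1] < 0 ||
      cfg$path_len[1] > cfg$path_len[2]) {
    abort("`path_len` must be (min, max) with 0 <= min <= max.")
  }
  if (length(cfg$tfs_per_pathway) != 2 || cfg$tfs_per_pathway[1] < 1 ||
      cfg$tfs_per_pathway[1] > cfg$tfs_per_pathway[2]) {
    abort("`tfs_per_pathway` must be (min, max) with 1 <= min <= max.")
  }
  if (cfg$k_planted > cfg$n_receptors) {
    abort("k_planted exceeds the receptor pool: infeasible config.")
  }
  if (cfg$k_planted * cfg$path_len[2] > n_inter) {
    abort("Not enough intermediates for node-disjoint planted pathways.")
  }
  if (cfg$k_planted * cfg$tfs_per_pathway[2] > cfg$n_tfs) {
    abort("Not enough TFs for node-disjoint planted pathways.")
  }
  structure(cfg, class = "synthetic_config")
}

sample1 <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
}

synth_names <- function(prefix, n, total) {
  if (n == 0) return(character(0))
  sprintf("%s%0*d", prefix, max(2, nchar(total)), seq_len(n))
}

#' Generate one synthetic instance
#'
#' Plants `k_planted` node-disjoint pathways receptor -> interior chain ->
#' TFs. The receptor's intended state is +1 and states propagate as
#' `state(target) = sign * state(source)`, so every planted edge is
#' sign-compatible with the expression pattern — the planted pathways
#' realize a constantly activated route from the stimulus to the TFs.
#' Random background edges are then added; a background edge between two
#' planted (nonzero-state) genes is forced to the sign-incompatible sign so
#' that the planted pathways remain the unique compatible routes and the
#' ground truth stays identifiable. Finally planted states are zeroed with
#' probability `planted_corrupt_rate` and non-planted genes flip to +/-1
#' with probability `noise_flip_rate`; up/down calls are emitted from the
#' final nonzero states.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_instance` list: `interactome` (tibble), `roles`
#'   (tibble from [classify_roles()]), `calls` (tibble `gene`, `direction`),
#'   `universe` (all gene symbols), `truth` (list: `planted_receptors`,
#'   `planted_edges`, `intended_states`, `final_states`), `config`.
#' @export
#' @examples
#' inst <- generate_instance(synthetic_config(seed = 42))
#' inst$truth$planted_receptors
generate_instance <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  n_inter <- config$n_genes - config$n_receptors - config$n_ligands - config$n_tfs
  receptors <- synth_names("R", config$n_receptors, config$n_receptors)
  ligands <- synth_names("L", config$n_ligands, config$n_ligands)
  tfs <- synth_names("T", config$n_tfs, config$n_tfs)
  inters <- synth_names("I", n_inter, n_inter)
  universe <- c(receptors, ligands, tfs, inters)

  draw_sign <- function(n) {
    ifelse(stats::runif(n) < config$inhibition_fraction, -1L, 1L)
  }

  # ---- plant node-disjoint pathways --------------------------------------
  planted_receptors <- sort(sample(receptors, config$k_planted))
  free_inter <- inters
  free_tfs <- tfs
  intended <- setNames(rep(0L, length(universe)), universe)
  planted_edges <- list()

  for (r in planted_receptors) {
    intended[r] <- 1L
    len <- sample1(config$path_len)
    chain <- if (len > 0) sample(free_inter, len) else character(0)
    free_inter <- setdiff(free_inter, chain)
    m <- sample1(config$tfs_per_pathway)
    leaf_tfs <- sample(free_tfs, m)
    free_tfs <- setdiff(free_tfs, leaf_tfs)

    prev <- r
    for (node in chain) {
      s <- draw_sign(1)
      intended[node] <- s * intended[prev]
      planted_edges[[length(planted_edges) + 1]] <-
        tibble(source = prev, target = node, sign = s)
      prev <- node
    }
    for (tf in leaf_tfs) {
      s <- draw_sign(1)
      intended[tf] <- s * intended[prev]
      planted_edges[[length(planted_edges) + 1]] <-
        tibble(source = prev, target = tf, sign = s)
    }
  }
  planted_edges <- bind_rows(planted_edges)

  # ---- random background edges -------------------------------------------
  key <- function(s, t, sg) paste(s, t, sg)
  seen <- key(planted_edges$source, planted_edges$target, planted_edges$sign)
  bg <- list()
  guard <- 0L
  while (length(bg) < config$extra_edges) {
    guard <- guard + 1L
    if (guard > 50L * config$extra_edges + 1000L) {
      abort("Could not place the requested number of background edges.")
    }
    st <- sample(universe, 2)
    s <- draw_sign(1)
    # keep planted routes the unique compatible ones: between two planted
    # genes, force the incompatible sign
    if (intended[st[1]] != 0L && intended[st[2]] != 0L &&
        s * intended[st[1]] == intended[st[2]]) {
      s <- -s
    }
    k <- key(st[1], st[2], s)
    if (k %in% seen) next
    seen <- c(seen, k)
    bg[[length(bg) + 1]] <- tibble(source = st[1], target = st[2], sign = s)
  }
  bg <- bind_rows(bg)

  interactome <- bind_rows(
    planted_edges %>% mutate(origin = "planted"),
    bg %>% mutate(origin = "background")
  ) %>%
    arrange(.data$source, .data$target, .data$sign)

  # ---- corruption and noise ----------------------------------------------
  final <- intended
  planted_genes <- names(intended)[intended != 0L]
  if (config$planted_corrupt_rate > 0) {
    zap <- stats::runif(length(planted_genes)) < config$planted_corrupt_rate
    final[planted_genes[zap]] <- 0L
  }
  nonplanted <- setdiff(universe, planted_genes)
  if (config$noise_flip_rate > 0) {
    flip <- stats::runif(length(nonplanted)) < config$noise_flip_rate
    final[nonplanted[flip]] <- sample(c(-1L, 1L), sum(flip), replace = TRUE)
  }

  calls <- tibble(
    gene = names(final)[final != 0L],
    direction = ifelse(final[final != 0L] == 1L, "up", "down")
  ) %>% arrange(.data$gene)

  structure(
    list(
      interactome = interactome,
      roles = classify_roles(universe, tfs = tfs, receptors = receptors,
                             ligands = ligands),
      calls = calls,
      universe = universe,
      truth = list(
        planted_receptors = planted_receptors,
        planted_edges = planted_edges %>%
          arrange(.data$source, .data$target, .data$sign),
        intended_states = intended,
        final_states = final
      ),
      config = config
    ),
    class = "synthetic_instance"
  )
}

#' Write a synthetic instance in the pipeline's input formats
#'
#' Emits exactly the files the real pipeline reads — interactome TSV,
#' expression call TSV, one role list per role — plus a ground-truth JSON,
#' so the pipeline is exercised through its public file interfaces.
#'
#' @param instance A `synthetic_instance`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_instance <- function(instance, dir) {
  stopifnot(inherits(instance, "synthetic_instance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    interactome = file.path(dir, "interactome.tsv"),
    expression = file.path(dir, "expression.tsv"),
    tf_list = file.path(dir, "tfs.txt"),
    receptor_list = file.path(dir, "receptors.txt"),
    ligand_list = file.path(dir, "ligands.txt"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_interactome(instance$interactome, paths["interactome"])
  readr::write_tsv(instance$calls, paths["expression"], progress = FALSE)
  writeLines(role_set(instance$roles, "tf"), paths["tf_list"])
  writeLines(role_set(instance$roles, "receptor"), paths["receptor_list"])
  writeLines(role_set(instance$roles, "ligand"), paths["ligand_list"])
  jsonlite::write_json(
    list(
      planted_receptors = instance$truth$planted_receptors,
      planted_edges = instance$truth$planted_edges,
      intended_states = as.list(instance$truth$intended_states),
      final_states = as.list(instance$truth$final_states)
    ),
    paths["truth"], auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(paths)
}

#' Score mediator recovery against the planted ground truth
#'
#' @param identified Character vector of identified mediators (root children
#'   present in the solution tree).
#' @param truth The `truth` element of a `synthetic_instance` (or any list
#'   with `planted_receptors`).
#' @return A one-row tibble (`precision`, `recall`, `f1`). Conventions for
#'   empty sets: empty identified and empty planted scores 1 everywhere;
#'   empty identified against a non-empty planted set scores 0 precision
#'   and recall; f1 is 0 whenever precision + recall is 0.
#' @export
#' @examples
#' evaluate_recovery(c("R01", "R09"),
#'                   list(planted_receptors = c("R01", "R02")))
evaluate_recovery <- function(identified, truth) {
  planted <- truth$planted_receptors
  identified <- unique(identified)
  hits <- length(intersect(identified, planted))
  precision <- if (length(identified) == 0) {
    if (length(planted) == 0) 1 else 0
  } else {
    hits / length(identified)
  }
  recall <- if (length(planted) == 0) 1 else hits / length(planted)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble(precision = precision, recall = recall, f1 = f1)
}

# drop terminals with no directed path from the root (used by the
# prize-collecting-style fallback of recovery_experiment and run_region)
drop_unreachable_terminals <- function(wnet) {
  g <- graph_index(wnet)
  reach <- dijkstra_from(g, g$root)$dist
  unreachable <- g$nodes[g$terminals[!is.finite(reach[g$terminals])]]
  wnet$terminals <- setdiff(wnet$terminals, unreachable)
  list(wnet = wnet, dropped = unreachable)
}

#' Planted-pathway recovery experiment
#'
#' The package's stand-in for a full re-analysis of real expression data:
#' for each replicate it generates an instance (seed = `config$seed` +
#' replicate - 1), booleanizes the emitted calls, builds the case-oriented
#' weighted network, solves the Steiner problem, takes the mediators (root
#' children used by the tree) and scores them against the planted
#' receptors. Solver errors are recorded per replicate, never fatal to the
#' batch.
#'
#' @param config A [synthetic_config()]; per-replicate seeds are derived
#'   from its `seed`.
#' @param n_replicates Number of replicates.
#' @param solver `"exact"`, `"heuristic"`, or `"brute"`.
#' @param params A [weight_params()]. The default `sign_consistency` scheme
#'   scores every planted edge high regardless of the downstream state sign,
#'   matching how the pathways are planted.
#' @param on_unreachable `"drop"` (default): terminals disconnected from
#'   every upregulated receptor (possible under state corruption) are
#'   dropped and counted, mirroring the prize-collecting fallback;
#'   `"error"`: the replicate records the solver error instead.
#' @param root_children Passed to [build_weighted_network()].
#' @return A tibble with one row per replicate (`replicate`, `seed`,
#'   `n_terminals`, `n_dropped_terminals`, `n_identified`, `precision`,
#'   `recall`, `f1`, `total_cost`, `error`) with a `"summary"` attribute: a
#'   one-row tibble of mean precision/recall/f1 over the replicates that
#'   produced a solution, plus `n_error`.
#' @export
#' @examples
#' \donttest{
#' recovery_experiment(synthetic_config(seed = 1), n_replicates = 2)
#' }
recovery_experiment <- function(config, n_replicates, solver = c("exact", "heuristic", "brute"),
                                params = weight_params(scheme = "sign_consistency"),
                                on_unreachable = c("drop", "error"),
                                root_children = c("receptors+ligands", "receptors")) {
  stopifnot(inherits(config, "synthetic_config"))
  solver <- match.arg(solver)
  on_unreachable <- match.arg(on_unreachable)
  root_children <- match.arg(root_children)

  solve_fn <- switch(solver,
    exact = exact_steiner,
    heuristic = heuristic_steiner,
    brute = brute_force_steiner
  )

  rows <- purrr::map(seq_len(n_replicates), function(i) {
    seed_i <- config$seed + i - 1L
    cfg_i <- config
    cfg_i$seed <- seed_i
    base <- tibble(
      replicate = i, seed = seed_i,
      n_terminals = NA_integer_, n_dropped_terminals = NA_integer_,
      n_identified = NA_integer_, precision = NA_real_, recall = NA_real_,
      f1 = NA_real_, total_cost = NA_real_, error = NA_character_
    )
    tryCatch({
      inst <- generate_instance(cfg_i)
      profile <- booleanize(inst$calls, inst$universe, region = "synthetic")
      wnet <- build_weighted_network(inst$interactome, profile, inst$roles,
                                     params, root_children)
      dropped <- character(0)
      if (on_unreachable == "drop") {
        d <- drop_unreachable_terminals(wnet)
        wnet <- d$wnet
        dropped <- d$dropped
        if (length(wnet$terminals) == 0) {
          abort("All terminals unreachable from the root.")
        }
      }
      sol <- solve_fn(wnet)
      identified <- sort(sol$tree_edges$target[sol$tree_edges$source == wnet$root])
      score <- evaluate_recovery(identified, inst$truth)
      base %>% mutate(
        n_terminals = length(wnet$terminals),
        n_dropped_terminals = length(dropped),
        n_identified = length(identified),
        precision = score$precision, recall = score$recall, f1 = score$f1,
        total_cost = sol$total_cost
      )
    }, error = function(e) {
      base %>% mutate(error = conditionMessage(e))
    })
  })
  out <- bind_rows(rows)
  ok <- is.na(out$error)
  attr(out, "summary") <- tibble(
    n_replicates = n_replicates,
    n_error = sum(!ok),
    mean_precision = mean(out$precision[ok]),
    mean_recall = mean(out$recall[ok]),
    mean_f1 = mean(out$f1[ok])
  )
  out
}

#' Summary of a recovery experiment
#'
#' @param x The tibble returned by [recovery_experiment()].
#' @return Its one-row summary tibble (means over successful replicates).
#' @export
recovery_summary <- function(x) {
  attr(x, "summary", exact = TRUE)
}
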