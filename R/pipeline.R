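# End-to-end orchestration: per region, run the case-oriented (constantly
# activated) and control-oriented (constantly inhibited) analyses, write the
# result files, and compare mediators across regions.

#' Assemble a validated pipeline configuration
#'
#' Inputs may be paths (read with the package readers) or in-memory tibbles
#' / character vectors, so the same configuration object drives both file
#' and programmatic use.
#'
#' @param interactome An interactome tibble or the path to a canonical
#'   interactome TSV (see [read_interactions()]).
#' @param expression Named list (region label -> call tibble or TSV path).
#' @param tfs,receptors,ligands Role annotations: character vectors or paths
#'   to one-symbol-per-line lists.
#' @param out_dir Output directory for result files.
#' @param params A [weight_params()].
#' @param solver `"exact"`, `"heuristic"`, or `"brute"`.
#' @param root_children Passed to [select_root_children()].
#' @param max_terminals,max_edges Solver caps (see [exact_steiner()],
#'   [brute_force_steiner()]).
#' @param pc_penalty Optional prize-collecting penalty (see
#'   [exact_steiner()]).
#' @param on_unreachable `"drop"` unreachable terminals (recorded) or
#'   `"error"` the phenotype run.
#' @param quiet Suppress progress messages.
#' @return A `run_config` list with all inputs materialized.
#' @export
run_config <- function(interactome, expression, tfs, receptors, ligands,
                       out_dir = tempfile("sustsig_run_"),
                       params = weight_params(),
                       solver = c("exact", "heuristic", "brute"),
                       root_children = c("receptors+ligands", "receptors"),
                       max_terminals = 12, max_edges = 18,
                       pc_penalty = NULL,
                       on_unreachable = c("drop", "error"),
                       quiet = FALSE) {
  solver <- match.arg(solver)
  root_children <- match.arg(root_children)
  on_unreachable <- match.arg(on_unreachable)
  load_tbl <- function(x, reader) if (is.character(x) && length(x) == 1) reader(x) else as_tibble(x)
  load_vec <- function(x) if (length(x) == 1 && file.exists(x)) read_role_list(x) else as.character(x)

  net <- load_tbl(interactome, read_interactions)
  assert_df_cols(net, c("source", "target", "sign"), "interactome")
  if (!"origin" %in% names(net)) net$origin <- "unknown"
  if (is.null(names(expression)) || any(names(expression) == "")) {
    abort("`expression` must be a named list: region label -> calls.")
  }
  calls <- purrr::map(expression, load_tbl, reader = read_calls)
  purrr::walk(calls, assert_df_cols, cols = c("gene", "direction"),
              what = "expression calls")

  structure(
    list(
      interactome = net,
      expression = calls,
      tfs = load_vec(tfs), receptors = load_vec(receptors),
      ligands = load_vec(ligands),
      out_dir = out_dir, params = params, solver = solver,
      root_children = root_children, max_terminals = max_terminals,
      max_edges = max_edges, pc_penalty = pc_penalty,
      on_unreachable = on_unreachable, quiet = quiet
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file names the input paths and options; relative paths are resolved
#' against the config file's directory. Recognized fields: `interactome`,
#' `expression` (mapping region -> path), `tfs`, `receptors`, `ligands`,
#' `out_dir`, `solver`, `scheme`, `p_high`, `p_low`, `root_edge_weight`,
#' `root_children`, `max_terminals`, `max_edges`, `pc_penalty`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base, p))
  }
  params <- weight_params(
    p_high = raw$p_high %||% 0.9,
    p_low = raw$p_low %||% 0.1,
    scheme = raw$scheme %||% "differential_activity",
    root_edge_weight = raw$root_edge_weight %||% raw$p_high %||% 0.9
  )
  run_config(
    interactome = resolve(raw$interactome),
    expression = purrr::map(raw$expression, resolve),
    tfs = resolve(raw$tfs), receptors = resolve(raw$receptors),
    ligands = resolve(raw$ligands),
    out_dir = raw$out_dir %||% tempfile("sustsig_run_"),
    params = params,
    solver = raw$solver %||% "exact",
    root_children = raw$root_children %||% "receptors+ligands",
    max_terminals = raw$max_terminals %||% 12,
    max_edges = raw$max_edges %||% 18,
    pc_penalty = raw$pc_penalty,
    on_unreachable = raw$on_unreachable %||% "drop",
    quiet = isTRUE(raw$quiet)
  )
}

solve_with <- function(config, wnet) {
  switch(config$solver,
    exact = exact_steiner(wnet, max_terminals = config$max_terminals,
                          pc_penalty = config$pc_penalty),
    heuristic = heuristic_steiner(wnet, pc_penalty = config$pc_penalty),
    brute = brute_force_steiner(wnet, max_edges = config$max_edges)
  )
}

say <- function(config, ...) {
  if (!isTRUE(config$quiet)) message(...)
}

#' Run both phenotype-oriented analyses for one region
#'
#' Executes the case-oriented run (constantly activated subnetworks: root
#' children are receptors/ligands upregulated in disease) and the
#' control-oriented run (constantly inhibited), writes per-run GraphML,
#' SIF and JSON manifests plus a per-region mediator TSV, and returns the
#' result bundle. A phenotype run that cannot start (for example no
#' upregulated receptor in that orientation) is reported as skipped with
#' its reason; the other run still completes.
#'
#' @param config A [run_config()].
#' @param region A region label present in `config$expression`.
#' @return A `region_bundle`: list with `region`, `runs` (per direction:
#'   `wnet`, `solution`, `subnetworks`, `files`, or `skipped` reason),
#'   `mediator_table`, `files`.
#' @export
run_region <- function(config, region) {
  stopifnot(inherits(config, "run_config"))
  if (!region %in% names(config$expression)) {
    abort(paste0("Region '", region, "' not present in the configuration."))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- config$expression[[region]]
  universe <- sort(union(interactome_nodes(config$interactome), calls$gene))
  case_profile <- booleanize(calls, universe, region = region)
  roles <- classify_roles(universe, tfs = config$tfs,
                          receptors = config$receptors,
                          ligands = config$ligands)
  report <- parse_report(config$interactome)
  if (!is.null(report)) {
    say(config, "[", region, "] interactome parse report: ",
        report$n_kept, " kept, ", report$n_skipped, " skipped")
  }

  runs <- list()
  for (phenotype in c("case", "control")) {
    direction <- label_direction(phenotype)
    run <- tryCatch({
      profile <- orient_for_phenotype(case_profile, phenotype)
      wnet <- build_weighted_network(config$interactome, profile, roles,
                                     config$params, config$root_children)
      dropped <- character(0)
      if (config$on_unreachable == "drop" && is.null(config$pc_penalty)) {
        d <- drop_unreachable_terminals(wnet)
        wnet <- d$wnet
        dropped <- d$dropped
        if (length(wnet$terminals) == 0) {
          abort("All terminals unreachable from the root.")
        }
      }
      say(config, "[", region, "/", direction, "] ",
          length(wnet$root_children), " root children, ",
          length(wnet$terminals), " terminals",
          if (length(dropped)) paste0(" (", length(dropped), " dropped as unreachable)") else "")
      sol <- solve_with(config, wnet)
      say(config, "[", region, "/", direction, "] solver ", sol$solver,
          ": cost ", format(sol$total_cost, digits = 6), ", ",
          nrow(sol$tree_edges), " edges")
      subnets <- decompose_by_receptor(sol, wnet, case_profile)
      stem <- file.path(config$out_dir, paste0(region, "_", direction))
      files <- c(
        graphml = paste0(stem, ".graphml"),
        sif = paste0(stem, ".sif"),
        manifest = paste0(stem, "_manifest.json")
      )
      write_graphml(wnet, files["graphml"], solution = sol,
                    profile = orient_for_phenotype(case_profile, phenotype),
                    roles = roles)
      write_sif(sol$tree_edges, files["sif"])
      write_solution_manifest(sol, wnet, files["manifest"])
      list(wnet = wnet, solution = sol, subnetworks = subnets,
           dropped_terminals = dropped, files = files)
    }, error = function(e) {
      say(config, "[", region, "/", direction, "] skipped: ",
          conditionMessage(e))
      list(skipped = conditionMessage(e))
    })
    runs[[direction]] <- run
  }

  mediator_table <- bind_rows(purrr::map(runs, function(r) {
    if (!is.null(r$skipped)) return(NULL)
    as_tibble(r$subnetworks) %>%
      select("mediator", "direction", "n_tfs_up", "n_tfs_down") %>%
      mutate(region = region, .before = 1)
  }))
  med_path <- file.path(config$out_dir, paste0(region, "_mediators.tsv"))
  readr::write_tsv(mediator_table, med_path, progress = FALSE)

  structure(
    list(region = region, runs = runs, mediator_table = mediator_table,
         files = c(mediators = med_path)),
    class = "region_bundle"
  )
}

#' Compare mediators across a set of region bundles
#'
#' Builds the cross-region overlap tables (one per direction) from the
#' mediator tables of [run_region()] bundles and writes them as TSV next to
#' the per-region outputs.
#'
#' @param bundles A list of `region_bundle` objects (at least one).
#' @param out_dir Directory for the overlap TSVs; defaults to the directory
#'   holding the first bundle's mediator table.
#' @return A list per direction (`constantly_activated`,
#'   `constantly_inhibited`): the `region_comparison` (or `NULL` when no
#'   region produced that direction), plus `tables` (the written tibbles)
#'   and `files`.
#' @export
run_compare <- function(bundles, out_dir = NULL) {
  if (length(bundles) < 1) abort("Need at least one region bundle.")
  stopifnot(all(vapply(bundles, inherits, TRUE, "region_bundle")))
  all_meds <- bind_rows(purrr::map(bundles, "mediator_table"))
  out_dir <- out_dir %||% dirname(bundles[[1]]$files[["mediators"]])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  out <- list(tables = list(), files = character(0))
  for (direction in c("constantly_activated", "constantly_inhibited")) {
    sub <- all_meds %>% filter(.data$direction == !!direction)
    if (nrow(sub) == 0) {
      out[[direction]] <- NULL
      next
    }
    cmp <- compare_regions(sub[, c("region", "mediator")])
    tab <- summarize_run(sub, cmp)
    path <- file.path(out_dir, paste0("overlap_", direction, ".tsv"))
    readr::write_tsv(tab$overlaps, path, progress = FALSE)
    out[[direction]] <- cmp
    out$tables[[direction]] <- tab
    out$files <- c(out$files, setNames(path, direction))
  }
  out
}
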