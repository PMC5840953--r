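# Decomposition of solution trees into per-receptor subnetworks and
# cross-region comparison of the inferred mediators.

#' Direction label of a phenotype-oriented run
#'
#' The case-oriented run attaches the root to receptors upregulated in
#' disease, so its subnetworks are interpreted as constantly activated under
#' the sustained stimulus; the control-oriented run (root children are the
#' receptors downregulated in disease) yields the constantly inhibited ones.
#'
#' @param run_phenotype `"case"` or `"control"`.
#' @return `"constantly_activated"` or `"constantly_inhibited"`.
#' @export
#' @examples
#' label_direction("case")
label_direction <- function(run_phenotype) {
  if (!is.character(run_phenotype) || length(run_phenotype) != 1 ||
      !run_phenotype %in% c("case", "control")) {
    abort("`run_phenotype` must be \"case\" or \"control\".")
  }
  c(case = "constantly_activated", control = "constantly_inhibited")[[run_phenotype]]
}

#' Decompose a solution tree into per-receptor subnetworks
#'
#' Each root child used by the tree (a mediator: receptor or ligand) heads
#' its own subtree; the tree property makes the decomposition unambiguous
#' (subtrees of distinct root children share no node except the root). TF
#' counts are always reported in disease-vs-control (case) orientation so
#' that activated and inhibited runs are directly comparable.
#'
#' @param sol A `steiner_solution`.
#' @param wnet The `weighted_network` it was computed on.
#' @param case_profile The case-oriented booleanized profile of the region.
#' @return A tibble with one row per mediator: `mediator`, `direction`
#'   (from [label_direction()] on the run phenotype), `n_tfs_up`,
#'   `n_tfs_down`, `tfs_up`, `tfs_down` (list-columns of symbols),
#'   `n_edges`, `edges` (list-column of edge tibbles).
#' @export
decompose_by_receptor <- function(sol, wnet, case_profile) {
  val <- validate_solution(wnet, sol)
  if (!all(val$pass)) {
    abort(paste0("Solution fails validation: ",
                 paste(val$check[!val$pass], collapse = ", "), "."))
  }
  if (!identical(profile_phenotype(case_profile), "case")) {
    abort("`case_profile` must be case-oriented (disease vs control).")
  }
  te <- sol$tree_edges
  direction <- label_direction(wnet$phenotype)
  mediators <- sort(te$target[te$source == wnet$root])
  covered <- setdiff(sol$terminals, sol$uncovered_terminals)

  rows <- purrr::map(mediators, function(med) {
    # collect the subtree hanging below this root child
    nodes <- med
    sub <- te[te$source != wnet$root, , drop = FALSE]
    edges <- sub[0, , drop = FALSE]
    repeat {
      hit <- sub$source %in% nodes & !(paste(sub$source, sub$target, sub$sign) %in%
                                         paste(edges$source, edges$target, edges$sign))
      if (!any(hit)) break
      edges <- bind_rows(edges, sub[hit, , drop = FALSE])
      nodes <- unique(c(nodes, sub$target[hit]))
    }
    tfs <- intersect(nodes, covered)
    states <- profile_state(case_profile, tfs)
    tibble(
      mediator = med,
      direction = direction,
      n_tfs_up = sum(states == 1L),
      n_tfs_down = sum(states == -1L),
      tfs_up = list(sort(tfs[states == 1L])),
      tfs_down = list(sort(tfs[states == -1L])),
      n_edges = nrow(edges),
      edges = list(as_tibble(edges))
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      mediator = character(), direction = character(),
      n_tfs_up = integer(), n_tfs_down = integer(),
      tfs_up = list(), tfs_down = list(), n_edges = integer(), edges = list()
    )
  }
  class(out) <- c("receptor_decomposition", class(out))
  out
}

#' Compare inferred mediators across regions
#'
#' Set algebra over the mediators identified per region (one direction at a
#' time): which mediators are shared by two or more regions and which are
#' region-specific, plus the full overlap-class table (every non-empty
#' combination of regions, as in a Venn diagram) for up to 6 regions.
#'
#' @param memberships A data frame with columns `region` and `mediator`
#'   (one row per mediator observed in a region), e.g. stacked
#'   [decompose_by_receptor()] results of one direction.
#' @return A `region_comparison`: list with `membership` (tibble `mediator`,
#'   `regions` list-column, `n_regions`, `status` shared/specific),
#'   `shared`, `specific` (character vectors), and `overlap_classes`
#'   (tibble `regions`, `n_mediators`, `mediators`).
#' @export
#' @examples
#' compare_regions(data.frame(
#'   region = c("HIP", "HIP", "EC"),
#'   mediator = c("EGFR", "FGFR1", "EGFR")
#' ))
compare_regions <- function(memberships) {
  assert_df_cols(memberships, c("region", "mediator"), "memberships")
  memberships <- as_tibble(memberships) %>%
    distinct(.data$region, .data$mediator)
  if (nrow(memberships) == 0 || length(unique(memberships$region)) < 1) {
    abort("Need at least one region with at least one mediator.")
  }
  k <- length(unique(memberships$region))
  if (k > 6) {
    abort("Overlap-class enumeration supports at most 6 regions.")
  }

  membership <- memberships %>%
    group_by(.data$mediator) %>%
    summarise(
      regions = list(sort(unique(.data$region))),
      n_regions = length(unique(.data$region)),
      .groups = "drop"
    ) %>%
    mutate(status = ifelse(.data$n_regions >= 2, "shared", "specific")) %>%
    arrange(.data$mediator)

  overlap_classes <- membership %>%
    mutate(regions_key = purrr::map_chr(.data$regions, paste, collapse = "&")) %>%
    group_by(.data$regions_key) %>%
    summarise(
      n_mediators = n(),
      mediators = list(sort(.data$mediator)),
      .groups = "drop"
    ) %>%
    rename(regions = "regions_key") %>%
    arrange(.data$regions)

  structure(
    list(
      membership = membership,
      shared = membership$mediator[membership$status == "shared"],
      specific = membership$mediator[membership$status == "specific"],
      overlap_classes = overlap_classes
    ),
    class = "region_comparison"
  )
}

#' @export
print.region_comparison <- function(x, ...) {
  cat("Cross-region mediator comparison:",
      length(x$shared), "shared,", length(x$specific), "region-specific\n")
  print(x$membership)
  invisible(x)
}

#' Report tables for a set of per-receptor subnetworks
#'
#' Emits the two tables the analysis is read through: the mediator table
#' (mediator, direction, up/down TF counts — the shape of the per-region
#' figure captions) and the cross-region overlap table. Deterministically
#' ordered, so identical inputs give byte-identical TSV output.
#'
#' @param subnetworks A `receptor_decomposition` tibble (possibly several
#'   regions / directions stacked, with a `region` column added).
#' @param comparison Optional `region_comparison`.
#' @return A list of tibbles: `mediators` and `overlaps` (the latter empty
#'   when no comparison is supplied).
#' @export
summarize_run <- function(subnetworks, comparison = NULL) {
  cols <- intersect(c("region", "mediator", "direction", "n_tfs_up", "n_tfs_down"),
                    names(subnetworks))
  mediators <- as_tibble(subnetworks)[, cols, drop = FALSE] %>%
    arrange(dplyr::across(dplyr::all_of(cols)))
  overlaps <- if (is.null(comparison)) {
    tibble(regions = character(), n_mediators = integer(),
           mediators = character())
  } else {
    comparison$overlap_classes %>%
      mutate(mediators = purrr::map_chr(.data$mediators, paste, collapse = ","))
  }
  list(mediators = mediators, overlaps = overlaps)
}

#' Bar chart of up/down TF counts per mediator
#'
#' @param object A `receptor_decomposition` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot receptor_decomposition
#' @export
autoplot.receptor_decomposition <- function(object, ...) {
  df <- as_tibble(object) %>%
    select("mediator", "direction", "n_tfs_up", "n_tfs_down") %>%
    tidyr::pivot_longer(c("n_tfs_up", "n_tfs_down"),
                        names_to = "tf_state", values_to = "n_tfs") %>%
    mutate(tf_state = ifelse(.data$tf_state == "n_tfs_up",
                             "upregulated TFs", "downregulated TFs"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mediator, y = .data$n_tfs,
                                   fill = .data$tf_state)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~direction, scales = "free_x") +
    ggplot2::labs(x = "mediator (root child in the solution tree)",
                  y = "TFs controlled", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Tile plot of mediator membership across regions
#'
#' @param comparison A `region_comparison`.
#' @return A ggplot object.
#' @export
plot_region_overlap <- function(comparison) {
  stopifnot(inherits(comparison, "region_comparison"))
  df <- comparison$membership %>%
    tidyr::unnest_longer("regions", values_to = "region")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$mediator,
                                   fill = .data$status)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
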