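# Booleanized differential expression and gene role classification.
#
# A profile is a tibble (gene, state) with state in {-1, 0, +1}, plus
# attributes `phenotype` ("case" or "control") and `region`. Genes absent
# from the table are 0 on lookup. States are always stored relative to the
# profile's phenotype: +1 means "upregulated in this phenotype".

new_profile <- function(genes, states, phenotype, region) {
  out <- tibble(gene = genes, state = as.integer(states)) %>%
    arrange(.data$gene)
  attr(out, "phenotype") <- phenotype
  attr(out, "region") <- region
  class(out) <- c("bool_profile", class(out))
  out
}

#' @export
print.bool_profile <- function(x, ...) {
  cat(
    "# Booleanized profile | phenotype:", profile_phenotype(x),
    "| region:", profile_region(x),
    sprintf(
      "| %d up, %d down, %d unchanged\n",
      sum(x$state == 1L), sum(x$state == -1L), sum(x$state == 0L)
    )
  )
  NextMethod()
}

#' Phenotype and region of a booleanized profile
#'
#' @param profile A profile from [booleanize()] or [orient_for_phenotype()].
#' @return The phenotype label (`"case"` / `"control"`) or region label.
#' @export
profile_phenotype <- function(profile) attr(profile, "phenotype", exact = TRUE)

#' @rdname profile_phenotype
#' @export
profile_region <- function(profile) attr(profile, "region", exact = TRUE)

#' Look up booleanized states with 0 default
#'
#' @param profile A booleanized profile.
#' @param genes Character vector of gene symbols.
#' @return Integer vector of states in \{-1, 0, +1\}; genes not covered by
#'   the profile are 0.
#' @export
profile_state <- function(profile, genes) {
  idx <- match(genes, profile$gene)
  out <- profile$state[idx]
  out[is.na(out)] <- 0L
  out
}

#' Read a differential-expression call table
#'
#' TSV with columns `gene` and `direction` (`up` / `down`), one region per
#' file. Duplicate rows for a gene with conflicting directions are rejected
#' by [booleanize()] downstream.
#'
#' @param path Path to the TSV file.
#' @return A tibble (`gene`, `direction`).
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE) %>%
    assert_df_cols(c("gene", "direction"), "call table")
}

#' Booleanize differential-expression calls over a gene universe
#'
#' Discretizes up/down calls to the three-state code the edge weighting
#' uses: upregulated genes become +1, downregulated -1, every other gene of
#' the universe 0. The result is case-oriented (+1 = upregulated in disease
#' versus control); use [orient_for_phenotype()] for the control-oriented
#' view.
#'
#' @param calls Data frame with columns `gene` and `direction` (`"up"` or
#'   `"down"`). A gene may appear only once; duplicates with conflicting
#'   directions are an error.
#' @param universe Character vector of all gene symbols under study
#'   (typically interactome nodes plus all called genes).
#' @param region Region label stored on the profile.
#' @return A case-oriented booleanized profile tibble (`gene`, `state`).
#' @export
#' @examples
#' booleanize(
#'   data.frame(gene = c("FGFR1", "ADAM17"), direction = c("up", "down")),
#'   universe = c("FGFR1", "ADAM17", "GRB2")
#' )
booleanize <- function(calls, universe, region = "unspecified") {
  assert_df_cols(calls, c("gene", "direction"), "calls")
  universe <- unique(trimws(universe))
  assert_no_root_symbol(universe, "universe")

  calls <- as_tibble(calls) %>%
    mutate(gene = trimws(.data$gene),
           direction = tolower(trimws(.data$direction))) %>%
    distinct()
  bad_dir <- setdiff(unique(calls$direction), c("up", "down"))
  if (length(bad_dir) > 0) {
    abort(paste0("Unknown call direction '", bad_dir[1],
                 "': expected 'up' or 'down'."))
  }
  dup <- calls$gene[duplicated(calls$gene)]
  if (length(dup) > 0) {
    abort(paste0("Conflicting duplicate calls for gene(s): ",
                 paste(unique(dup), collapse = ", "), "."))
  }
  outside <- setdiff(calls$gene, universe)
  if (length(outside) > 0) {
    abort(paste0("Called gene(s) outside the universe: ",
                 paste(outside, collapse = ", "), "."))
  }

  states <- setNames(rep(0L, length(universe)), universe)
  states[calls$gene] <- ifelse(calls$direction == "up", 1L, -1L)
  new_profile(universe, states, phenotype = "case", region = region)
}

#' Re-orient a booleanized profile to the other phenotype
#'
#' The two phenotypes of a differential comparison are mirror images: a gene
#' upregulated in disease is, by construction, downregulated in the control
#' phenotype. Orienting to the profile's own phenotype is the identity;
#' orienting to the other negates every state (0 stays 0). Involution.
#'
#' @param profile A booleanized profile.
#' @param phenotype `"case"` or `"control"`.
#' @return The re-oriented profile.
#' @export
orient_for_phenotype <- function(profile, phenotype) {
  if (!is.character(phenotype) || length(phenotype) != 1 ||
      !phenotype %in% c("case", "control")) {
    abort("`phenotype` must be \"case\" or \"control\".")
  }
  if (identical(profile_phenotype(profile), phenotype)) {
    return(profile)
  }
  new_profile(profile$gene, -profile$state, phenotype,
              profile_region(profile))
}

#' Classify universe genes into TF / receptor / ligand roles
#'
#' Intersects the universe with externally supplied annotation lists
#' (AnimalTFDB-style TF symbols, GO receptor-activity/plasma-membrane-style
#' receptor symbols, curated ligand symbols). Roles are not exclusive: a
#' gene present in several lists carries all of its roles.
#'
#' @param universe Character vector of gene symbols.
#' @param tfs,receptors,ligands Character vectors of annotated symbols.
#' @return A long tibble (`gene`, `role`) with `role` in
#'   `"tf"`, `"receptor"`, `"ligand"`; one row per membership.
#' @export
#' @examples
#' classify_roles(c("FGFR1", "NFKB1"), tfs = "NFKB1",
#'                receptors = c("FGFR1", "EGFR"), ligands = character())
classify_roles <- function(universe, tfs = character(),
                           receptors = character(), ligands = character()) {
  universe <- unique(trimws(universe))
  assert_no_root_symbol(c(tfs, receptors, ligands), "role lists")
  bind_rows(
    tibble(gene = intersect(universe, trimws(tfs)), role = "tf"),
    tibble(gene = intersect(universe, trimws(receptors)), role = "receptor"),
    tibble(gene = intersect(universe, trimws(ligands)), role = "ligand")
  ) %>%
    arrange(.data$role, .data$gene)
}

#' Read a plain-text role list
#'
#' One gene symbol per line; blank lines and `#` comments ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of symbols.
#' @export
read_role_list <- function(path) {
  x <- trimws(readLines(path))
  x[x != "" & !startsWith(x, "#")]
}

role_set <- function(roles, which) {
  assert_df_cols(roles, c("gene", "role"), "roles")
  sort(unique(roles$gene[roles$role %in% which]))
}

#' Terminal nodes: differentially expressed transcription factors
#'
#' The Steiner solver must connect the root to every differentially
#' expressed TF, so the terminal set is the TFs of the role annotation with
#' a nonzero booleanized state. Membership depends only on |state|, so the
#' set is identical for both phenotype orientations.
#'
#' @param profile A booleanized profile.
#' @param roles Role tibble from [classify_roles()].
#' @return Sorted character vector of terminal symbols. Hard error when
#'   empty: there is nothing to connect.
#' @export
select_terminals <- function(profile, roles) {
  tfs <- role_set(roles, "tf")
  out <- tfs[profile_state(profile, tfs) != 0L]
  if (length(out) == 0) {
    abort("No differentially expressed TF in the profile: no terminals to connect.")
  }
  sort(out)
}

#' Root children: upregulated receptors/ligands of the oriented phenotype
#'
#' The dummy stimulus node is connected to every receptor (and, by default,
#' ligand) that is upregulated in the phenotype being analyzed, so that any
#' root-to-TF path must pass through an upregulated sensor of the
#' environment. In the control orientation these are exactly the genes
#' downregulated in disease.
#'
#' @param profile A booleanized profile, already oriented to the phenotype
#'   under analysis.
#' @param roles Role tibble from [classify_roles()].
#' @param root_children `"receptors+ligands"` (default; the inclusive
#'   reading) or `"receptors"`.
#' @return Sorted character vector of root-child symbols. Hard error when
#'   empty: the root would be disconnected.
#' @export
select_root_children <- function(profile, roles,
                                 root_children = c("receptors+ligands", "receptors")) {
  root_children <- match.arg(root_children)
  pool <- if (root_children == "receptors") {
    role_set(roles, "receptor")
  } else {
    role_set(roles, c("receptor", "ligand"))
  }
  out <- pool[profile_state(profile, pool) == 1L]
  if (length(out) == 0) {
    abort(paste0(
      "No upregulated receptor/ligand in the ",
      profile_phenotype(profile) %||% "?",
      "-oriented profile: the root would be disconnected."
    ))
  }
  sort(out)
}
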