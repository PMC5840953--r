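# Signed directed interactome: parsing, merging, induction, serialization.
#
# An interactome is a tibble with columns
#   source, target : gene symbols (trimmed, case-sensitive)
#   sign           : integer +1 (activation) / -1 (inhibition)
#   origin         : free-text provenance tag
# keyed on (source, target, sign): duplicates are collapsed, opposite-sign
# parallel edges between the same ordered pair are retained.

#' Describe the column layout of an interaction table
#'
#' A dialect maps the columns of a tabular interaction export onto the
#' fields the pipeline needs (source, target, sign, optionally a separate
#' direction column) and declares which tokens mean activation and
#' inhibition. Rows without a resolvable direction or sign are skipped and
#' counted in the parse report; the method needs signal-flow direction, so
#' direction-ambiguous records are dropped rather than symmetrized.
#'
#' @param source,target Names of the columns holding the source and target
#'   gene symbols.
#' @param sign Name of the column holding the interaction sign token.
#' @param direction Optional name of a column holding a directedness flag;
#'   rows whose value is not in `directed_tokens` are skipped.
#' @param activation_tokens,inhibition_tokens Character vectors of tokens
#'   (matched case-insensitively after trimming) meaning activation (+1) and
#'   inhibition (-1). Numeric tables can use `"1"` / `"-1"`.
#' @param directed_tokens Tokens in `direction` marking a row as directed.
#' @param origin Provenance tag stored on every parsed edge.
#' @return A `sustsig_dialect` list.
#' @seealso [dialect_omnipath()], [dialect_reactomefi()],
#'   [parse_interactions()]
#' @export
#' @examples
#' interaction_dialect(
#'   source = "from", target = "to", sign = "effect",
#'   activation_tokens = "activate", inhibition_tokens = "inhibit"
#' )
interaction_dialect <- function(source = "source",
                                target = "target",
                                sign = "sign",
                                direction = NULL,
                                activation_tokens = c("activation", "activate", "1", "+1"),
                                inhibition_tokens = c("inhibition", "inhibit", "-1"),
                                directed_tokens = c("1", "true", "directed", "->", "yes"),
                                origin = "unknown") {
  structure(
    list(
      source = source, target = target, sign = sign, direction = direction,
      activation_tokens = tolower(trimws(activation_tokens)),
      inhibition_tokens = tolower(trimws(inhibition_tokens)),
      directed_tokens = tolower(trimws(directed_tokens)),
      origin = origin
    ),
    class = "sustsig_dialect"
  )
}

#' Built-in dialect for OmniPath-style exports
#'
#' Expects `source`, `target`, `is_directed`, and the consensus sign columns
#' `consensus_stimulation` / `consensus_inhibition` collapsed into a single
#' `sign` column is not assumed; instead the common flat export with
#' `is_stimulation` / `is_inhibition` folded to one token column named
#' `effect` is used. Rows flagged both or neither are skipped.
#'
#' @return A `sustsig_dialect`.
#' @export
dialect_omnipath <- function() {
  interaction_dialect(
    source = "source_genesymbol", target = "target_genesymbol",
    sign = "effect", direction = "is_directed",
    activation_tokens = c("stimulation", "1", "+1", "activation"),
    inhibition_tokens = c("inhibition", "-1"),
    origin = "omnipath"
  )
}

#' Built-in dialect for ReactomeFI-style exports
#'
#' Expects `Gene1`, `Gene2`, a `Direction` arrow column (`->`, `|-` style)
#' and a `Score`-free sign encoded in the arrow itself: `->` activation,
#' `-|` inhibition. Undirected arrows (`-`, `<->`) are skipped.
#'
#' @return A `sustsig_dialect`.
#' @export
dialect_reactomefi <- function() {
  interaction_dialect(
    source = "Gene1", target = "Gene2", sign = "Direction",
    activation_tokens = c("->", "activates"),
    inhibition_tokens = c("-|", "inhibits"),
    origin = "reactomefi"
  )
}

#' Parse an interaction table into a signed directed interactome
#'
#' Turns a raw data frame (as read from a TSV export) into the canonical
#' interactome tibble. Each row must resolve to a direction and a sign; rows
#' lacking either are skipped and tallied in the parse report attached as
#' the `"parse_report"` attribute (see [parse_report()]). Unknown non-blank
#' sign tokens are a hard error (they indicate a wrong dialect, not missing
#' data).
#'
#' @param data A data frame with at least the columns named by `dialect`.
#' @param dialect An [interaction_dialect()].
#' @return An interactome tibble (`source`, `target`, `sign`, `origin`),
#'   deduplicated on (source, target, sign), with a `"parse_report"`
#'   attribute.
#' @export
#' @examples
#' raw <- data.frame(
#'   source = c("TNF", "TNFRSF1A"), target = c("TNFRSF1A", "NFKB1"),
#'   sign = c("activate", "activate")
#' )
#' parse_interactions(raw, interaction_dialect(
#'   activation_tokens = "activate", inhibition_tokens = "inhibit"
#' ))
parse_interactions <- function(data, dialect = interaction_dialect()) {
  stopifnot(inherits(dialect, "sustsig_dialect"))
  needed <- c(dialect$source, dialect$target, dialect$sign, dialect$direction)
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "Mapped column(s) absent from the interaction table: ",
      paste0("'", missing, "'", collapse = ", "), "."
    ))
  }

  src <- trimws(as.character(data[[dialect$source]]))
  tgt <- trimws(as.character(data[[dialect$target]]))
  sign_tok <- tolower(trimws(as.character(data[[dialect$sign]])))

  n_rows <- nrow(data)
  keep <- rep(TRUE, n_rows)

  # direction filter: rows not asserted directed are dropped, never
  # symmetrized (the solver needs true signal flow)
  n_undirected <- 0L
  if (!is.null(dialect$direction)) {
    dir_tok <- tolower(trimws(as.character(data[[dialect$direction]])))
    directed <- dir_tok %in% dialect$directed_tokens
    n_undirected <- sum(!directed)
    keep <- keep & directed
  }

  is_act <- sign_tok %in% dialect$activation_tokens
  is_inh <- sign_tok %in% dialect$inhibition_tokens
  blank <- is.na(sign_tok) | sign_tok == "" | sign_tok == "na"
  unknown <- keep & !is_act & !is_inh & !blank
  if (any(unknown)) {
    abort(paste0(
      "Unknown sign token '", sign_tok[which(unknown)[1]],
      "' at row ", which(unknown)[1],
      "; declare it in the dialect or fix the table."
    ))
  }
  n_signless <- sum(keep & blank)
  keep <- keep & (is_act | is_inh)

  bad_symbol <- keep & (src == "" | tgt == "" | is.na(src) | is.na(tgt))
  n_bad_symbol <- sum(bad_symbol)
  keep <- keep & !bad_symbol

  assert_no_root_symbol(src[keep], "source column")

  edges <- tibble(
    source = src[keep],
    target = tgt[keep],
    sign = ifelse(is_act[keep], 1L, -1L),
    origin = dialect$origin
  ) %>%
    distinct(.data$source, .data$target, .data$sign, .keep_all = TRUE) %>%
    arrange(.data$source, .data$target, .data$sign)

  report <- tibble(
    n_rows = n_rows,
    n_kept = nrow(edges),
    n_skipped = n_undirected + n_signless + n_bad_symbol,
    n_undirected = n_undirected,
    n_signless = n_signless,
    n_bad_symbol = n_bad_symbol,
    n_duplicate = (n_rows - n_undirected - n_signless - n_bad_symbol) - nrow(edges)
  )
  attr(edges, "parse_report") <- report
  edges
}

#' Read a delimiter-separated interaction export
#'
#' Thin wrapper around [readr::read_tsv()] + [parse_interactions()].
#'
#' @param path Path to a TSV file with a header row.
#' @param dialect An [interaction_dialect()].
#' @return An interactome tibble; see [parse_interactions()].
#' @export
read_interactions <- function(path, dialect = interaction_dialect()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  parse_interactions(raw, dialect)
}

#' Retrieve the parse report of an interactome
#'
#' @param net An interactome returned by [parse_interactions()].
#' @return A one-row tibble with row counts: total, kept, skipped (split by
#'   reason: undirected, sign-less, malformed symbol) and collapsed
#'   duplicates, or `NULL` if `net` carries no report.
#' @export
parse_report <- function(net) {
  attr(net, "parse_report", exact = TRUE)
}

#' Merge two interactomes into one set of unique interactions
#'
#' Union keyed on (source, target, sign): an identical record present in
#' both inputs is stored once, with the provenance tags of both
#' concatenated (`"a+b"`). Records that differ only in sign remain distinct
#' parallel edges. Commutative up to origin tag order.
#'
#' @param a,b Interactome tibbles.
#' @return The merged interactome tibble.
#' @export
#' @examples
#' a <- parse_interactions(data.frame(source = "A", target = "B", sign = "1"))
#' b <- parse_interactions(data.frame(source = "A", target = "B", sign = "-1"))
#' merge_interactomes(a, b)
merge_interactomes <- function(a, b) {
  assert_df_cols(a, c("source", "target", "sign", "origin"), "a")
  assert_df_cols(b, c("source", "target", "sign", "origin"), "b")
  bind_rows(as_tibble(a), as_tibble(b)) %>%
    group_by(.data$source, .data$target, .data$sign) %>%
    summarise(
      origin = paste(unique(.data$origin), collapse = "+"),
      .groups = "drop"
    ) %>%
    arrange(.data$source, .data$target, .data$sign)
}

#' Restrict an interactome to a gene set
#'
#' Keeps exactly the edges with both endpoints in `genes` (for example the
#' genes actually measured on the expression platform).
#'
#' @param net An interactome tibble.
#' @param genes Character vector of gene symbols.
#' @return The induced interactome tibble.
#' @export
induce_subgraph <- function(net, genes) {
  assert_df_cols(net, c("source", "target", "sign"), "net")
  net %>%
    filter(.data$source %in% genes, .data$target %in% genes) %>%
    as_tibble()
}

#' All gene symbols appearing in an interactome
#'
#' @param net An interactome tibble.
#' @return Sorted character vector: the union of edge endpoints.
#' @export
interactome_nodes <- function(net) {
  assert_df_cols(net, c("source", "target"), "net")
  sort(unique(c(net$source, net$target)))
}

#' Write an interactome as canonical TSV
#'
#' Columns `source`, `target`, `sign`, `origin`; readable back with
#' [read_interactions()] under the default dialect.
#'
#' @param net An interactome tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(net, path) {
  assert_df_cols(net, c("source", "target", "sign", "origin"), "net")
  readr::write_tsv(net[, c("source", "target", "sign", "origin")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write an edge list in SIF format
#'
#' One line per edge: `source activates|inhibits target`.
#'
#' @param net A tibble with `source`, `target`, `sign` columns (an
#'   interactome or the `tidy()` of a solution).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  assert_df_cols(net, c("source", "target", "sign"), "net")
  rel <- ifelse(net$sign > 0, "activates", "inhibits")
  writeLines(paste(net$source, rel, net$target), path)
  invisible(path)
}
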