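test_that("parsing maps sign tokens and skips unresolvable rows", {
  dia <- interaction_dialect(activation_tokens = "activate",
                             inhibition_tokens = "inhibit", origin = "db1")
  out <- parse_interactions(
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
               sign = c("activate", "inhibit", "activate")),
    dia
  )
  expect_equal(nrow(out), 3)
  expect_setequal(out$sign, c(1L, -1L, 1L))
  expect_equal(out$sign[match(paste(out$source, out$target), c("A B", "B C", "C D"))],
               c(1L, -1L, 1L))

  empty <- parse_interactions(
    data.frame(source = character(), target = character(), sign = character()),
    dia
  )
  expect_equal(nrow(empty), 0)
  expect_equal(parse_report(empty)$n_skipped, 0)

  with_blank <- parse_interactions(
    data.frame(source = c("A", "B", "C", "D"), target = c("B", "C", "D", "E"),
               sign = c("activate", "", "inhibit", "activate")),
    dia
  )
  expect_equal(nrow(with_blank), 3)
  expect_equal(parse_report(with_blank)$n_skipped, 1)
  expect_equal(parse_report(with_blank)$n_signless, 1)
})

test_that("parsing fails hard on missing columns and unknown sign tokens", {
  dia <- interaction_dialect()
  expect_error(
    parse_interactions(data.frame(source = "A", target = "B"), dia),
    "sign"
  )
  expect_error(
    parse_interactions(
      data.frame(source = c("A", "B"), target = c("B", "C"),
                 sign = c("1", "banana")),
      dia
    ),
    "row 2"
  )
})

test_that("direction-ambiguous rows are dropped, not symmetrized, and counted", {
  dia <- interaction_dialect(direction = "is_directed")
  out <- parse_interactions(
    data.frame(source = c("A", "B"), target = c("B", "C"),
               sign = c("1", "1"), is_directed = c("1", "0")),
    dia
  )
  expect_equal(nrow(out), 1)
  expect_equal(out$source, "A")
  expect_equal(parse_report(out)$n_undirected, 1)
})

test_that("merging keeps unique (source, target, sign) keys", {
  mk <- function(df, origin) {
    parse_interactions(df, interaction_dialect(origin = origin))
  }
  a <- mk(data.frame(source = "A", target = "B", sign = "1"), "db1")
  b <- mk(data.frame(source = "A", target = "B", sign = "1"), "db2")
  m <- merge_interactomes(a, b)
  expect_equal(nrow(m), 1)
  expect_equal(m$origin, "db1+db2")

  b2 <- mk(data.frame(source = "A", target = "B", sign = "-1"), "db2")
  expect_equal(nrow(merge_interactomes(a, b2)), 2)

  a5 <- mk(data.frame(source = letters[1:5], target = LETTERS[1:5],
                      sign = rep("1", 5)), "db1")
  empty <- mk(data.frame(source = character(), target = character(),
                         sign = character()), "db2")
  m2 <- merge_interactomes(a5, empty)
  expect_equal(m2[, c("source", "target", "sign")],
               a5[, c("source", "target", "sign")], ignore_attr = TRUE)
})

test_that("merge is idempotent, bounded, and commutative up to origin", {
  set.seed(11)
  for (i in 1:5) {
    df1 <- data.frame(
      source = sample(LETTERS[1:6], 8, replace = TRUE),
      target = sample(LETTERS[1:6], 8, replace = TRUE),
      sign = sample(c("1", "-1"), 8, replace = TRUE)
    )
    df2 <- data.frame(
      source = sample(LETTERS[1:6], 8, replace = TRUE),
      target = sample(LETTERS[1:6], 8, replace = TRUE),
      sign = sample(c("1", "-1"), 8, replace = TRUE)
    )
    a <- parse_interactions(df1, interaction_dialect(origin = "x"))
    b <- parse_interactions(df2, interaction_dialect(origin = "y"))
    key <- function(n) paste(n$source, n$target, n$sign)

    self <- merge_interactomes(a, a)
    expect_equal(key(self), key(a))

    m <- merge_interactomes(a, b)
    expect_lte(nrow(m), nrow(a) + nrow(b))
    shared <- length(intersect(key(a), key(b)))
    expect_equal(nrow(m), nrow(a) + nrow(b) - shared)

    m_rev <- merge_interactomes(b, a)
    expect_equal(key(m), key(m_rev))
  }
})

test_that("induced subgraphs keep exactly the edges inside the gene set", {
  net <- parse_interactions(
    data.frame(source = c("A", "B"), target = c("B", "C"), sign = c("1", "1"))
  )
  expect_equal(nrow(induce_subgraph(net, c("A", "B"))), 1)
  expect_equal(induce_subgraph(net, c("A", "B"))$target, "B")
  expect_equal(
    induce_subgraph(net, interactome_nodes(net))[, c("source", "target", "sign")],
    net[, c("source", "target", "sign")], ignore_attr = TRUE
  )
  expect_equal(nrow(induce_subgraph(net, character())), 0)
})

test_that("TSV round trip preserves the edge key set; SIF uses the verb form", {
  net <- parse_interactions(
    data.frame(source = c("A", "A", "B"), target = c("B", "B", "C"),
               sign = c("1", "-1", "1"))
  )
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_interactome(net, tsv)
  back <- read_interactions(tsv)
  key <- function(n) sort(paste(n$source, n$target, n$sign))
  expect_equal(key(back), key(net))

  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  expect_setequal(readLines(sif),
                  c("A activates B", "A inhibits B", "B activates C"))
})

test_that("the reserved root symbol is rejected in inputs", {
  expect_error(
    parse_interactions(data.frame(source = root_node(), target = "B", sign = "1")),
    "ROOT"
  )
})
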