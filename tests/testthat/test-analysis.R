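toy_decomposition <- function() {
  # ROOT -> R1 -> {T1 (up), T2 (down)}, ROOT -> R2 -> T3 (up)
  wnet <- make_wnet(
    tibble::tribble(
      ~source,     ~target, ~sign, ~weight,
      root_node(), "R1",    1L,    0.9,
      root_node(), "R2",    1L,    0.9,
      "R1",        "T1",    1L,    0.9,
      "R1",        "T2",    -1L,   0.9,
      "R2",        "T3",    1L,    0.9
    ),
    terminals = c("T1", "T2", "T3")
  )
  profile <- booleanize(
    data.frame(gene = c("R1", "R2", "T1", "T2", "T3"),
               direction = c("up", "up", "up", "down", "up")),
    universe = c("R1", "R2", "T1", "T2", "T3"),
    region = "toy"
  )
  sol <- exact_steiner(wnet)
  list(wnet = wnet, profile = profile, sol = sol)
}

test_that("trees decompose into per-receptor subnetworks with case-oriented counts", {
  d <- toy_decomposition()
  dec <- decompose_by_receptor(d$sol, d$wnet, d$profile)
  expect_equal(dec$mediator, c("R1", "R2"))
  expect_equal(dec$n_tfs_up, c(1L, 1L))
  expect_equal(dec$n_tfs_down, c(1L, 0L))
  expect_equal(dec$tfs_up[[1]], "T1")
  expect_equal(dec$tfs_down[[1]], "T2")
  expect_equal(unique(dec$direction), "constantly_activated")
  # every covered terminal lives in exactly one subtree
  expect_equal(sum(dec$n_tfs_up + dec$n_tfs_down), length(d$sol$terminals))
})

test_that("a single root child owns every terminal", {
  wnet <- make_wnet(
    tibble::tribble(
      ~source,     ~target, ~weight,
      root_node(), "R1",    0.9,
      "R1",        "T1",    0.9,
      "R1",        "T2",    0.9
    ),
    terminals = c("T1", "T2")
  )
  profile <- booleanize(
    data.frame(gene = c("R1", "T1", "T2"), direction = c("up", "up", "down")),
    universe = c("R1", "T1", "T2")
  )
  dec <- decompose_by_receptor(exact_steiner(wnet), wnet, profile)
  expect_equal(nrow(dec), 1)
  expect_equal(dec$n_tfs_up + dec$n_tfs_down, 2L)
})

test_that("a dual-role receptor-TF directly under the root heads its own subnetwork", {
  wnet <- make_wnet(
    tibble::tibble(source = root_node(), target = "RT1", weight = 0.9),
    terminals = "RT1"
  )
  profile <- booleanize(data.frame(gene = "RT1", direction = "up"),
                        universe = "RT1")
  dec <- decompose_by_receptor(exact_steiner(wnet), wnet, profile)
  expect_equal(dec$mediator, "RT1")
  expect_equal(dec$n_tfs_up, 1L)
})

test_that("control-oriented runs report TF counts in disease orientation", {
  # disease-downregulated receptor and TF: the control-oriented run uses them
  wnet <- make_wnet(
    tibble::tribble(
      ~source,     ~target, ~weight,
      root_node(), "R1",    0.9,
      "R1",        "T1",    0.9
    ),
    terminals = "T1", phenotype = "control"
  )
  case_profile <- booleanize(
    data.frame(gene = c("R1", "T1"), direction = c("down", "down")),
    universe = c("R1", "T1")
  )
  dec <- decompose_by_receptor(exact_steiner(wnet), wnet, case_profile)
  expect_equal(dec$direction, "constantly_inhibited")
  expect_equal(dec$n_tfs_down, 1L) # down in disease, not negated
  expect_equal(dec$n_tfs_up, 0L)
})

test_that("run direction labels map case/control to activated/inhibited", {
  expect_equal(label_direction("case"), "constantly_activated")
  expect_equal(label_direction("control"), "constantly_inhibited")
  expect_false(label_direction("case") == label_direction("control"))
  expect_error(label_direction("placebo"), "case")
})

test_that("cross-region comparison separates shared from specific mediators", {
  cmp <- compare_regions(data.frame(
    region = c("A", "A", "B"),
    mediator = c("EGFR", "FGFR1", "EGFR")
  ))
  expect_equal(cmp$shared, "EGFR")
  expect_equal(cmp$specific, "FGFR1")

  same4 <- compare_regions(data.frame(
    region = rep(c("A", "B", "C", "D"), each = 2),
    mediator = rep(c("EGFR", "TNFRSF1A"), 4)
  ))
  expect_setequal(same4$shared, c("EGFR", "TNFRSF1A"))
  expect_equal(unique(same4$membership$n_regions), 4L)

  disjoint <- compare_regions(data.frame(
    region = paste0("R", 1:6), mediator = paste0("M", 1:6)
  ))
  expect_length(disjoint$shared, 0)
  expect_equal(nrow(disjoint$overlap_classes), 6)

  expect_error(compare_regions(data.frame(
    region = paste0("R", 1:7), mediator = paste0("M", 1:7)
  )), "6")
})

test_that("comparison is invariant to region order", {
  df <- data.frame(
    region = c("A", "B", "B", "C"),
    mediator = c("EGFR", "EGFR", "SORT1", "PPP2CA")
  )
  a <- compare_regions(df)
  b <- compare_regions(df[sample(nrow(df)), ])
  expect_equal(a$membership, b$membership)
  expect_equal(a$overlap_classes, b$overlap_classes)
})

test_that("summaries have the caption shape and are byte-deterministic", {
  d <- toy_decomposition()
  dec <- decompose_by_receptor(d$sol, d$wnet, d$profile)
  cmp <- compare_regions(data.frame(region = "toy", mediator = dec$mediator))
  tabs <- summarize_run(dec, cmp)
  expect_named(tabs$mediators, c("mediator", "direction", "n_tfs_up", "n_tfs_down"))
  expect_equal(nrow(tabs$mediators), 2)

  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tabs$mediators, f1)
  readr::write_tsv(summarize_run(dec, cmp)$mediators, f2)
  expect_identical(readLines(f1), readLines(f2))

  empty <- summarize_run(dec[0, ], NULL)
  expect_equal(nrow(empty$overlaps), 0)
})

test_that("plots build without error", {
  d <- toy_decomposition()
  dec <- decompose_by_receptor(d$sol, d$wnet, d$profile)
  p1 <- ggplot2::autoplot(dec)
  expect_s3_class(p1, "ggplot")
  cmp <- compare_regions(data.frame(region = c("A", "B"),
                                    mediator = c("R1", "R1")))
  p2 <- plot_region_overlap(cmp)
  expect_s3_class(p2, "ggplot")
})
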