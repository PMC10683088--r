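dia <- fx_ont("diabetes.onto")

test_that("contradictory literals: disjoint classes, intervals, bridging", {
  lit <- function(txt) {
    suppressWarnings(parse_strategy(sprintf("L: %s -> gets(x,Metformin)", txt),
                                    dia))$statements[[1]]$premise
  }
  # declared disjoint diagnoses on one variable
  expect_equal(contradictory_literals(lit("DiabetesType1(x)"),
                                      lit("DiabetesType2(x)"), dia),
               "contradictory")
  # overlapping half-lines are compatible
  expect_equal(contradictory_literals(lit("hasFBST(x,i), equalOrGreaterThan(i,1.26)"),
                                      lit("hasFBST(x,i), equalOrGreaterThan(i,1.00)"),
                                      dia),
               "compatible")
  # complementary inclusive comparisons conflict under strict boundary semantics
  expect_equal(contradictory_literals(lit("hasFBST(x,i), equalOrGreaterThan(i,1.26)"),
                                      lit("hasFBST(x,j), equalOrLessThan(j,1.26)"),
                                      dia),
               "contradictory")
  expect_equal(contradictory_literals(lit("hasFBST(x,i), equalOrGreaterThan(i,1.26)"),
                                      lit("hasFBST(x,j), equalOrLessThan(j,1.26)"),
                                      dia, cfg = sc_config(strict_boundary = FALSE)),
               "compatible")
  # the measurement pattern contradicts the other diagnosis once the
  # diagnostic rule bridges it to the disjoint class
  s10 <- fx_rules("conflicts.rules", dia)$statements$S10
  l1 <- lit("hasFBST(x,i), equalOrGreaterThan(i,1.26), hasSymptomsT2(x,True)")
  l2 <- lit("DiabetesType1(x)")
  expect_equal(contradictory_literals(l1, l2, dia, statements = list(s10)),
               "contradictory")
  expect_equal(contradictory_literals(l1, l2, dia), "compatible")
})

test_that("the conflict corpus yields one strong and two probable conflicts", {
  s <- fx_rules("conflicts.rules", dia)
  rep <- run_pipeline(s, dia)
  recs <- rep$phases$conflicts
  key <- function(r) paste(sort(r$members), collapse = "+")
  kinds <- stats::setNames(vapply(recs, `[[`, character(1), "kind"),
                           vapply(recs, key, character(1)))
  expect_equal(kinds[["S10+S14"]], "conflict_strong")
  expect_equal(kinds[["S11+S15"]], "conflict_probable")
  expect_equal(kinds[["S10+S13"]], "conflict_probable")
  cases <- stats::setNames(vapply(recs, `[[`, character(1), "case"),
                           vapply(recs, key, character(1)))
  expect_equal(cases[["S11+S15"]], "case1")
  expect_equal(cases[["S10+S13"]], "case2")
  # probable conflicts are saved, never deleted
  expect_true(all(c("S11", "S15", "S13") %in% strategy_ids(rep$strategy)))
  expect_false(is.null(kb_is_known(rep$kb, "conflict_probable", c("S15", "S11"))))
})

test_that("strong-conflict victim selection follows the policy", {
  s <- fx_rules("conflicts.rules", dia)
  rep_def <- run_pipeline(s, dia)  # both statements original: later one goes
  expect_true("S14" %in% rep_def$deleted)
  rep_none <- run_pipeline(s, dia, cfg = sc_config(strong_conflict_policy = "delete_none"))
  expect_length(rep_none$deleted, 0)
  # an added clone is preferred as victim over an original, whatever the order
  s2 <- stratcheck:::new_strategy(list(
    local({ x <- s$statements$S14; x$provenance <- "added"; x$ordinal <- 1L; x }),
    local({ x <- s$statements$S10; x$ordinal <- 2L; x })), "pair")
  g2 <- build_graph(s2, dia)
  res <- detect_conflicts(s2, group_statements(g2), dia, cfg = sc_config())
  expect_equal(sub("deleted:", "", res$records[[1]]$action), "S14")
})

test_that("corresponding premises with different constant conclusions are saved", {
  ml <- fx_ont("meals.onto")
  rep <- run_pipeline(fx_rules("ex14.rules", ml), ml)
  recs <- rep$phases$conflicts
  expect_length(recs, 1)
  expect_equal(recs[[1]]$kind, "conflict_probable")
  expect_setequal(recs[[1]]$members, c("S22", "S22C"))
  expect_equal(recs[[1]]$action, "saved_for_expert")
  entry <- kb_is_known(rep$kb, "conflict_probable", c("S22C", "S22"))
  expect_equal(entry$status, "pending_expert")
})

test_that("conflict records are invariant under statement order", {
  txt <- readLines(fx_path("conflicts.rules"))
  txt <- txt[!grepl("^#", txt) & nzchar(trimws(txt))]
  key_set <- function(rep) sort(vapply(rep$phases$conflicts, function(r)
    paste(sort(r$members), collapse = "+"), character(1)))
  rep1 <- run_pipeline(parse_strategy(txt, dia), dia,
                       cfg = sc_config(strong_conflict_policy = "delete_none"))
  rep2 <- run_pipeline(parse_strategy(rev(txt), dia), dia,
                       cfg = sc_config(strong_conflict_policy = "delete_none"))
  expect_identical(key_set(rep1), key_set(rep2))
})

test_that("an expert false-positive verdict suppresses re-detection", {
  ml <- fx_ont("meals.onto")
  s <- fx_rules("ex14.rules", ml)
  rep1 <- run_pipeline(s, ml)
  kb <- rep1$kb
  key <- kb_entries(kb)$key[[1]]
  kb <- kb_set_status(kb, key, "false_positive")$kb
  rep2 <- run_pipeline(s, ml, kb = kb)
  expect_length(rep2$phases$conflicts, 0)
})
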