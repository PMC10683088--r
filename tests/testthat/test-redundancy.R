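food <- fx_ont("food.onto")
dia <- fx_ont("diabetes.onto")

test_that("equivalence resolution keeps one phrasing per worked case", {
  s <- fx_rules("ex4.rules", food)
  g <- build_graph(s, food)
  res <- resolve_equivalence(s, group_statements(g), food)
  expect_setequal(strategy_ids(res$strategy), "S01")
  by_victim <- stats::setNames(
    vapply(res$records, `[[`, character(1), "case"),
    vapply(res$records, function(r) sub("deleted:", "", r$action), character(1)))
  expect_equal(by_victim[["S02"]], "case1")
  expect_equal(by_victim[["S03"]], "case2.1")
  expect_equal(by_victim[["S04"]], "case2.2")
})

test_that("subsumption deletes the larger and the specialised premises", {
  s <- fx_rules("ex5.rules", food)
  # simple case: S06 restates S05 with extra atoms
  pair <- stratcheck:::new_strategy(s$statements[c("S05", "S06")], "pair")
  g <- build_graph(pair, food)
  res <- resolve_subsumption(pair, group_statements(g), g, food)
  expect_setequal(strategy_ids(res$strategy), "S05")
  expect_equal(res$records[[1]]$kind, "subsumption_simple")
  # semantic case: each sub-property specialisation goes independently
  quad <- stratcheck:::new_strategy(s$statements[c("S05", "S07", "S08", "S09")], "quad")
  g2 <- build_graph(quad, food)
  res2 <- resolve_subsumption(quad, group_statements(g2), g2, food)
  expect_setequal(strategy_ids(res2$strategy), "S05")
  expect_true(all(vapply(res2$records, `[[`, character(1), "kind")
                  == "subsumption_semantic"))
  # disjoint conclusions: nothing to do
  other <- parse_strategy(c("N1: Patient(x) -> eats(x,x)",
                            "N2: Patient(x), Food(y) -> hasFood(x,y)"), food)
  g3 <- build_graph(other, food)
  res3 <- resolve_subsumption(other, group_statements(g3), g3, food)
  expect_length(res3$records, 0)
})

test_that("the composed diagnosis rule is deleted as transitive", {
  s <- fx_rules("ex6.rules", dia)
  g <- build_graph(s, dia)
  res <- resolve_transitivity(s, g, group_statements(g), dia)
  expect_setequal(strategy_ids(res$strategy), c("S10", "S11"))
  expect_equal(res$records[[1]]$members, c("S12", "S10", "S11"))
})

test_that("a shortcut whose conclusion differs from the chain tail survives", {
  s <- parse_strategy(c(
    "S10: Person(x), hasFBST(x,i), equalOrGreaterThan(i,1.26), hasSymptomsT2(x,True) -> DiabetesType2(x)",
    "S11: DiabetesType2(x) -> gets(x,Metformin)",
    "S12: Person(x), hasFBST(x,i), equalOrGreaterThan(i,1.26), hasSymptomsT2(x,True) -> gets(x,Insulin)"),
    dia)
  g <- build_graph(s, dia)
  res <- resolve_transitivity(s, g, group_statements(g), dia)
  expect_length(res$records, 0)
  expect_setequal(strategy_ids(res$strategy), c("S10", "S11", "S12"))
})

test_that("a shortcut with a laxer threshold than its chain survives", {
  s <- parse_strategy(c(
    "S10: Person(x), hasFBST(x,i), equalOrGreaterThan(i,1.26), hasSymptomsT2(x,True) -> DiabetesType2(x)",
    "S11: DiabetesType2(x) -> gets(x,Metformin)",
    "S12: Person(x), hasFBST(x,i), equalOrGreaterThan(i,1.00), hasSymptomsT2(x,True) -> gets(x,Metformin)"),
    dia)
  g <- build_graph(s, dia)
  res <- resolve_transitivity(s, g, group_statements(g), dia)
  # boundary witnesses at 1.00 fire S12 but not the chain
  expect_true("S12" %in% strategy_ids(res$strategy))
})

test_that("redundancy removal preserves derivable knowledge on the fixtures", {
  for (nm in c("ex4", "ex5", "ex6")) {
    ont <- fx_ont(FIXTURE_SETS[[nm]][[2]])
    s <- fx_rules(FIXTURE_SETS[[nm]][[1]], ont)
    rep <- run_pipeline(s, ont)
    seed <- strategy_seed_store(s, ont)
    before <- forward_chain(unname(s$statements), seed, ont)$store
    after <- forward_chain(unname(rep$strategy$statements), seed, ont)$store
    expect_true(facts_match_up_to_hierarchy(before, after, ont), info = nm)
  }
})

test_that("illegal property values are flagged without deletion", {
  s <- suppressWarnings(parse_strategy(c(
    "I1: Person(x), age(x,-3) -> DiabetesType2(x)",
    "I2: Person(x), age(x,47) -> DiabetesType2(x)",
    "I3: Person(x) -> hasSymptomsT2(x,Maybe)"), dia))
  recs <- check_illegal_values(s, dia)
  expect_length(recs, 2)  # -3 out of range; Maybe outside the enumeration
  expect_setequal(vapply(recs, `[[`, character(1), "members"), c("I1", "I3"))
  expect_true(all(vapply(recs, `[[`, character(1), "action") == "saved_for_expert"))
  clean <- parse_strategy("I2: Person(x), age(x,47) -> DiabetesType2(x)", dia)
  expect_length(check_illegal_values(clean, dia), 0)
})
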