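dia <- fx_ont("diabetes.onto")

test_that("comparison builtins honour inclusive and strict boundaries", {
  expect_true(eval_builtin("GE", 185, 180))
  expect_true(eval_builtin("GE", 1.26, 1.26))
  expect_false(eval_builtin("GT", 20, 20))
  expect_true(eval_builtin("LT", 19.9, 20))
  expect_true(eval_builtin("NE", "a", "b"))
  expect_true(eval_builtin("EQ", "2.0", "2"))
  expect_error(eval_builtin("GE", "abc", 1), "numeric")
})

test_that("premise matching honours the class and property closures", {
  st <- fx_rules("ex6.rules", dia)$statements
  store <- fact_store(list(list(predicate = "DiabetesType2", args = "p1")))
  b <- match_premise(st$S11$premise, store, dia)
  expect_equal(b, list(list(x = "p1")))
  # disjoint-premise statement matches nothing on a store without a shared member
  s30 <- fx_rules("s30.rules", dia)$statements$S30
  store2 <- fact_store(list(list(predicate = "DiabetesType1", args = "p1"),
                            list(predicate = "DiabetesType2", args = "p2")))
  expect_length(match_premise(s30$premise, store2, dia), 0)
  expect_length(match_premise(st$S11$premise, fact_store(), dia), 0)
  # a subclass member satisfies a superclass atom
  food <- fx_ont("food.onto")
  sf <- parse_strategy("F1: Food(y) -> Food(y)", food)$statements$F1
  store3 <- fact_store(list(list(predicate = "Lunch", args = "l1")))
  expect_equal(match_premise(sf$premise, store3, food), list(list(y = "l1")))
})

test_that("forward chaining reaches the drug-category fixpoint", {
  dr <- fx_ont("drugs.onto")
  s7 <- fx_rules("ex7.rules", dr)
  store <- fact_store(list(
    list(predicate = "Drug", args = "d1"), list(predicate = "Drug", args = "d2"),
    list(predicate = "Drug", args = "d3"),
    list(predicate = "hasCategory", args = c("d1", "c")),
    list(predicate = "hasEquivalent", args = c("d1", "d2")),
    list(predicate = "hasEquivalent", args = c("d3", "d2"))))
  run <- forward_chain(unname(s7$statements), store, dr)
  expect_true(run$reached_fixpoint)
  keys <- names(run$store$facts)
  expect_true(all(c("hasCategory(d2,c)", "includes(c,d2)", "hasCategory(d3,c)")
                  %in% keys))
})

test_that("the diagnosis chain derives the prescription and stops", {
  st <- fx_rules("ex6.rules", dia)$statements
  store <- fact_store(list(list(predicate = "Person", args = "p1"),
                           list(predicate = "hasFBST", args = c("p1", "1.30")),
                           list(predicate = "hasSymptomsT2", args = c("p1", "True"))))
  run <- forward_chain(list(st$S10, st$S11), store, dia)
  expect_true(run$reached_fixpoint)
  expect_true("DiabetesType2(p1)" %in% names(run$store$facts))
  expect_true("gets(p1,Metformin)" %in% names(run$store$facts))
  # empty statement list: unchanged store, fixpoint in round one
  run0 <- forward_chain(list(), store, dia, max_rounds = 5)
  expect_equal(stratcheck:::store_size(run0$store), stratcheck:::store_size(store))
  expect_true(run0$reached_fixpoint)
  expect_equal(run0$rounds_used, 1L)
})

test_that("chaining is monotone, order-independent and sound", {
  st <- fx_rules("ex6.rules", dia)$statements
  store <- fact_store(list(list(predicate = "Person", args = "p1"),
                           list(predicate = "hasFBST", args = c("p1", "1.30")),
                           list(predicate = "hasSymptomsT2", args = c("p1", "True"))))
  runs <- lapply(list(list(st$S10, st$S11), list(st$S11, st$S10)),
                 function(sts) forward_chain(sts, store, dia))
  for (run in runs) {
    expect_true(all(names(store$facts) %in% names(run$store$facts)))  # monotone
  }
  expect_setequal(names(runs[[1]]$store$facts), names(runs[[2]]$store$facts))
  # soundness: every inferred fact is re-derivable from the final store
  final <- runs[[1]]$store
  for (f in stratcheck:::derived_facts(final)) {
    sid <- sub("^inferred\\((.*)\\)$", "\\1", f$derivation)
    bindings <- match_premise(st[[sid]]$premise, final, dia)
    grounded <- unlist(lapply(bindings, function(b)
      vapply(stratcheck:::ground_conclusion(st[[sid]]$conclusion, b, sid),
             stratcheck:::fact_key, character(1))))
    expect_true(stratcheck:::fact_key(f) %in% grounded)
  }
})

test_that("unsafe statements are skipped with a warning", {
  food <- fx_ont("food.onto")
  bad <- suppressWarnings(parse_strategy("B1: Patient(x) -> eats(x,z)", food))
  store <- fact_store(list(list(predicate = "Patient", args = "p1")))
  expect_warning(run <- forward_chain(unname(bad$statements), store, food),
                 "unsafe")
  expect_equal(stratcheck:::store_size(run$store), 1L)
})
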