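food <- fx_ont("food.onto")
ex4 <- fx_rules("ex4.rules", food)

test_that("correspondence reproduces the worked premise pairs", {
  st <- ex4$statements
  expect_equal(parts_correspond(st$S01$premise, st$S02$premise, food)$status, "exact")
  c21 <- parts_correspond(st$S01$premise, st$S03$premise, food)
  expect_equal(c21$status, "semantic")
  expect_equal(c21$substitutions[[1]]$relation, "ancestor")
  expect_equal(parts_correspond(st$S01$premise, st$S04$conclusion, food)$status, "none")
})

test_that("correspondence status is symmetric and constants never unify", {
  st <- ex4$statements
  pairs <- utils::combn(names(st), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- st[[pairs[1, k]]]$premise; b <- st[[pairs[2, k]]]$premise
    expect_equal(parts_correspond(a, b, food)$status,
                 parts_correspond(b, a, food)$status)
  }
  dia <- fx_ont("diabetes.onto")
  two <- parse_strategy(c(
    "T1: Person(x), hasFBST(x,i), equalOrGreaterThan(i,1.26) -> DiabetesType2(x)",
    "T2: Person(x), hasFBST(x,i), equalOrLessThan(i,1.26) -> DiabetesType2(x)",
    "T3: Person(x), hasFBST(x,i), equalOrGreaterThan(i,2.00) -> DiabetesType2(x)"), dia)
  st2 <- two$statements
  # differing builtin operator or threshold blocks correspondence
  expect_equal(parts_correspond(st2$T1$premise, st2$T2$premise, dia)$status, "none")
  expect_equal(parts_correspond(st2$T1$premise, st2$T3$premise, dia)$status, "none")
})

test_that("exact correspondence matches brute-force bijection enumeration", {
  ont <- parse_ontology(c("class A", "class B", "class C",
                          "objprop p domain A range B",
                          "objprop q domain B range C",
                          "dataprop d domain A range decimal[0..9]"))
  set.seed(23)
  rand_part <- function(vars) {
    n <- sample(2:4, 1)
    atoms <- character(n)
    for (i in seq_len(n)) {
      kind <- sample(c("cls", "p", "q", "d"), 1)
      v1 <- sample(vars, 1); v2 <- sample(vars, 1)
      atoms[[i]] <- switch(kind,
        cls = sprintf("%s(%s)", sample(c("A", "B", "C"), 1), v1),
        p = sprintf("p(%s,%s)", v1, v2),
        q = sprintf("q(%s,%s)", v1, v2),
        d = sprintf("d(%s,%s)", v1, sample(c("3", "7"), 1)))
    }
    paste(atoms, collapse = ", ")
  }
  for (rep in 1:40) {
    pa_txt <- rand_part(c("x", "y", "z"))
    pb_txt <- rand_part(c("u", "v", "w"))
    s <- suppressWarnings(  # random premises need not bind the carrier head
      parse_strategy(c(sprintf("P1: %s -> A(x)", pa_txt),
                       sprintf("P2: %s -> A(u)", pb_txt)), ont))
    pa <- s$statements$P1$premise; pb <- s$statements$P2$premise
    got <- parts_correspond(pa, pb, ont, mode = "exact_only")$status == "exact"
    expect_equal(got, brute_exact_correspond(pa, pb),
                 info = paste(pa_txt, "||", pb_txt))
  }
})

test_that("integer builtin normalisation equates >=21 with >20 only when enabled", {
  sm <- fx_ont("smoking.onto")
  st <- fx_rules("ex15.rules", sm)$statements
  expect_equal(parts_correspond(st$R08$premise, st$R08b$premise, sm)$status, "none")
  on_ <- parts_correspond(st$R08$premise, st$R08b$premise, sm,
                          normalize_integer_builtins = TRUE)
  expect_equal(on_$status, "exact")
})
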