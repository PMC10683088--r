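test_that("native schema loads with symmetric and involutive closures", {
  ont <- parse_ontology(c(
    "class DiabetesType1",
    "class DiabetesType1 disjoint DiabetesType2",
    "class DiabetesType2",
    "objprop hasFood domain DiabetesType1 range DiabetesType2",
    "objprop hasLunch < hasFood",
    "objprop isGreaterThan inverse isLessThan",
    "objprop isLessThan"))
  # disjointness declared one way holds both ways
  expect_true("DiabetesType1" %in% ont$classes$DiabetesType2$disjoints)
  expect_equal(entity_relation("DiabetesType2", "DiabetesType1", "class", ont),
               "disjoint")
  # sub-property declared with < resolves through the hierarchy
  expect_equal(entity_relation("hasLunch", "hasFood", "property", ont), "descendant")
  # inverse is involutive
  expect_equal(ont$properties$isLessThan$inverse, "isGreaterThan")
})

test_that("dangling references and bad declarations fail with the entity named", {
  expect_error(parse_ontology("objprop p domain Foo"), "Foo")
  expect_error(parse_ontology(c("class A", "class A < A")), "cyclic")
  expect_error(parse_ontology(c("class A < B", "class B < A")), "cyclic")
  expect_error(parse_ontology(c("class A", "class B < A", "class A disjoint B")),
               "disjoint")
})

test_that("entity_relation reproduces the worked class pairs", {
  ont <- parse_ontology(c("class Person", "class Car",
                          "objprop hasCar domain Person range Car"))
  expect_equal(entity_relation("Person", "Person", "class", ont), "equal")
  expect_equal(entity_relation("Person", "Car", "class", ont), "none")
  food <- fx_ont("food.onto")
  expect_equal(entity_relation("hasFood", "hasLunch", "property", food), "ancestor")
  expect_error(entity_relation("Person", "Nope", "class", ont), "unknown")
})

test_that("entity_relation agrees with a brute-force closure on random taxonomies", {
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(5:30, 1)
    nms <- sprintf("N%02d", seq_len(n))
    lines <- sprintf("class %s", nms)
    parents <- stats::setNames(vector("list", n), nms)
    equivs <- stats::setNames(vector("list", n), nms)
    disjoints <- stats::setNames(vector("list", n), nms)
    for (i in seq(2, n)) if (stats::runif(1) < 0.7) {
      p <- nms[[sample(i - 1, 1)]]
      lines <- c(lines, sprintf("class %s < %s", nms[[i]], p))
      parents[[nms[[i]]]] <- c(parents[[nms[[i]]]], p)
    }
    ont <- parse_ontology(lines)
    for (k in 1:25) {
      ab <- sample(nms, 2, replace = TRUE)
      expect_equal(entity_relation(ab[[1]], ab[[2]], "class", ont),
                   brute_relation(ab[[1]], ab[[2]], parents, equivs, disjoints),
                   info = paste(ab, collapse = " vs "))
    }
    # symmetry invariants on the same taxonomy
    for (k in 1:10) {
      ab <- sample(nms, 2)
      r1 <- entity_relation(ab[[1]], ab[[2]], "class", ont)
      r2 <- entity_relation(ab[[2]], ab[[1]], "class", ont)
      flip <- c(equal = "equal", equivalent = "equivalent", ancestor = "descendant",
                descendant = "ancestor", disjoint = "disjoint", none = "none")
      expect_equal(r2, unname(flip[[r1]]))
    }
    expect_equal(entity_relation(nms[[1]], nms[[1]], "class", ont), "equal")
  }
})

test_that("referenced_classes follows the atom kind", {
  ont <- parse_ontology(c("class Person", "class Car",
                          "objprop hasCar domain Person range Car",
                          "dataprop age domain Person range integer[0..150]"))
  cls <- function(txt) {
    s <- suppressWarnings(  # the carrier head need not bind anything
      parse_strategy(sprintf("T1: %s -> Person(p1)", txt), ont))
    referenced_classes(s$statements[[1]]$premise[[1]], ont)
  }
  expect_equal(cls("Person(p1)"), "Person")
  expect_setequal(cls("hasCar(p,c)"), c("Person", "Car"))
  expect_equal(cls("age(p,47)"), "Person")
  expect_equal(cls("equalOrGreaterThan(i,1.26)"), character())
})

test_that("linking_properties honours hierarchy on either end", {
  food <- fx_ont("food.onto")
  ont <- parse_ontology(c("class Patient", "class Food",
                          "objprop eats domain Patient range Food"))
  got <- linking_properties("Patient", "Food", ont)
  expect_equal(got$property, "eats")
  expect_equal(got$link, "direct")
  none <- linking_properties("Food", "Patient", ont)
  expect_equal(nrow(none), 0)
  # range Food is a superclass of the destination Lunch: hierarchical link
  viasub <- linking_properties("Patient", "Lunch", food)
  expect_true("hasFood" %in% viasub$property)
  expect_equal(viasub$link[viasub$property == "hasFood"], "hierarchical")
})

test_that("check_value_legal separates illegal, legal and indeterminate", {
  ont <- parse_ontology(c("class Person",
                          "dataprop age domain Person range integer[0..150]",
                          "dataprop note domain Person"))
  expect_false(check_value_legal("age", -3, ont))
  expect_true(check_value_legal("age", 47, ont))
  expect_true(is.na(check_value_legal("note", 47, ont)))
  expect_error(check_value_legal("nope", 1, ont), "unknown")
})
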