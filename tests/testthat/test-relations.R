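person_car <- parse_ontology(c("class Person", "class Car",
                               "objprop hasCar domain Person range Car"))
pc_atoms <- local({
  s <- suppressWarnings(
    parse_strategy("W1: hasCar(p,c) -> Person(p1)", person_car))$statements[[1]]
  list(person = s$conclusion[[1]], hascar = s$premise[[1]])
})

test_that("the worked atom pair weighs 1 through the (Person,Person) equality", {
  w <- atom_pair_weight(pc_atoms$person, pc_atoms$hascar, person_car)
  expect_identical(w, 1)
  # the equal pair contributes weight 1, the unrelated pair 0
  rw <- stratcheck:::relation_weight
  expect_identical(rw(entity_relation("Person", "Person", "class", person_car),
                      sc_config()), 1)
  expect_identical(rw(entity_relation("Person", "Car", "class", person_car),
                      sc_config()), 0)
})

test_that("unrelated atoms weigh 0 and hierarchy weighs the table value", {
  ont <- parse_ontology(c("class Person", "class Car"))
  s <- suppressWarnings(
    parse_strategy("W2: Car(c) -> Person(p1)", ont))$statements[[1]]
  expect_identical(atom_pair_weight(s$conclusion[[1]], s$premise[[1]], ont), 0)
  food <- fx_ont("food.onto")
  s2 <- parse_strategy("W3: hasFood(x,y) -> hasLunch(x,y)", food)$statements[[1]]
  w <- atom_pair_weight(s2$conclusion[[1]], s2$premise[[1]], food)
  expect_identical(w, 1)  # Patient-Patient equality dominates
  # builtins reference no class
  dia <- fx_ont("diabetes.onto")
  s3 <- parse_strategy("W4: equalOrGreaterThan(i,1.26), hasFBST(x,i) -> DiabetesType2(x)", dia)$statements[[1]]
  expect_identical(atom_pair_weight(s3$conclusion[[1]], s3$premise[[1]], dia), 0)
})

test_that("conclusion-premise confidence picks the consuming direction", {
  dia <- fx_ont("diabetes.onto")
  st <- fx_rules("ex6.rules", dia)$statements
  r <- cp_confidence(st$S10, st$S11, dia)
  expect_equal(r$src, "S10"); expect_equal(r$dst, "S11")
  expect_identical(r$confidence, 1)
  # no shared vocabulary: zero confidence
  ont <- parse_ontology(c("class A", "class B"))
  two <- parse_strategy(c("U1: A(x) -> A(x)", "U2: B(x) -> B(x)"), ont)
  expect_identical(cp_confidence(two$statements$U1, two$statements$U2, ont)$confidence, 0)
})

test_that("conclusion-conclusion confidence follows declared linking properties", {
  ont <- parse_ontology(c("class Patient", "class Food", "class Verdict",
                          "class Menu",
                          "objprop eats domain Patient range Food",
                          "objprop about domain Verdict range Patient"))
  # unbound-variable warnings suppressed: these rules are only carriers of
  # conclusions for the scoring test
  s <- suppressWarnings(
    parse_strategy(c("V1: eats(x,y) -> Verdict(v), about(v,x)",
                     "V2: Patient(x) -> Food(y2), Menu(m)"), ont))
  r <- cc_confidence(s$statements$V1, s$statements$V2, ont)
  # conclusion of V2 references Food; about/eats link Verdict,Patient -> Patient,Food
  expect_equal(r$technique, "CC")
  expect_gt(r$confidence, 0)
  ont2 <- parse_ontology(c("class A", "class B"))
  s2 <- parse_strategy(c("Z1: A(x) -> A(x)", "Z2: B(x) -> B(x)"), ont2)
  expect_identical(cc_confidence(s2$statements$Z1, s2$statements$Z2, ont2)$confidence, 0)
})

test_that("filtering keeps the highest coefficient-weighted product", {
  cfg <- sc_config()
  mk <- function(cd, tech, tie = FALSE)
    stratcheck:::new_relation("X", "Y", cd, tech, tie)
  win <- filter_relation(mk(0.8, "CP"), mk(0.5, "CC"), cfg)
  expect_equal(win$technique, "CC")  # 0.5*1 beats 0.8*0.5
  expect_equal(win$product, 0.5)
  win2 <- filter_relation(mk(1.0, "CP"), mk(0, "CC"), cfg)
  expect_equal(win2$technique, "CP")
  expect_equal(win2$product, 0.5)
  expect_null(filter_relation(mk(0, "CP"), mk(0, "CC"), cfg))
  # equal products prefer the conclusion-conclusion technique
  win3 <- filter_relation(mk(1.0, "CP"), mk(0.5, "CC"), cfg)
  expect_equal(win3$technique, "CC")
})

test_that("the dependency graph recovers the worked chain and cycle", {
  dia <- fx_ont("diabetes.onto")
  g6 <- build_graph(fx_rules("ex6.rules", dia), dia)
  expect_true(stratcheck:::has_edge(g6, "S10", "S11"))
  dr <- fx_ont("drugs.onto")
  g7 <- build_graph(fx_rules("ex7.rules", dr), dr)
  expect_true(stratcheck:::has_edge(g7, "St01", "St02"))
  expect_true(stratcheck:::has_edge(g7, "St02", "St03"))
  expect_true(stratcheck:::has_edge(g7, "St03", "St01"))
  # unrelated statements give an edgeless graph
  ont <- parse_ontology(c("class A", "class B"))
  g0 <- build_graph(parse_strategy(c("Z1: A(x) -> A(x)", "Z2: B(x) -> B(x)"), ont), ont)
  expect_equal(nrow(g0$edges), 0)
})

test_that("build_graph is invariant under permutations of the strategy file", {
  dia <- fx_ont("diabetes.onto")
  txt <- readLines(fx_path("conflicts.rules"))
  txt <- txt[!grepl("^#", txt) & nzchar(trimws(txt))]
  g1 <- build_graph(parse_strategy(txt, dia), dia)
  set.seed(5)
  for (k in 1:3) {
    g2 <- build_graph(parse_strategy(sample(txt), dia), dia)
    key <- function(g) sort(sprintf("%s>%s:%s:%.3f", g$edges$src, g$edges$dst,
                                    g$edges$technique, g$edges$confidence))
    expect_identical(key(g2), key(g1))
  }
})

test_that("grouping is a partition whose members carry the group signature", {
  dia <- fx_ont("diabetes.onto")
  s <- fx_rules("conflicts.rules", dia)
  g <- build_graph(s, dia)
  groups <- group_statements(g)
  members <- unname(unlist(lapply(groups, `[[`, "members")))
  expect_setequal(members, g$nodes)
  expect_equal(anyDuplicated(members), 0L)
  for (gr in groups) {
    sigs <- lapply(gr$members, function(v)
      list(p = setdiff(stratcheck:::graph_preds(g, v), gr$members),
           s = setdiff(stratcheck:::graph_succs(g, v), gr$members)))
    for (sg in sigs) expect_identical(sg, sigs[[1]])
  }
  # the conflict corpus groups parallel diagnoses together
  mem <- attr(groups, "membership")
  expect_equal(mem[["S10"]], mem[["S14"]])
  expect_equal(mem[["S11"]], mem[["S15"]])
  expect_false(mem[["S10"]] == mem[["S11"]])
})

test_that("an edgeless graph yields singleton groups", {
  ont <- parse_ontology(c("class A", "class B", "class C"))
  s <- parse_strategy(c("Z1: A(x) -> A(x)", "Z2: B(x) -> B(x)", "Z3: C(x) -> C(x)"),
                      ont)
  groups <- group_statements(build_graph(s, ont))
  expect_length(groups, 3)
  expect_true(all(lengths(lapply(groups, `[[`, "members")) == 1))
})

test_that("graph and group exports are written", {
  dr <- fx_ont("drugs.onto")
  g <- build_graph(fx_rules("ex7.rules", dr), dr)
  dot <- tempfile(fileext = ".dot"); gml <- tempfile(fileext = ".graphml")
  grp <- tempfile(fileext = ".json")
  export_graph(g, dot, "dot")
  export_graph(g, gml, "graphml")
  export_groups(group_statements(g), grp)
  expect_true(any(grepl("St01", readLines(dot))))
  expect_true(any(grepl("graphml", readLines(gml))))
  expect_true(jsonlite::validate(paste(readLines(grp), collapse = "")))
})
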