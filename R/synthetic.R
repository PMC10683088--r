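# Synthetic verification cases: a layered, anomaly-free base strategy plus
# constructively injected anomalies with exact ground-truth labels, emulating
# the evaluation protocol of consistent curated rule bases perturbed by known
# edits. Base statements are class-mediated chains (each statement consumes a
# stage class and concludes its own fresh stage class), which keeps the
# dependency graph exactly the designed DAG and makes the base a fixed point
# of the pipeline by construction.

#' Configuration for the synthetic case generator
#'
#' Defaults emulate the mid-sized evaluation scenario: 24 base statements in
#' 3 layers with 8 redundant, 4 cycle-forming, 8 conflicting and 3
#' inaccessible injected statements.
#'
#' @param seed integer seed; generation is bit-for-bit reproducible.
#' @param n_statements number of base statements.
#' @param chain_depth number of layers in the base chain.
#' @param n_classes,n_properties minimum ontology sizes (padded with inert
#'   declarations when the structural classes/properties fall short).
#' @param injections named integer vector of injected-statement counts per
#'   anomaly kind: `equiv_case1`, `equiv_case2a`, `equiv_case2b`,
#'   `subsump_simple`, `subsump_semantic`, `transitive`, `cycle_real`,
#'   `cycle_fake` (statement counts; loops need at least 3 statements),
#'   `conflict_strong`, `conflict_probable1` (pairs of 2), `conflict_probable2`,
#'   `inaccessible`, `illegal_value`.
#' @return a `gen_config` list.
#' @export
gen_config <- function(seed = 1L, n_statements = 24L, chain_depth = 3L,
                       n_classes = 30L, n_properties = 10L,
                       injections = c(equiv_case1 = 2L, equiv_case2a = 1L,
                                      equiv_case2b = 1L, subsump_simple = 2L,
                                      subsump_semantic = 1L, transitive = 1L,
                                      cycle_real = 0L, cycle_fake = 4L,
                                      conflict_strong = 4L,
                                      conflict_probable1 = 2L,
                                      conflict_probable2 = 2L,
                                      inaccessible = 3L, illegal_value = 0L)) {
  all_kinds <- c("equiv_case1", "equiv_case2a", "equiv_case2b", "subsump_simple",
                 "subsump_semantic", "transitive", "cycle_real", "cycle_fake",
                 "conflict_strong", "conflict_probable1", "conflict_probable2",
                 "inaccessible", "illegal_value")
  inj <- setNames(rep(0L, length(all_kinds)), all_kinds)
  inj[names(injections)] <- as.integer(injections)
  stopifnot(n_statements >= chain_depth, chain_depth >= 2, all(inj >= 0))
  for (ck in c("cycle_real", "cycle_fake"))
    if (inj[[ck]] %in% c(1L, 2L))
      stop("cycle injections need at least 3 statements per loop")
  if (inj[["conflict_probable1"]] %% 2L != 0L)
    stop("conflict_probable1 counts statements and must be even (pairs)")
  structure(list(seed = as.integer(seed), n_statements = as.integer(n_statements),
                 chain_depth = as.integer(chain_depth),
                 n_classes = as.integer(n_classes),
                 n_properties = as.integer(n_properties),
                 injections = inj),
            class = "gen_config")
}

# split n cycle-forming statements into loop sizes >= 3 (4 stays one loop)
loop_sizes <- function(n) {
  sizes <- integer()
  while (n >= 3L) {
    s <- if (n == 4L) 4L else 3L
    sizes <- c(sizes, s)
    n <- n - s
  }
  if (n != 0L) stop("cycle statement count cannot be partitioned into loops >= 3")
  sizes
}

#' Generate a synthetic verification case
#'
#' Builds the ontology (native text), the base strategy, the injected
#' statements (provenance `added`) and a ground-truth table labelling every
#' injected statement with its anomaly kind, partner statements and expected
#' pipeline action.
#'
#' @param cfg a [gen_config()].
#' @return list with `ont` (`sc_ontology`), `strategy` (`sc_strategy`,
#'   base + injected), `truth` (data.frame: `id`, `kind`, `partners`,
#'   `expected`), `ontology_text`, `strategy_text`.
#' @export
generate_case <- function(cfg = gen_config()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  d <- cfg$chain_depth
  per <- diff(round(seq(0, cfg$n_statements, length.out = d + 1)))
  onto <- character()   # ontology lines
  rules <- character()  # base strategy lines
  added <- character()  # injected strategy lines
  truth <- list()

  # layer-1 source classes and per-statement stage classes
  n_roots <- max(2L, ceiling(per[[1]] / 2))
  roots <- sprintf("C1_%d", seq_len(n_roots))
  onto <- c(onto, sprintf("class %s", roots))

  sid <- 0L
  stmts <- list()  # bookkeeping: id, layer, prem_class, concl_class, dataprop, thr
  for (k in seq_len(d)) {
    stage <- sprintf("C%d_%d", k + 1L, seq_len(per[[k]]))
    # source classes for this layer: cover every previous conclusion when the
    # layer is large enough (so statements are not isolated in the graph),
    # keep the first conclusion single-consumer (for the transitivity chain),
    # and draw any surplus from the remaining conclusions
    srcs <- if (k == 1L) sample(roots, per[[k]], replace = TRUE) else {
      prev <- Filter(function(s) s$layer == k - 1L, stmts)
      pc <- vapply(prev, `[[`, character(1), "concl")
      m <- per[[k]]
      if (length(pc) == 1L) rep(pc, m)
      else if (m >= length(pc))
        c(pc[[1L]], sample(pc[-1L]),
          if (m > length(pc)) sample(pc[-1L], m - length(pc), replace = TRUE))
      else c(pc[[1L]], sample(pc[-1L], m - 1L))
    }
    for (i in seq_len(per[[k]])) {
      sid <- sid + 1L
      id <- sprintf("S%02d", sid)
      src <- srcs[[i]]
      concl <- stage[[i]]
      onto <- c(onto, sprintf("class %s", concl))
      if (k == 1L) {
        dp <- sprintf("m%02d", sid)
        thr <- round(stats::runif(1, 10, 90), 1)
        onto <- c(onto, sprintf("dataprop %s domain %s range decimal[0..100]", dp, src))
        rules <- c(rules, sprintf("%s: %s(x), %s(x,v), GE(v,%s) -> %s(x)",
                                  id, src, dp, format(thr), concl))
        stmts[[id]] <- list(id = id, layer = k, prem = src, concl = concl,
                            dataprop = dp, thr = thr)
      } else {
        rules <- c(rules, sprintf("%s: %s(x) -> %s(x)", id, src, concl))
        stmts[[id]] <- list(id = id, layer = k, prem = src, concl = concl,
                            dataprop = NA, thr = NA)
      }
    }
  }

  inj <- cfg$injections
  aid <- 0L
  next_id <- function() { aid <<- aid + 1L; sprintf("A%02d", aid) }
  label <- function(id, kind, partners, expected)
    truth[[length(truth) + 1]] <<- data.frame(
      id = id, kind = kind, partners = paste(partners, collapse = ","),
      expected = expected, stringsAsFactors = FALSE)
  pick <- function(pool) stmts[[sample(names(pool), 1L)]]
  consumed <- unique(vapply(Filter(function(s) s$layer > 1L, stmts),
                            `[[`, character(1), "prem"))
  # clone-based injections must target statements with graph arcs, otherwise
  # the clone pair is isolated and group pruning never examines it
  layer1 <- Filter(function(s) s$layer == 1L && s$concl %in% consumed, stmts)
  upper <- Filter(function(s) s$layer > 1L, stmts)

  for (n in seq_len(inj[["equiv_case1"]])) {
    b <- pick(layer1); id <- next_id()
    # same atoms, permuted, variables renamed
    added <- c(added, sprintf("%s: %s(p,w), %s(p), GE(w,%s) -> %s(p)",
                              id, b$dataprop, b$prem, format(b$thr), b$concl))
    label(id, "equiv_case1", b$id, "deleted")
  }
  for (n in seq_len(inj[["equiv_case2a"]])) {
    b <- pick(upper); id <- next_id()
    sub <- sprintf("Sub%s_%d", b$prem, n)
    onto <- c(onto, sprintf("class %s < %s", sub, b$prem))
    added <- c(added, sprintf("%s: %s(x) -> %s(x)", id, sub, b$concl))
    label(id, "equiv_case2a", b$id, "deleted")
  }
  for (n in seq_len(inj[["equiv_case2b"]])) {
    b <- pick(upper); id <- next_id()
    sub <- sprintf("Sub%s_%d", b$concl, n)
    onto <- c(onto, sprintf("class %s < %s", sub, b$concl))
    added <- c(added, sprintf("%s: %s(x) -> %s(x)", id, b$prem, sub))
    label(id, "equiv_case2b", b$id, "deleted")
  }
  for (n in seq_len(inj[["subsump_simple"]])) {
    b <- pick(upper); id <- next_id()
    extra <- sprintf("Ctx%d", n)
    onto <- c(onto, sprintf("class %s", extra))
    added <- c(added, sprintf("%s: %s(x), %s(x) -> %s(x)", id, b$prem, extra, b$concl))
    label(id, "subsump_simple", b$id, "deleted")
  }
  for (n in seq_len(inj[["subsump_semantic"]])) {
    b <- pick(layer1); id <- next_id()
    sub <- sprintf("sub%s_%d", b$dataprop, n)
    onto <- c(onto, sprintf("dataprop %s domain %s range decimal[0..100] < %s",
                            sub, b$prem, b$dataprop))
    added <- c(added, sprintf("%s: %s(x), %s(x,v), GE(v,%s) -> %s(x)",
                              id, b$prem, sub, format(b$thr), b$concl))
    label(id, "subsump_semantic", b$id, "deleted")
  }
  for (n in seq_len(inj[["transitive"]])) {
    # a chained pair whose link class has exactly one consumer
    cand <- Filter(function(s2) {
      s2$layer > 1L &&
        sum(vapply(stmts, function(t) identical(t$prem, s2$prem), logical(1))) == 1L
    }, stmts)
    s2 <- cand[[sample(length(cand), 1L)]]
    s1 <- Filter(function(t) identical(t$concl, s2$prem), stmts)[[1]]
    id <- next_id()
    prem_txt <- if (s1$layer == 1L)
      sprintf("%s(x), %s(x,v), GE(v,%s)", s1$prem, s1$dataprop, format(s1$thr))
    else sprintf("%s(x)", s1$prem)
    added <- c(added, sprintf("%s: %s -> %s(x)", id, prem_txt, s2$concl))
    label(id, "transitive", c(s1$id, s2$id), "deleted")
  }
  for (ck in c("cycle_fake", "cycle_real")) {
    li <- 0L
    for (sz in loop_sizes(inj[[ck]])) {
      li <- li + 1L
      cls <- sprintf("Loop%s%d_%d", if (ck == "cycle_fake") "F" else "R", li,
                     seq_len(sz))
      onto <- c(onto, sprintf("class %s", cls))
      ids <- vapply(seq_len(sz), function(m) next_id(), character(1))
      for (m in seq_len(sz)) {
        nxt <- cls[[if (m == sz) 1L else m + 1L]]
        added <- c(added, sprintf("%s: %s(x) -> %s(x)", ids[[m]], cls[[m]], nxt))
      }
      for (m in seq_len(sz)) label(ids[[m]], "cycle", setdiff(ids, ids[[m]]), "detected")
    }
  }
  for (n in seq_len(inj[["conflict_strong"]])) {
    b <- pick(upper); id <- next_id()
    conf <- sprintf("Conf%s_%d", b$concl, n)
    onto <- c(onto, sprintf("class %s disjoint %s", conf, b$concl))
    added <- c(added, sprintf("%s: %s(x) -> %s(x)", id, b$prem, conf))
    label(id, "conflict_strong", b$id, "deleted")
  }
  for (n in seq_len(inj[["conflict_probable1"]] %/% 2L)) {
    ida <- next_id(); idb <- next_id()
    d1 <- sprintf("Dis%dA", n); d2 <- sprintf("Dis%dB", n); f <- sprintf("Out%d", n)
    onto <- c(onto, sprintf("class %s", c(d1, f)),
              sprintf("class %s disjoint %s", d2, d1))
    added <- c(added, sprintf("%s: %s(x) -> %s(x)", ida, d1, f),
               sprintf("%s: %s(x) -> %s(x)", idb, d2, f))
    label(ida, "conflict_probable1", idb, "saved")
    label(idb, "conflict_probable1", ida, "saved")
  }
  for (n in seq_len(inj[["conflict_probable2"]])) {
    b <- pick(layer1); id <- next_id()
    added <- c(added, sprintf("%s: %s(x), %s(x,v), LE(v,%s) -> %s(x)",
                              id, b$prem, b$dataprop, format(b$thr), b$concl))
    label(id, "conflict_probable2", b$id, "saved")
  }
  for (n in seq_len(inj[["inaccessible"]])) {
    b <- pick(stmts); id <- next_id()
    blk <- sprintf("Blk%d", n); f <- sprintf("Dead%d", n)
    onto <- c(onto, sprintf("class %s disjoint %s", blk, b$prem),
              sprintf("class %s", f))
    added <- c(added, sprintf("%s: %s(x), %s(x) -> %s(x)", id, b$prem, blk, f))
    label(id, "inaccessible", character(), "deleted")
  }
  for (n in seq_len(inj[["illegal_value"]])) {
    b <- pick(layer1); id <- next_id()
    added <- c(added, sprintf("%s: %s(x) -> %s(x,150)", id, b$prem, b$dataprop))
    label(id, "illegal_value", character(), "flagged")
  }

  # pad the ontology to the configured sizes with inert declarations
  n_cls <- sum(grepl("^class ", onto))
  if (n_cls < cfg$n_classes)
    onto <- c(onto, sprintf("class PadC%d", seq_len(cfg$n_classes - n_cls)))
  n_prp <- sum(grepl("^(objprop|dataprop) ", onto))
  if (n_prp < cfg$n_properties)
    onto <- c(onto, sprintf("dataprop padp%d range decimal[0..1]",
                            seq_len(cfg$n_properties - n_prp)))

  ont <- parse_ontology(onto, source = sprintf("synthetic(seed=%d)", cfg$seed))
  base <- parse_strategy(rules, ont, source = "base", provenance = "original")
  extra <- if (length(added))
    parse_strategy(added, ont, source = "injected", provenance = "added")$statements
  else list()
  all_sts <- c(base$statements, extra)
  for (i in seq_along(all_sts)) all_sts[[i]]$ordinal <- i
  strategy <- new_strategy(all_sts, source = sprintf("synthetic(seed=%d)", cfg$seed))
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(), kind = character(), partners = character(),
               expected = character(), stringsAsFactors = FALSE)
  list(ont = ont, strategy = strategy, truth = truth_df,
       ontology_text = paste(onto, collapse = "\n"),
       strategy_text = paste(c(rules, added), collapse = "\n"),
       config = cfg)
}

#' Write a generated case to a directory
#'
#' Emits `ontology.onto`, `strategy.rules` and `ground_truth.json`.
#'
#' @param case result of [generate_case()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(case$ontology_text, file.path(dir, "ontology.onto"))
  writeLines(case$strategy_text, file.path(dir, "strategy.rules"))
  jsonlite::write_json(case$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}

# record kinds that satisfy each ground-truth label; the semantic-subsumption
# pattern is structurally an equivalence Case 2.1 as well, so the earlier
# phase may legitimately claim it
TRUTH_KIND_MAP <- list(
  equiv_case1 = "equivalence", equiv_case2a = "equivalence",
  equiv_case2b = "equivalence",
  subsump_simple = "subsumption_simple",
  subsump_semantic = c("equivalence", "subsumption_semantic"),
  transitive = "transitivity",
  cycle = c("cycle_real", "cycle_fake"),
  conflict_strong = "conflict_strong",
  conflict_probable1 = "conflict_probable", conflict_probable2 = "conflict_probable",
  inaccessible = "inaccessible", illegal_value = "illegal_value")

#' Score detector output against ground truth
#'
#' An injected statement counts as recovered when an anomaly record of a kind
#' compatible with its label contains it (and, for labels expecting deletion,
#' when it was indeed deleted). Precision and recall follow
#' TP / (TP + FP) and TP / (TP + FN); an undefined ratio (0/0) is reported as
#' `NA`, not 1. Deletion precision additionally reports whether any unlabeled
#' (base) statement was deleted.
#'
#' @param records list of anomaly records (e.g. `report$records`).
#' @param truth ground-truth data.frame from [generate_case()].
#' @return an `sc_evalscore`: `per_kind` data.frame, `overall` precision and
#'   recall, and `deletions` summary.
#' @export
score_detection <- function(records, truth) {
  deleted_ids <- unlist(lapply(records, function(r) {
    if (grepl("^deleted:", r$action)) sub("^deleted:", "", r$action) else character()
  }))
  rec_kind <- vapply(records, `[[`, character(1), "kind")
  rec_members <- lapply(records, `[[`, "members")

  hit <- function(id, kinds, need_deleted) {
    in_rec <- any(rec_kind %in% kinds &
                    vapply(rec_members, function(m) id %in% m, logical(1)))
    if (need_deleted) in_rec && id %in% deleted_ids else in_rec
  }

  kinds <- unique(truth$kind)
  per <- lapply(kinds, function(k) {
    rows <- truth[truth$kind == k, , drop = FALSE]
    ok_kinds <- TRUTH_KIND_MAP[[k]]
    need_del <- all(rows$expected == "deleted")
    tp <- sum(vapply(rows$id, hit, logical(1), kinds = ok_kinds,
                     need_deleted = need_del))
    fn <- nrow(rows) - tp
    # false positives: records of a compatible kind touching no labeled id
    labeled <- truth$id[vapply(truth$kind, function(tk)
      any(TRUTH_KIND_MAP[[tk]] %in% ok_kinds), logical(1))]
    fp <- sum(rec_kind %in% ok_kinds &
                vapply(rec_members, function(m) !any(m %in% labeled), logical(1)))
    data.frame(kind = k, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per_kind <- if (length(per)) do.call(rbind, per) else
    data.frame(kind = character(), tp = integer(), fp = integer(),
               fn = integer(), precision = numeric(), recall = numeric())
  tp_all <- sum(per_kind$tp); fp_all <- sum(per_kind$fp); fn_all <- sum(per_kind$fn)
  base_deleted <- setdiff(deleted_ids, truth$id)
  structure(list(
    per_kind = per_kind,
    overall = list(
      precision = if (tp_all + fp_all > 0) tp_all / (tp_all + fp_all) else NA_real_,
      recall = if (tp_all + fn_all > 0) tp_all / (tp_all + fn_all) else NA_real_),
    deletions = list(
      deleted = deleted_ids,
      injected_deleted = intersect(deleted_ids, truth$id),
      base_deleted = base_deleted,
      precision = if (length(deleted_ids))
        length(intersect(deleted_ids, truth$id)) / length(deleted_ids)
      else NA_real_)),
    class = "sc_evalscore")
}

#' @export
print.sc_evalscore <- function(x, ...) {
  cat("<evaluation score>\n")
  print(x$per_kind, row.names = FALSE)
  cat(sprintf("overall precision %.3f recall %.3f; deletion precision %s (%d base deleted)\n",
              x$overall$precision, x$overall$recall,
              format(x$deletions$precision), length(x$deletions$base_deleted)))
  invisible(x)
}
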