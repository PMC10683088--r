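# Module M2, redundancy phases: equivalence, subsumption, transitivity.
# Candidate pairs are pruned through the statement groups built by M1.

anomaly_record <- function(kind, members, action, evidence, case = NA_character_) {
  structure(list(kind = kind, members = members, action = action,
                 evidence = evidence, case = case), class = "sc_anomaly")
}

#' @export
print.sc_anomaly <- function(x, ...) {
  cat(sprintf("<%s%s: [%s] %s — %s>\n", x$kind,
              if (!is.na(x$case)) paste0("/", x$case) else "",
              paste(x$members, collapse = ","), x$action, x$evidence))
  invisible(x)
}

drop_statements <- function(strategy, ids) {
  keep <- Filter(function(s) !(s$id %in% ids), strategy$statements)
  new_strategy(keep, source = strategy$source)
}

sub_describe <- function(subs) {
  paste(vapply(subs, function(s)
    sprintf("%s~%s[%s]", s$atom_a, s$atom_b, s$relation), character(1)),
    collapse = "; ")
}

# victim of a hierarchy substitution set: the statement whose substituted
# atoms reference the descendant (more specific) entity. Substitutions are
# recorded as (atom of sx, atom of sy, relation of sx's predicate to sy's):
# "ancestor" means sy holds the lower entity.
hierarchy_victim <- function(sx, sy, subs) {
  dirs <- unique(vapply(subs, `[[`, character(1), "relation"))
  dirs <- setdiff(dirs, c("equivalent", "builtin_normalized"))
  if (identical(dirs, "ancestor")) return(sy$id)
  if (identical(dirs, "descendant")) return(sx$id)
  NA_character_  # mixed or no hierarchy direction
}

later_declared <- function(sx, sy) if (sx$ordinal >= sy$ordinal) sx$id else sy$id

#' Resolve equivalence redundancy
#'
#' Examines statement pairs within each group for corresponding premises and
#' corresponding conclusions under one shared variable bijection. Identical
#' parts up to atom order (Case 1) delete the later-declared statement;
#' a hierarchy substitution in the premise (Case 2.1) or in the conclusion
#' (Case 2.2) deletes the statement whose substituted atom references the more
#' specific entity, so no inferable knowledge is lost.
#'
#' @param strategy an `sc_strategy`.
#' @param groups result of [group_statements()] on the current graph.
#' @param ont an `sc_ontology`.
#' @param cfg an [sc_config()].
#' @return list with `strategy` (survivors) and `records`.
#' @export
resolve_equivalence <- function(strategy, groups, ont, cfg = sc_config()) {
  records <- list()
  deleted <- character()
  for (gr in groups) {
    members <- intersect(strategy_ids(strategy), gr$members)
    if (length(members) < 2) next
    for (i in seq_len(length(members) - 1)) for (j in seq(i + 1, length(members))) {
      a <- members[[i]]; b <- members[[j]]
      if (a %in% deleted || b %in% deleted) next
      sx <- strategy$statements[[a]]; sy <- strategy$statements[[b]]
      corr <- statements_correspond(sx, sy, ont, "allow_semantic",
                                    cfg$normalize_integer_builtins)
      if (corr$status == "none") next
      hier <- Filter(function(s) s$relation %in% c("ancestor", "descendant"),
                     corr$substitutions)
      if (corr$status == "exact" || !length(hier)) {
        victim <- later_declared(sx, sy)
        case <- "case1"
        ev <- if (length(corr$substitutions))
          paste("parts identical up to", sub_describe(corr$substitutions)) else
            "identical parts up to atom order and variable renaming"
      } else {
        in_conclusion <- any(vapply(hier, function(s) s$segment == 2L, logical(1)))
        case <- if (in_conclusion) "case2.2" else "case2.1"
        victim <- hierarchy_victim(sx, sy, hier)
        if (is.na(victim)) victim <- later_declared(sx, sy)
        ev <- sub_describe(corr$substitutions)
      }
      deleted <- c(deleted, victim)
      records[[length(records) + 1]] <- anomaly_record(
        "equivalence", c(sx$id, sy$id), paste0("deleted:", victim), ev, case)
    }
  }
  list(strategy = drop_statements(strategy, deleted), records = records)
}

# candidate pairs for subsumption: within one group, or across groups Gi, Gj
# with In(Gi) a proper subset of In(Gj) and Out(Gi) = Out(Gj)
subsumption_pairs <- function(strategy, groups) {
  ids <- strategy_ids(strategy)
  pairs <- list()
  add <- function(a, b) pairs[[length(pairs) + 1]] <<- c(a, b)
  for (gr in groups) {
    m <- intersect(ids, gr$members)
    if (length(m) >= 2)
      for (i in seq_len(length(m) - 1)) for (j in seq(i + 1, length(m)))
        add(m[[i]], m[[j]])
  }
  ng <- length(groups)
  if (ng >= 2) for (i in seq_len(ng)) for (j in seq_len(ng)) {
    if (i == j) next
    gi <- groups[[i]]; gj <- groups[[j]]
    proper <- all(gi$in_arcs %in% gj$in_arcs) && length(gi$in_arcs) < length(gj$in_arcs)
    if (proper && setequal(gi$out_arcs, gj$out_arcs))
      for (a in intersect(ids, gi$members)) for (b in intersect(ids, gj$members))
        add(a, b)
  }
  pairs
}

#' Resolve subsumption redundancy
#'
#' Case 1 (simple): two statements share a corresponding conclusion while one
#' premise is a proper sub-multiset of the other under the shared variable
#' bijection; the larger-premise statement is deleted. Case 2 (semantic): a
#' statement specialises another's premise through sub-property/subclass
#' substitutions with a corresponding conclusion; each specific statement is
#' deleted independently, keeping the general one. Candidates are restricted
#' to pairs within one group and to group pairs whose incoming arcs are
#' properly nested with equal outgoing arcs.
#'
#' @inheritParams resolve_equivalence
#' @param graph the current `sc_depgraph`.
#' @return list with `strategy` and `records`.
#' @export
resolve_subsumption <- function(strategy, groups, graph, ont, cfg = sc_config()) {
  records <- list()
  deleted <- character()
  for (pr in subsumption_pairs(strategy, groups)) {
    a <- pr[[1]]; b <- pr[[2]]
    if (a %in% deleted || b %in% deleted) next
    sx <- strategy$statements[[a]]; sy <- strategy$statements[[b]]
    # orient so sx has the smaller premise
    if (length(sx$premise) > length(sy$premise)) { tmp <- sx; sx <- sy; sy <- tmp }
    # Case 1: conclusions correspond exactly, premise(sx) proper sub-multiset
    if (length(sx$premise) < length(sy$premise)) {
      hit <- match_segments(list(
        list(A = sx$conclusion, B = sy$conclusion),
        list(A = sx$premise, B = sy$premise, partial = TRUE)),
        ont, "exact_only", cfg$normalize_integer_builtins)
      if (!is.null(hit)) {
        deleted <- c(deleted, sy$id)
        records[[length(records) + 1]] <- anomaly_record(
          "subsumption_simple", c(sx$id, sy$id), paste0("deleted:", sy$id),
          sprintf("premise of %s embeds into premise of %s with identical conclusion",
                  sx$id, sy$id), "case1")
        next
      }
    }
    # Case 2: full semantic correspondence whose hierarchy substitutions sit
    # in the premise; delete the specialised statement
    corr <- statements_correspond(sx, sy, ont, "allow_semantic",
                                  cfg$normalize_integer_builtins)
    if (corr$status != "semantic") next
    hier <- Filter(function(s) s$relation %in% c("ancestor", "descendant"),
                   corr$substitutions)
    if (!length(hier) || any(vapply(hier, function(s) s$segment == 1L, logical(1)) == FALSE))
      next
    victim <- hierarchy_victim(sx, sy, hier)
    if (is.na(victim)) next
    deleted <- c(deleted, victim)
    records[[length(records) + 1]] <- anomaly_record(
      "subsumption_semantic", c(sx$id, sy$id), paste0("deleted:", victim),
      sub_describe(corr$substitutions), "case2")
  }
  list(strategy = drop_statements(strategy, deleted), records = records)
}

# signature of an atom for the transitivity input condition: predicate name
# for classes/properties, operator plus threshold for builtins
atom_sig <- function(a) {
  if (a$kind == "builtin") {
    consts <- Filter(function(t) t$kind != "variable", a$args)
    return(paste(c(a$predicate, vapply(consts, `[[`, character(1), "value")),
                 collapse = ":"))
  }
  a$predicate
}

part_sigs <- function(atoms) unique(vapply(atoms, atom_sig, character(1)))

# net input signatures of a chain: union of member premise signatures minus
# the signatures produced by earlier members' conclusions
chain_input_sigs <- function(chain_sts) {
  produced <- character()
  input <- character()
  for (s in chain_sts) {
    input <- union(input, setdiff(part_sigs(s$premise), produced))
    produced <- union(produced, part_sigs(s$conclusion))
  }
  input
}

# simple paths of length 2..bound (in statements) in the dependency graph,
# excluding a given node
enumerate_chains <- function(graph, bound, exclude = character()) {
  nodes <- setdiff(graph$nodes, exclude)
  succs <- lapply(setNames(nodes, nodes), function(v)
    intersect(graph_succs(graph, v), nodes))
  chains <- list()
  grow <- function(path) {
    if (length(path) >= 2) chains[[length(chains) + 1]] <<- path
    if (length(path) >= bound) return(invisible(NULL))
    for (nxt in succs[[path[[length(path)]]]])
      if (!nxt %in% path) grow(c(path, nxt))
    invisible(NULL)
  }
  for (v in nodes) grow(v)
  chains
}

external_arcs <- function(graph, members, exclude, side) {
  got <- unique(unlist(lapply(members, function(v)
    if (side == "in") graph_preds(graph, v) else graph_succs(graph, v))))
  sort(setdiff(got, exclude))
}

#' Resolve transitivity redundancy
#'
#' A statement is transitive when a chain of other statements reproduces it:
#' the chain's net input signatures (union of member premises minus what the
#' chain itself produces) equal the statement's premise signatures, the chain
#' tail's conclusion corresponds to the statement's, and forward-chaining the
#' statement alone versus the chain alone over generated witness objects
#' derives the same conclusion facts. Group arc signatures prune the chains
#' examined; arcs involving the chain or the candidate's own group are set
#' aside in that comparison, because the redundancy under test creates them.
#'
#' @inheritParams resolve_subsumption
#' @return list with `strategy` and `records`.
#' @export
resolve_transitivity <- function(strategy, graph, groups, ont, cfg = sc_config()) {
  records <- list()
  deleted <- character()
  for (gr in groups) {
    for (st_id in intersect(strategy_ids(strategy), gr$members)) {
      if (st_id %in% deleted) next
      st <- strategy$statements[[st_id]]
      chains <- enumerate_chains(graph, cfg$chain_bound,
                                 exclude = c(st_id, deleted))
      for (ch in chains) {
        ch_sts <- strategy$statements[ch]
        if (any(vapply(ch_sts, is.null, logical(1)))) next
        sn <- ch_sts[[length(ch_sts)]]
        concl_corr <- parts_correspond(st$conclusion, sn$conclusion, ont,
                                       "allow_semantic",
                                       cfg$normalize_integer_builtins)
        if (concl_corr$status == "none") next
        # Algorithm-1 style arc pruning, net of the chain and candidate group
        aside <- union(ch, gr$members)
        g_in <- external_arcs(graph, gr$members, union(gr$members, ch), "in")
        c_in <- external_arcs(graph, ch, aside, "in")
        if (!setequal(g_in, c_in)) next
        g_out <- external_arcs(graph, gr$members, union(gr$members, ch), "out")
        c_out <- external_arcs(graph, ch, aside, "out")
        if (!setequal(g_out, c_out)) next
        # Definition-1 input condition on premise signatures
        if (!setequal(part_sigs(st$premise), chain_input_sigs(ch_sts))) next
        # confirm on witnesses: same conclusion facts from St alone and CH alone
        seed <- c(st$premise, chain_net_input_atoms(ch_sts))
        all_atoms <- unlist(lapply(c(ch_sts, list(st)),
                                   function(s) c(s$premise, s$conclusion)),
                            recursive = FALSE)
        store <- witness_store(seed, ont, threshold_atoms = all_atoms)
        concl_preds <- unique(c(vapply(st$conclusion, `[[`, character(1), "predicate"),
                                vapply(sn$conclusion, `[[`, character(1), "predicate")))
        run_st <- forward_chain(list(st), store, ont)
        run_ch <- forward_chain(unname(ch_sts), store, ont)
        k_st <- derived_keys(run_st$store, concl_preds)
        k_ch <- derived_keys(run_ch$store, concl_preds)
        if (length(k_st) && identical(k_st, k_ch)) {
          deleted <- c(deleted, st_id)
          records[[length(records) + 1]] <- anomaly_record(
            "transitivity", c(st_id, ch), paste0("deleted:", st_id),
            sprintf("%s reproduced by chain <%s>; witnesses derive {%s} both ways",
                    st_id, paste(ch, collapse = ","),
                    paste(k_st, collapse = "; ")))
          break
        }
      }
    }
  }
  list(strategy = drop_statements(strategy, deleted), records = records)
}

# premise atoms a chain still needs from outside (atoms whose signature is not
# produced by an earlier member)
chain_net_input_atoms <- function(chain_sts) {
  produced <- character()
  out <- list()
  for (s in chain_sts) {
    for (a in s$premise)
      if (!atom_sig(a) %in% produced) out[[length(out) + 1]] <- a
    produced <- union(produced, part_sigs(s$conclusion))
  }
  out
}

#' Flag illegal property values
#'
#' Every constant argument of a data-property atom is checked against the
#' property's declared data range; violations are flagged (never deleted).
#' Properties without a declared range are left unchecked.
#'
#' @param strategy an `sc_strategy`.
#' @param ont an `sc_ontology`.
#' @return list of `illegal_value` records.
#' @export
check_illegal_values <- function(strategy, ont) {
  records <- list()
  for (s in strategy$statements) {
    for (a in c(s$premise, s$conclusion)) {
      if (a$kind != "data_property") next
      v <- a$args[[2]]
      if (v$kind == "variable") next
      ok <- check_value_legal(a$predicate, v$value, ont)
      if (isFALSE(ok))
        records[[length(records) + 1]] <- anomaly_record(
          "illegal_value", s$id, "saved_for_expert",
          sprintf("%s in %s violates the declared range of %s",
                  atom_string(a), s$id, a$predicate))
    }
  }
  records
}
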