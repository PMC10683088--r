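# Conflict detection (strong / probable) and inaccessible-statement handling,
# both built on a shared notion of contradictory literals: disjoint class
# memberships on one variable, numeric comparison constraints with disjoint
# (or complementary inclusive) satisfying sets, and declared-inverse property
# atoms performing opposite checks on one argument pair.

# canonicalise object-property atoms through declared inverses: the
# lexicographically smaller property of an inverse pair becomes the
# representative, with swapped arguments
normalize_inverses <- function(atoms, ont) {
  lapply(atoms, function(a) {
    if (a$kind != "object_property") return(a)
    inv <- ont$properties[[a$predicate]]$inverse
    if (!is.na(inv) && inv < a$predicate)
      sc_atom("object_property", inv, list(a$args[[2]], a$args[[1]]))
    else a
  })
}

# class memberships asserted on each variable by a literal's class atoms
var_classes <- function(atoms) {
  out <- list()
  for (a in atoms) {
    if (a$kind != "class") next
    t <- a$args[[1]]
    if (t$kind == "variable") out[[t$value]] <- union(out[[t$value]], a$predicate)
  }
  out
}

# numeric constraint intervals keyed by variable name and by
# "<subject>.<data property>" so two literals can disagree about the same
# measured quantity through differently named value variables
constraint_keys <- function(atoms) {
  keys <- list()
  link <- list()  # value variable -> keys it also posts to
  for (a in atoms) {
    if (a$kind == "data_property" && a$args[[2]]$kind == "variable" &&
        a$args[[1]]$kind == "variable") {
      v <- a$args[[2]]$value
      link[[v]] <- union(link[[v]], sprintf("%s.%s", a$args[[1]]$value, a$predicate))
    }
  }
  for (a in atoms) {
    if (a$kind != "builtin") next
    v <- NULL; cst <- NULL
    for (t in a$args) {
      if (t$kind == "variable") v <- t$value
      if (t$kind == "number") cst <- as.numeric(t$value)
    }
    if (is.null(v) || is.null(cst)) next
    entry <- list(op = a$predicate, t = cst)
    for (k in c(v, link[[v]])) keys[[k]] <- c(keys[[k]], list(entry))
  }
  keys
}

# intersect the satisfying set of a constraint list into an interval
constraints_interval <- function(cons) {
  lo <- -Inf; hi <- Inf; lo_open <- FALSE; hi_open <- FALSE
  for (cn in cons) {
    switch(cn$op,
      GE = if (cn$t > lo) { lo <- cn$t; lo_open <- FALSE }
        else if (cn$t == lo) { },
      GT = if (cn$t >= lo) { lo <- cn$t; lo_open <- TRUE },
      LE = if (cn$t < hi) { hi <- cn$t; hi_open <- FALSE },
      LT = if (cn$t <= hi) { hi <- cn$t; hi_open <- TRUE },
      EQ = { if (cn$t > lo) { lo <- cn$t; lo_open <- FALSE }
             if (cn$t < hi) { hi <- cn$t; hi_open <- FALSE } },
      NE = { })
  }
  list(lo = lo, hi = hi, lo_open = lo_open, hi_open = hi_open)
}

interval_empty <- function(iv) {
  iv$lo > iv$hi || (iv$lo == iv$hi && (iv$lo_open || iv$hi_open))
}

# do two constraint lists on the same quantity contradict? Disjoint satisfying
# sets always do; complementary inclusive half-lines meeting in one point
# (GE t vs LE t) do under strict boundary semantics.
constraints_contradict <- function(c1, c2, strict_boundary = TRUE) {
  iv1 <- constraints_interval(c1)
  iv2 <- constraints_interval(c2)
  both <- constraints_interval(c(c1, c2))
  if (interval_empty(both)) return(TRUE)
  if (strict_boundary && both$lo == both$hi && !both$lo_open && !both$hi_open) {
    half_up <- function(iv) is.infinite(iv$hi) && is.finite(iv$lo)
    half_dn <- function(iv) is.infinite(iv$lo) && is.finite(iv$hi)
    if ((half_up(iv1) && half_dn(iv2)) || (half_dn(iv1) && half_up(iv2)))
      return(TRUE)
  }
  # EQ on one side vs NE on the other at the same point
  eqs <- function(cc) vapply(Filter(function(x) x$op == "EQ", cc), `[[`, numeric(1), "t")
  nes <- function(cc) vapply(Filter(function(x) x$op == "NE", cc), `[[`, numeric(1), "t")
  if (length(intersect(eqs(c1), nes(c2))) || length(intersect(eqs(c2), nes(c1))))
    return(TRUE)
  FALSE
}

# classes asserted on each variable after optionally saturating the literal's
# witness instantiation through bridging statements
saturated_var_classes <- function(atoms, ont, statements) {
  direct <- var_classes(atoms)
  if (!length(statements)) return(direct)
  store <- witness_store(atoms, ont, domain_facts = TRUE)
  run <- forward_chain(statements, store, ont)
  for (f in run$store$facts) {
    if (!f$predicate %in% names(ont$classes)) next
    m <- regmatches(f$args[[1]], regexec("^i_([A-Za-z0-9_]+)_[0-9]+$", f$args[[1]]))[[1]]
    if (length(m) == 2)
      direct[[m[[2]]]] <- union(direct[[m[[2]]]], f$predicate)
  }
  direct
}

#' Are two literals contradictory?
#'
#' Two literals (sub-conjunctions of atoms sharing a variable context by
#' name) are contradictory when they place one variable in declared-disjoint
#' classes, when they impose comparison constraints on the same quantity whose
#' satisfying sets are disjoint (or are complementary inclusive half-lines
#' under strict boundary semantics), or when declared-inverse object
#' properties are applied to the same ordered argument pair. An optional list
#' of bridging statements lets class memberships implied by one literal (e.g.
#' a diagnostic measurement pattern) surface before the disjointness check.
#'
#' @param l1,l2 nonempty lists of [sc_atom()]s sharing variable names.
#' @param ont an `sc_ontology`.
#' @param statements optional statements forward-chained over each literal's
#'   instantiation before comparing class memberships.
#' @param cfg an [sc_config()].
#' @return `"contradictory"` or `"compatible"`.
#' @export
contradictory_literals <- function(l1, l2, ont, statements = list(),
                                   cfg = sc_config()) {
  if (!length(l1) || !length(l2)) stop("literals must be nonempty")
  l1 <- normalize_inverses(l1, ont)
  l2 <- normalize_inverses(l2, ont)
  cls1 <- saturated_var_classes(l1, ont, statements)
  cls2 <- saturated_var_classes(l2, ont, statements)
  for (v in intersect(names(cls1), names(cls2)))
    for (a in cls1[[v]]) for (b in cls2[[v]])
      if (entity_relation(a, b, "class", ont) == "disjoint")
        return("contradictory")
  k1 <- constraint_keys(l1)
  k2 <- constraint_keys(l2)
  for (k in intersect(names(k1), names(k2)))
    if (constraints_contradict(k1[[k]], k2[[k]], cfg$strict_boundary))
      return("contradictory")
  # declared-inverse properties applied to the same ordered pair
  sig <- function(a) vapply(a$args, function(t) paste(t$kind, t$value), character(1))
  for (a in l1) for (b in l2) {
    if (a$kind != "object_property" || b$kind != "object_property") next
    inv <- ont$properties[[a$predicate]]$inverse
    if (!is.na(inv) && inv == b$predicate && identical(sig(a), sig(b)))
      return("contradictory")
    if (a$predicate == b$predicate && !identical(sig(a), sig(b)) &&
        identical(sig(a), rev(sig(b))) &&
        sig(a)[[1]] != sig(a)[[2]] &&
        !is.na(ont$properties[[a$predicate]]$inverse))
      return("contradictory")
  }
  "compatible"
}

# rename part B's variables into part A's space using the correspondence map
# (A variable -> B variable, inverted here); unmapped variables get a
# distinguishing prefix
rename_part <- function(atoms, vmap_fwd) {
  bwd <- setNames(names(vmap_fwd), unlist(vmap_fwd))
  lapply(atoms, function(a) {
    a$args <- lapply(a$args, function(t) {
      if (t$kind == "variable") {
        hit <- unname(bwd[t$value])
        t$value <- if (length(hit) == 1 && !is.na(hit)) hit
                   else paste0("other_", t$value)
      }
      t
    })
    a
  })
}

# value-disagreement between corresponding conclusions: same property on the
# same (renamed) subject with different constant objects
conclusion_value_disagreement <- function(ca, cb) {
  for (a in ca) for (b in cb) {
    if (a$kind == b$kind && a$kind %in% c("object_property", "data_property") &&
        a$predicate == b$predicate &&
        a$args[[1]]$kind == "variable" && b$args[[1]]$kind == "variable" &&
        a$args[[1]]$value == b$args[[1]]$value &&
        a$args[[2]]$kind != "variable" && b$args[[2]]$kind != "variable" &&
        !terms_equal(a$args[[2]], b$args[[2]]))
      return(sprintf("%s vs %s assign different values to the same property",
                     atom_string(a), atom_string(b)))
  }
  NULL
}

conflict_victim <- function(sx, sy, policy) {
  if (policy == "delete_none") return(NA_character_)
  if (policy == "delete_added") {
    ax <- identical(sx$provenance, "added")
    ay <- identical(sy$provenance, "added")
    if (ax && !ay) return(sx$id)
    if (ay && !ax) return(sy$id)
  }
  later_declared(sx, sy)
}

#' Detect strong and probable conflicts
#'
#' Strong conflict: corresponding premises with contradictory conclusions;
#' resolved by the configured policy (default: delete the provenance-tagged
#' added statement). Probable conflicts are saved for expert review, never
#' deleted: corresponding conclusions with contradictory premises (Case 1),
#' corresponding conclusions with partially contradictory premises (Case 2),
#' and corresponding premises whose conclusions assign different constant
#' values to one property. Pairs recorded as false conflicts in the knowledge
#' base are skipped; candidate pairs share a group or sit in groups with
#' identical incoming arcs.
#'
#' @inheritParams resolve_equivalence
#' @param kb an `sc_kb` or `NULL`.
#' @return list with `strategy`, `records`, and the updated `kb`.
#' @export
detect_conflicts <- function(strategy, groups, ont, kb = NULL, cfg = sc_config()) {
  records <- list()
  deleted <- character()
  ids <- strategy_ids(strategy)
  membership <- attr(groups, "membership")
  in_of <- setNames(lapply(groups, `[[`, "in_arcs"),
                    vapply(groups, `[[`, character(1), "id"))

  candidate <- function(a, b) {
    ga <- membership[[a]]; gb <- membership[[b]]
    if (is.na(ga) || is.na(gb)) return(FALSE)
    ga == gb || setequal(in_of[[ga]], in_of[[gb]])
  }

  n <- length(ids)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- ids[[i]]; b <- ids[[j]]
    if (a %in% deleted || b %in% deleted) next
    if (!candidate(a, b)) next
    sx <- strategy$statements[[a]]; sy <- strategy$statements[[b]]
    if (!is.null(kb)) {
      known <- kb_is_known(kb, "conflict_probable", c(a, b))
      if (!is.null(known) &&
          (known$kind == "conflict_false" || known$status == "false_positive")) next
    }
    prem <- parts_correspond(sx$premise, sy$premise, ont, "allow_semantic",
                             cfg$normalize_integer_builtins)
    if (prem$status != "none") {
      cy <- rename_part(sy$conclusion, prem$variable_map)
      if (contradictory_literals(sx$conclusion, cy, ont, cfg = cfg) == "contradictory") {
        victim <- conflict_victim(sx, sy, cfg$strong_conflict_policy)
        act <- if (is.na(victim)) "saved_for_expert" else paste0("deleted:", victim)
        if (!is.na(victim)) deleted <- c(deleted, victim)
        records[[length(records) + 1]] <- anomaly_record(
          "conflict_strong", c(a, b), act,
          "corresponding premises infer contradictory conclusions")
        next
      }
      dis <- conclusion_value_disagreement(sx$conclusion, cy)
      if (!is.null(dis)) {
        rec <- anomaly_record("conflict_probable", c(a, b), "saved_for_expert", dis)
        records[[length(records) + 1]] <- rec
        if (!is.null(kb)) kb <- kb_record(kb, rec)$kb
        next
      }
    }
    concl <- parts_correspond(sx$conclusion, sy$conclusion, ont, "allow_semantic",
                              cfg$normalize_integer_builtins)
    if (concl$status != "none") {
      py <- rename_part(sy$premise, concl$variable_map)
      if (contradictory_literals(sx$premise, py, ont, cfg = cfg) == "contradictory") {
        # Case 2 when part of the premises still correspond, Case 1 otherwise
        shared <- 0L
        taken <- logical(length(py))
        for (ax in sx$premise) for (k in seq_along(py)) {
          if (taken[[k]]) next
          hit <- try_atom_pair(ax, py[[k]], list(fwd = list(), bwd = list()),
                               ont, "exact_only", FALSE)
          if (!is.null(hit) &&
              all(vapply(seq_along(ax$args), function(m)
                ax$args[[m]]$kind != "variable" ||
                  ax$args[[m]]$value == py[[k]]$args[[m]]$value, logical(1)))) {
            shared <- shared + 1L; taken[[k]] <- TRUE; break
          }
        }
        case <- if (shared > 0L) "case2" else "case1"
        rec <- anomaly_record(
          "conflict_probable", c(a, b), "saved_for_expert",
          sprintf("corresponding conclusions with %s contradictory premises",
                  if (case == "case2") "partially" else "fully"), case)
        records[[length(records) + 1]] <- rec
        if (!is.null(kb)) kb <- kb_record(kb, rec)$kb
      }
    }
  }
  list(strategy = drop_statements(strategy, deleted), records = records, kb = kb)
}

# is a single part (premise or conclusion) unsatisfiable on its own?
part_unsatisfiable <- function(part, ont, cfg) {
  part <- normalize_inverses(part, ont)
  cls <- var_classes(part)
  for (v in names(cls)) {
    cc <- cls[[v]]
    if (length(cc) >= 2)
      for (i in seq_len(length(cc) - 1)) for (j in seq(i + 1, length(cc)))
        if (entity_relation(cc[[i]], cc[[j]], "class", ont) == "disjoint")
          return(sprintf("%s and %s are disjoint classes on variable %s",
                         cc[[i]], cc[[j]], v))
  }
  keys <- constraint_keys(part)
  for (k in names(keys)) {
    iv <- constraints_interval(keys[[k]])
    if (interval_empty(iv))
      return(sprintf("comparison constraints on %s cannot be satisfied together", k))
  }
  sig <- function(a) vapply(a$args, function(t) paste(t$kind, t$value), character(1))
  op <- Filter(function(a) a$kind == "object_property", part)
  if (length(op) >= 2)
    for (i in seq_len(length(op) - 1)) for (j in seq(i + 1, length(op))) {
      ai <- op[[i]]; aj <- op[[j]]
      inv <- ont$properties[[ai$predicate]]$inverse
      direct <- !is.na(inv) && inv == aj$predicate && identical(sig(ai), sig(aj))
      # after inverse normalisation the pair appears as p(x,y) and p(y,x)
      swapped <- ai$predicate == aj$predicate && !is.na(inv) &&
        !identical(sig(ai), sig(aj)) && identical(sig(ai), rev(sig(aj))) &&
        sig(ai)[[1]] != sig(ai)[[2]]
      if (direct || swapped)
        return(sprintf("%s and %s perform opposite checks (declared inverse properties)",
                       atom_string(ai), atom_string(aj)))
    }
  NULL
}

#' Detect and delete inaccessible statements
#'
#' Statements in groups with no incoming arcs or no outgoing arcs (the
#' necessary screen; terminal and initial statements legitimately sit there
#' too) are scanned for non-satisfiable literals in their premise or
#' conclusion — disjoint classes on one variable, jointly unsatisfiable
#' comparison constraints, declared-inverse properties on one argument pair.
#' A statement with such a literal can never fire and is deleted. The
#' `exhaustive_inaccessible` configuration scans every statement instead.
#'
#' @inheritParams resolve_subsumption
#' @return list with `strategy` and `records`.
#' @export
detect_inaccessible <- function(strategy, groups, graph, ont, cfg = sc_config()) {
  records <- list()
  deleted <- character()
  ids <- strategy_ids(strategy)
  cand <- if (cfg$exhaustive_inaccessible) ids else {
    unique(unlist(lapply(groups, function(gr)
      if (!length(gr$in_arcs) || !length(gr$out_arcs)) gr$members else character())))
  }
  for (id in intersect(ids, cand)) {
    s <- strategy$statements[[id]]
    why <- part_unsatisfiable(s$premise, ont, cfg)
    where <- "premise"
    if (is.null(why)) { why <- part_unsatisfiable(s$conclusion, ont, cfg); where <- "conclusion" }
    if (!is.null(why)) {
      deleted <- c(deleted, id)
      records[[length(records) + 1]] <- anomaly_record(
        "inaccessible", id, paste0("deleted:", id),
        sprintf("unsatisfiable %s: %s", where, why))
    }
  }
  list(strategy = drop_statements(strategy, deleted), records = records)
}
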