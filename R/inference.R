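# Minimal monotone forward-chaining engine over ground atoms. Used by
# transitivity verification (compare a candidate shortcut against its chain on
# generated witnesses), fake-cycle classification, and satisfiability checks.

new_fact <- function(predicate, args, derivation = "asserted") {
  structure(list(predicate = predicate, args = as.character(args),
                 derivation = derivation), class = "sc_fact")
}

fact_key <- function(f) sprintf("%s(%s)", f$predicate, paste(f$args, collapse = ","))

#' Create a fact store
#'
#' A set of ground facts (no duplicate ground atoms) indexed by predicate;
#' forward chaining only ever grows it.
#'
#' @param facts optional list of facts built with ground atoms, each a list
#'   with `predicate` and `args`.
#' @return an `sc_factstore`.
#' @export
fact_store <- function(facts = list()) {
  store <- structure(list(facts = list()), class = "sc_factstore")
  for (f in facts) store <- add_fact(store, f)
  store
}

add_fact <- function(store, f) {
  if (is.null(f$derivation)) f$derivation <- "asserted"
  k <- fact_key(f)
  if (is.null(store$facts[[k]])) store$facts[[k]] <- f
  store
}

store_has <- function(store, f) !is.null(store$facts[[fact_key(f)]])

store_size <- function(store) length(store$facts)

#' @export
print.sc_factstore <- function(x, ...) {
  cat(sprintf("<fact store: %d facts>\n", store_size(x)))
  for (k in sort(names(x$facts)))
    cat(sprintf("  %s [%s]\n", k, x$facts[[k]]$derivation))
  invisible(x)
}

# parse a "pred(a,b)" line into a fact (fact files use the atom dialect with
# ground arguments)
parse_fact_line <- function(txt) {
  m <- regmatches(txt, regexec("^([A-Za-z][A-Za-z0-9_-]*)\\((.*)\\)$", trimws(txt)))[[1]]
  if (length(m) != 3) stop(sprintf("unparseable fact '%s'", txt), call. = FALSE)
  new_fact(m[[2]], trimws(strsplit(m[[3]], ",", fixed = TRUE)[[1]]))
}

#' Load ground facts from a file
#'
#' One ground atom per line, `#` comments.
#'
#' @param path fact file.
#' @return an `sc_factstore`.
#' @export
load_facts <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  fact_store(lapply(lines[lines != ""], parse_fact_line))
}

is_numeric_value <- function(x) grepl("^-?[0-9]+(\\.[0-9]+)?$", x)

#' Evaluate a comparison builtin
#'
#' Canonical comparison semantics on decimal values: `GE`, `LE`, `GT`, `LT`,
#' `EQ`, `NE`. `EQ`/`NE` fall back to string comparison when either side is
#' not numeric; the ordered comparisons require numbers.
#'
#' @param op canonical operator name.
#' @param a,b ground argument values (character or numeric).
#' @return logical.
#' @export
eval_builtin <- function(op, a, b) {
  a <- as.character(a); b <- as.character(b)
  if (op %in% c("EQ", "NE") && !(is_numeric_value(a) && is_numeric_value(b)))
    return(if (op == "EQ") a == b else a != b)
  if (!is_numeric_value(a) || !is_numeric_value(b))
    stop(sprintf("builtin %s needs numeric arguments, got (%s, %s)", op, a, b))
  x <- as.numeric(a); y <- as.numeric(b)
  switch(op,
         GE = x >= y, LE = x <= y, GT = x > y, LT = x < y,
         EQ = x == y, NE = x != y,
         stop("unknown builtin: ", op))
}

# predicates whose facts satisfy an atom of predicate p: p itself, declared
# equivalents, and declared descendants (a fact C(a) matches atom D(a) when
# C is a subclass of D; properties likewise honour sub-properties)
matching_predicates <- function(p, kind, ont) {
  if (kind == "builtin") return(p)
  if (kind == "class") {
    all <- names(ont$classes)
    cand <- unique(c(ont$class_equiv[[p]],
                     all[vapply(all, function(x) p %in% ont$class_anc[[x]], logical(1))]))
  } else {
    all <- names(ont$properties)
    cand <- unique(c(ont$prop_equiv[[p]],
                     all[vapply(all, function(x) p %in% ont$prop_anc[[x]], logical(1))]))
  }
  unique(c(p, cand))
}

term_value <- function(t, binding) {
  if (t$kind == "variable") binding[[t$value]] else t$value
}

#' Match a premise against a fact store
#'
#' Enumerates every variable binding under which each non-builtin atom of the
#' premise unifies with a stored fact (class membership honours the subclass
#' and equivalence closure, properties honour sub-properties) and every
#' builtin evaluates true. Enumeration is complete.
#'
#' @param premise list of [sc_atom()]s.
#' @param store an `sc_factstore` of ground facts.
#' @param ont an `sc_ontology`.
#' @return list of bindings (named lists variable -> value); empty when the
#'   premise cannot be satisfied.
#' @export
match_premise <- function(premise, store, ont) {
  builtins <- Filter(function(a) a$kind == "builtin", premise)
  others <- Filter(function(a) a$kind != "builtin", premise)
  facts <- store$facts
  by_pred <- split(unname(facts), vapply(facts, `[[`, character(1), "predicate"))

  results <- list()
  extend <- function(ai, binding) {
    if (ai > length(others)) {
      for (b in builtins) {
        va <- term_value(b$args[[1]], binding)
        vb <- term_value(b$args[[2]], binding)
        if (is.null(va) || is.null(vb))
          stop(sprintf("builtin %s has unbound arguments", atom_string(b)))
        if (!eval_builtin(b$predicate, va, vb)) return(invisible(NULL))
      }
      results[[length(results) + 1]] <<- binding
      return(invisible(NULL))
    }
    a <- others[[ai]]
    for (p in matching_predicates(a$predicate, a$kind, ont)) {
      for (f in by_pred[[p]]) {
        if (length(f$args) != length(a$args)) next
        b2 <- binding
        ok <- TRUE
        for (k in seq_along(a$args)) {
          t <- a$args[[k]]
          if (t$kind == "variable") {
            cur <- b2[[t$value]]
            if (is.null(cur)) b2[[t$value]] <- f$args[[k]]
            else if (cur != f$args[[k]]) { ok <- FALSE; break }
          } else {
            want <- t$value
            got <- f$args[[k]]
            same <- if (is_numeric_value(want) && is_numeric_value(got))
              as.numeric(want) == as.numeric(got) else want == got
            if (!same) { ok <- FALSE; break }
          }
        }
        if (ok) extend(ai + 1L, b2)
      }
    }
    invisible(NULL)
  }
  extend(1L, list())
  results
}

ground_conclusion <- function(atoms, binding, sid) {
  lapply(atoms, function(a) {
    if (a$kind == "builtin")
      stop(sprintf("statement %s: builtin in conclusion is not inferable", sid))
    vals <- vapply(a$args, function(t) {
      v <- term_value(t, binding)
      if (is.null(v)) stop(sprintf("statement %s: unbound conclusion variable '%s'",
                                   sid, t$value))
      v
    }, character(1))
    new_fact(a$predicate, vals, derivation = sprintf("inferred(%s)", sid))
  })
}

#' Forward-chain statements over a fact store
#'
#' Repeatedly fires every statement against the store, adding the ground
#' conclusions of each satisfying binding, until a round adds no new fact
#' (fixpoint) or `max_rounds` is exhausted. Unsafe statements (conclusion
#' variables the premise does not bind) are skipped with a warning.
#'
#' @param statements list of [sc_statement()]s.
#' @param store an `sc_factstore`.
#' @param ont an `sc_ontology`.
#' @param max_rounds round budget; defaults to `2 * length(statements) + 2`.
#' @return list with `store` (final facts), `rounds_used`, and
#'   `reached_fixpoint`.
#' @export
forward_chain <- function(statements, store, ont,
                          max_rounds = 2L * length(statements) + 2L) {
  max_rounds <- max(1L, as.integer(max_rounds))
  safe <- Filter(function(s) {
    unsafe <- setdiff(atom_vars(s$conclusion), atom_vars(s$premise))
    if (length(unsafe)) {
      warning(sprintf("skipping unsafe statement %s (unbound: %s)",
                      s$id, paste(unsafe, collapse = ", ")), call. = FALSE)
      FALSE
    } else TRUE
  }, statements)
  rounds <- 0L
  fixpoint <- FALSE
  repeat {
    if (rounds >= max_rounds) break
    rounds <- rounds + 1L
    before <- store_size(store)
    for (s in safe) {
      for (binding in match_premise(s$premise, store, ont)) {
        for (f in ground_conclusion(s$conclusion, binding, s$id))
          store <- add_fact(store, f)
      }
    }
    if (store_size(store) == before) { fixpoint <- TRUE; break }
  }
  list(store = store, rounds_used = rounds, reached_fixpoint = fixpoint)
}

derived_facts <- function(store) {
  Filter(function(f) f$derivation != "asserted", store$facts)
}
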