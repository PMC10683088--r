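# fixture loaders and independent oracles shared across the suite

fx_path <- function(name) {
  p <- system.file("extdata", name, package = "stratcheck")
  if (p == "") p <- file.path("../../inst/extdata", name)
  p
}

fx_ont <- function(name) load_ontology(fx_path(name))

fx_rules <- function(name, ont) load_strategy(fx_path(name), ont)

# all rule fixtures with their schema
FIXTURE_SETS <- list(
  ex4 = c("ex4.rules", "food.onto"),
  ex5 = c("ex5.rules", "food.onto"),
  ex6 = c("ex6.rules", "diabetes.onto"),
  ex7 = c("ex7.rules", "drugs.onto"),
  conflicts = c("conflicts.rules", "diabetes.onto"),
  s30 = c("s30.rules", "diabetes.onto"),
  ex14 = c("ex14.rules", "meals.onto"),
  ex15 = c("ex15.rules", "smoking.onto"),
  inverse = c("inverse.rules", "quantities.onto"))

# --- independent oracle: brute-force elementary-cycle enumeration ------------
# breadth-wise simple-path extension: seed with every edge, extend each path
# by every node it does not contain, and harvest a cycle whenever an edge
# closes a path back to its first node; canonical rotation (smallest first)
# deduplicates. Independent of the anchored DFS in the package.

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[[i]], p)
  out
}

brute_cycles <- function(nodes, edges) {
  adj <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(edges)) adj[edges] <- TRUE
  rotate_min <- function(cyc) {
    k <- which(cyc == min(cyc))[[1]]
    if (k == 1) cyc else c(cyc[k:length(cyc)], cyc[seq_len(k - 1)])
  }
  found <- new.env(parent = emptyenv())
  out <- list()
  paths <- lapply(nodes, function(v) v)
  while (length(paths)) {
    nxt <- list()
    for (p in paths) {
      last <- p[[length(p)]]
      for (w in nodes[adj[last, ]]) {
        if (w == p[[1]] && length(p) >= 1) {
          cyc <- rotate_min(p)
          key <- paste(cyc, collapse = ",")
          if (is.null(found[[key]])) {
            found[[key]] <- TRUE
            out[[length(out) + 1]] <- cyc
          }
        } else if (!w %in% p) {
          nxt[[length(nxt) + 1]] <- c(p, w)
        }
      }
    }
    paths <- nxt
  }
  out
}

# --- independent oracle: exact part correspondence by full enumeration ------
# tries every variable bijection and every atom pairing explicitly

brute_exact_correspond <- function(pa, pb) {
  if (length(pa) != length(pb)) return(FALSE)
  vs_a <- stratcheck:::atom_vars(pa)
  vs_b <- stratcheck:::atom_vars(pb)
  if (length(vs_a) != length(vs_b)) return(FALSE)
  atom_txt <- function(a, map) {
    args <- vapply(a$args, function(t) {
      if (t$kind == "variable") map[[t$value]] else paste0("<", t$kind, ":", t$value, ">")
    }, character(1))
    paste0(a$kind, ":", a$predicate, "(", paste(args, collapse = ","), ")")
  }
  maps <- if (length(vs_a)) perms_of(vs_b) else list(character())
  for (m in maps) {
    map <- as.list(stats::setNames(m, vs_a))
    ka <- sort(vapply(pa, atom_txt, character(1), map = map))
    id <- as.list(stats::setNames(vs_b, vs_b))
    kb <- sort(vapply(pb, atom_txt, character(1), map = id))
    if (identical(ka, kb)) return(TRUE)
  }
  FALSE
}

# --- independent oracle: entity relations by naive reachability --------------

brute_relation <- function(a, b, parents, equivs, disjoints) {
  grp <- function(x) {
    seen <- x
    repeat {
      nxt <- unique(c(seen, unlist(equivs[seen])))
      if (length(nxt) == length(seen)) return(seen)
      seen <- nxt
    }
  }
  ups <- function(x) {
    seen <- grp(x)
    repeat {
      nxt <- unique(c(seen, grp(unlist(parents[seen]))))
      nxt <- nxt[!is.na(nxt)]
      if (length(nxt) == length(seen)) return(seen)
      seen <- nxt
    }
  }
  if (a == b) return("equal")
  if (b %in% grp(a)) return("equivalent")
  if (a %in% setdiff(ups(b), grp(b))) return("ancestor")
  if (b %in% setdiff(ups(a), grp(a))) return("descendant")
  for (x in ups(a)) for (y in ups(b))
    if (y %in% disjoints[[x]] || x %in% disjoints[[y]]) return("disjoint")
  "none"
}

# --- hierarchy-entailment comparison of fact stores --------------------------

facts_match_up_to_hierarchy <- function(sa, sb, ont) {
  rel_ok <- c("equal", "equivalent", "ancestor", "descendant")
  entailed <- function(f, other) {
    for (g in other$facts) {
      if (!identical(unname(g$args), unname(f$args))) next
      if (g$predicate == f$predicate) return(TRUE)
      kind <- if (f$predicate %in% names(ont$classes)) "class" else "property"
      if (g$predicate %in% names(if (kind == "class") ont$classes else ont$properties) &&
          entity_relation(f$predicate, g$predicate, kind, ont) %in% rel_ok)
        return(TRUE)
    }
    FALSE
  }
  all(vapply(sa$facts, entailed, logical(1), other = sb)) &&
    all(vapply(sb$facts, entailed, logical(1), other = sa))
}

# seed facts that fire a strategy's entry points: ground every statement's
# premise with its own individuals, choosing numeric values that satisfy the
# statement's builtins (t + eps for lower bounds, t - eps for upper bounds)
strategy_seed_store <- function(strategy, ont) {
  facts <- list()
  for (s in strategy$statements) {
    vals <- list()
    for (a in s$premise) {
      if (a$kind != "builtin") next
      v <- NULL; cst <- NULL
      for (t in a$args) {
        if (t$kind == "variable") v <- t$value
        if (t$kind == "number") cst <- as.numeric(t$value)
      }
      if (is.null(v) || is.null(cst)) next
      vals[[v]] <- switch(a$predicate,
                          GE = , GT = cst + 0.5, LE = , LT = cst - 0.5,
                          cst)
    }
    for (a in s$premise) {
      if (a$kind == "builtin") next
      args <- vapply(a$args, function(t) {
        if (t$kind != "variable") return(t$value)
        if (!is.null(vals[[t$value]])) return(format(vals[[t$value]]))
        paste0("i_", s$id, "_", t$value)
      }, character(1))
      facts[[length(facts) + 1]] <- list(predicate = a$predicate, args = args)
    }
  }
  fact_store(facts)
}
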