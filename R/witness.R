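# Deterministic generation of example objects ("witnesses") used to confirm
# transitivity, classify cycles and saturate literals: one fresh individual
# per non-numeric variable, and for every comparison threshold t the numeric
# probes t - eps, t, t + eps (eps = 1% of |t|, at least 0.01), so a candidate
# behaves differently from its chain exactly when some probe separates them.

builtin_eps <- function(t) max(abs(t) * 0.01, 0.01)

# variables constrained by comparison builtins anywhere in the atom lists
numeric_vars <- function(atoms) {
  unique(unlist(lapply(Filter(function(a) a$kind == "builtin", atoms), function(a)
    vapply(Filter(function(t) t$kind == "variable", a$args),
           `[[`, character(1), "value"))))
}

# thresholds per numeric variable
var_thresholds <- function(atoms) {
  out <- list()
  for (a in Filter(function(a) a$kind == "builtin", atoms)) {
    v <- NULL; cst <- NULL
    for (t in a$args) {
      if (t$kind == "variable") v <- t$value
      if (t$kind == "number") cst <- as.numeric(t$value)
    }
    if (!is.null(v) && !is.null(cst)) out[[v]] <- c(out[[v]], cst)
  }
  lapply(out, unique)
}

dedupe_atoms <- function(atoms) {
  atoms[!duplicated(vapply(atoms, atom_string, character(1)))]
}

# Ground `seed_atoms` (variables shared by name) into a fact store. Numeric
# variables sweep their probe grids; every combination becomes an independent
# scenario with its own individuals. `threshold_atoms` contributes extra
# probe thresholds without being seeded. `domain_facts` adds the domain/range
# class memberships implied by property atoms (used when saturating literals
# through bridging statements).
witness_store <- function(seed_atoms, ont, threshold_atoms = list(),
                          domain_facts = FALSE, max_scenarios = 64L) {
  seed_atoms <- dedupe_atoms(seed_atoms)
  thr <- var_thresholds(c(seed_atoms, threshold_atoms))
  nvars <- unique(c(numeric_vars(c(seed_atoms, threshold_atoms)), names(thr)))
  probes <- lapply(setNames(nvars, nvars), function(v) {
    ts <- thr[[v]]
    if (is.null(ts)) return(1)
    sort(unique(unlist(lapply(ts, function(t)
      c(t - builtin_eps(t), t, t + builtin_eps(t))))))
  })
  combos <- if (length(probes)) {
    sizes <- lengths(probes)
    total <- prod(sizes)
    if (is.finite(total) && total <= max_scenarios) {
      do.call(expand.grid, c(probes, KEEP.OUT.ATTRS = FALSE))
    } else {
      # materialise only the first max_scenarios combinations (mixed-radix
      # enumeration); building the full grid can be astronomically large
      rows <- lapply(seq_len(max_scenarios) - 1L, function(ix) {
        vals <- numeric(length(probes))
        for (d in seq_along(probes)) {
          vals[[d]] <- probes[[d]][[ix %% sizes[[d]] + 1L]]
          ix <- ix %/% sizes[[d]]
        }
        vals
      })
      grid <- as.data.frame(do.call(rbind, rows))
      names(grid) <- names(probes)
      grid
    }
  } else data.frame(row.names = 1)

  facts <- list()
  for (sc in seq_len(nrow(combos))) {
    val <- function(t) {
      if (t$kind != "variable") return(t$value)
      if (t$value %in% nvars) return(format(combos[sc, t$value], scientific = FALSE))
      sprintf("i_%s_%d", t$value, sc)
    }
    for (a in seed_atoms) {
      if (a$kind == "builtin") next
      vals <- vapply(a$args, val, character(1))
      facts[[length(facts) + 1]] <- new_fact(a$predicate, vals)
      if (domain_facts && a$kind != "class") {
        p <- ont$properties[[a$predicate]]
        if (!is.na(p$domain))
          facts[[length(facts) + 1]] <- new_fact(p$domain, vals[[1]])
        if (p$kind == "object" && !is.na(p$range))
          facts[[length(facts) + 1]] <- new_fact(p$range, vals[[2]])
      }
    }
  }
  fact_store(facts)
}

# derived facts restricted to the given predicates, as a sorted key vector
derived_keys <- function(store, predicates) {
  keep <- Filter(function(f) f$derivation != "asserted" &&
                   f$predicate %in% predicates, store$facts)
  sort(vapply(keep, fact_key, character(1)))
}
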