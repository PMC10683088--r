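# Correspondence between statement parts: a complete backtracking search for a
# variable bijection (plus, in semantic mode, predicate substitutions along
# declared equivalence/hierarchy relations) mapping one atom list onto another
# order-insensitively. Parts are small (<= ~8 atoms), so exhaustive search is
# the right trade-off; entity relations are already O(1) lookups on the
# precomputed closures.

# normalise an integer-threshold strict comparison to its inclusive form so
# that GT(20) and GE(21) compare equal when requested
normalize_builtin <- function(pred, args) {
  cst <- args[[2]]
  if (cst$kind == "number") {
    v <- as.numeric(cst$value)
    if (v == round(v)) {
      if (pred == "GT") return(list(pred = "GE", const = v + 1))
      if (pred == "LT") return(list(pred = "LE", const = v - 1))
    }
    return(list(pred = pred, const = v))
  }
  list(pred = pred, const = cst$value)
}

terms_equal <- function(a, b) {
  if (a$kind != b$kind) return(FALSE)
  if (a$kind == "number") return(as.numeric(a$value) == as.numeric(b$value))
  a$value == b$value
}

# relation between two atoms' predicates usable as a substitution;
# NULL when the atoms cannot correspond
atom_predicate_relation <- function(a, b, ont, mode, normalize_int) {
  if (a$kind != b$kind) return(NULL)
  if (a$kind == "builtin") {
    if (a$predicate == b$predicate &&
        terms_equal(a$args[[2]], b$args[[2]])) return("equal")
    if (normalize_int) {
      na <- normalize_builtin(a$predicate, a$args)
      nb <- normalize_builtin(b$predicate, b$args)
      if (na$pred == nb$pred && identical(na$const, nb$const))
        return("builtin_normalized")
    }
    return(NULL)
  }
  kind <- if (a$kind == "class") "class" else "property"
  rel <- entity_relation(a$predicate, b$predicate, kind, ont)
  if (rel == "equal") return("equal")
  if (mode == "allow_semantic" && rel %in% c("equivalent", "ancestor", "descendant"))
    return(rel)
  NULL
}

# can atom a map onto atom b under (extended) variable bijection vmap?
# returns list(vmap, relation) or NULL
try_atom_pair <- function(a, b, vmap, ont, mode, normalize_int) {
  rel <- atom_predicate_relation(a, b, ont, mode, normalize_int)
  if (is.null(rel)) return(NULL)
  n_cmp <- if (a$kind == "builtin" && rel == "builtin_normalized") 1L else length(a$args)
  for (k in seq_len(n_cmp)) {
    ta <- a$args[[k]]; tb <- b$args[[k]]
    if (ta$kind == "variable" && tb$kind == "variable") {
      fwd <- vmap$fwd[[ta$value]]
      bwd <- vmap$bwd[[tb$value]]
      if (!is.null(fwd)) { if (fwd != tb$value) return(NULL) }
      else if (!is.null(bwd)) { if (bwd != ta$value) return(NULL) }
      else { vmap$fwd[[ta$value]] <- tb$value; vmap$bwd[[tb$value]] <- ta$value }
    } else {
      if (!terms_equal(ta, tb)) return(NULL)
    }
  }
  list(vmap = vmap, relation = rel)
}

# segs: list of list(A = atoms, B = atoms, partial = logical). All segments
# must match under one shared bijection; a partial segment embeds all of A into
# B without consuming every B atom. Returns list(vmap, subs) or NULL.
match_segments <- function(segs, ont, mode, normalize_int = FALSE) {
  for (sg in segs) {
    if (!isTRUE(sg$partial) && length(sg$A) != length(sg$B)) return(NULL)
    if (isTRUE(sg$partial) && length(sg$A) > length(sg$B)) return(NULL)
  }
  subs <- list()
  rec <- function(si, ai, used, vmap) {
    if (si > length(segs)) return(list(vmap = vmap, subs = subs))
    sg <- segs[[si]]
    if (ai > length(sg$A)) return(rec(si + 1L, 1L, NULL, vmap))
    if (ai == 1L) used <- logical(length(sg$B))
    a <- sg$A[[ai]]
    for (bi in seq_along(sg$B)) {
      if (used[[bi]]) next
      hit <- try_atom_pair(a, sg$B[[bi]], vmap, ont, mode, normalize_int)
      if (is.null(hit)) next
      used[[bi]] <- TRUE
      if (hit$relation != "equal")
        subs[[length(subs) + 1]] <<- list(
          atom_a = atom_string(a), atom_b = atom_string(sg$B[[bi]]),
          relation = hit$relation, segment = si)
      res <- rec(si, ai + 1L, used, hit$vmap)
      if (!is.null(res)) return(res)
      if (hit$relation != "equal") subs[[length(subs)]] <<- NULL
      used[[bi]] <- FALSE
    }
    NULL
  }
  rec(1L, 1L, NULL, list(fwd = list(), bwd = list()))
}

new_correspondence <- function(status, vmap = NULL, subs = list()) {
  structure(list(status = status,
                 variable_map = if (is.null(vmap)) list() else vmap$fwd,
                 substitutions = subs),
            class = "sc_correspondence")
}

#' Correspondence between two statement parts
#'
#' Decides whether two atom lists describe the same part up to variable
#' renaming and atom order (`exact`), the same part after additionally
#' replacing predicates by declared equivalent or hierarchically related ones
#' (`semantic`, each substitution recorded), or neither (`none`). The search is
#' complete: if any witness bijection exists, one is found. Individuals and
#' numeric constants must match exactly; builtin atoms match on identical
#' canonical operator and threshold (optionally up to integer normalisation,
#' which makes `GT(20)` equal to `GE(21)`).
#'
#' @param partA,partB nonempty lists of [sc_atom()]s.
#' @param ont an `sc_ontology`.
#' @param mode `"exact_only"` or `"allow_semantic"`.
#' @param normalize_integer_builtins treat strict integer comparisons as their
#'   inclusive equivalents (off by default).
#' @return an `sc_correspondence` with `status`, `variable_map` and
#'   `substitutions`.
#' @export
parts_correspond <- function(partA, partB, ont,
                             mode = c("allow_semantic", "exact_only"),
                             normalize_integer_builtins = FALSE) {
  mode <- match.arg(mode)
  if (!length(partA) || !length(partB)) stop("parts must be nonempty")
  hit <- match_segments(list(list(A = partA, B = partB)), ont, "exact_only",
                        normalize_integer_builtins)
  if (!is.null(hit))
    return(new_correspondence("exact", hit$vmap, hit$subs))
  if (mode == "allow_semantic") {
    hit <- match_segments(list(list(A = partA, B = partB)), ont, "allow_semantic",
                          normalize_integer_builtins)
    if (!is.null(hit))
      return(new_correspondence("semantic", hit$vmap, hit$subs))
  }
  new_correspondence("none")
}

# whole-statement correspondence: premises onto premises and conclusions onto
# conclusions under ONE shared variable bijection
statements_correspond <- function(sx, sy, ont, mode = "allow_semantic",
                                  normalize_integer_builtins = FALSE) {
  segs <- list(list(A = sx$premise, B = sy$premise),
               list(A = sx$conclusion, B = sy$conclusion))
  hit <- match_segments(segs, ont, "exact_only", normalize_integer_builtins)
  if (!is.null(hit)) return(new_correspondence("exact", hit$vmap, hit$subs))
  if (mode == "allow_semantic") {
    hit <- match_segments(segs, ont, "allow_semantic", normalize_integer_builtins)
    if (!is.null(hit)) return(new_correspondence("semantic", hit$vmap, hit$subs))
  }
  new_correspondence("none")
}

#' @export
print.sc_correspondence <- function(x, ...) {
  cat(sprintf("<correspondence: %s", x$status))
  if (length(x$variable_map))
    cat(sprintf("; vars %s",
                paste(sprintf("%s->%s", names(x$variable_map),
                              unlist(x$variable_map)), collapse = " ")))
  cat(">\n")
  for (s in x$substitutions)
    cat(sprintf("  %s ~ %s [%s]\n", s$atom_a, s$atom_b, s$relation))
  invisible(x)
}
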