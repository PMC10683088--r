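# Module M1: dependency-relation extraction. Two scoring techniques per
# statement pair (conclusion-premise and conclusion-conclusion), coefficient
# filtering to a single directed relation, and arc-signature grouping.

new_relation <- function(src, dst, confidence, technique, tie = FALSE) {
  structure(list(src = src, dst = dst, confidence = confidence,
                 technique = technique, tie = tie),
            class = "sc_relation")
}

#' Weight of an atom pair under the entity-relation table
#'
#' The conclusion-premise analysis scores an atom pair by the strongest
#' ontology relation between any class referenced by one atom and any class
#' referenced by the other; when both atoms are property atoms the relation
#' between the two predicates themselves also competes for the maximum. A pair
#' where either atom references no class (e.g. a comparison builtin) weighs 0.
#'
#' @param ai,aj resolved [sc_atom()]s.
#' @param ont an `sc_ontology`.
#' @param cfg an [sc_config()].
#' @return weight in \[0, 1\].
#' @export
atom_pair_weight <- function(ai, aj, ont, cfg = sc_config()) {
  ci <- referenced_classes(ai, ont)
  cj <- referenced_classes(aj, ont)
  if (!length(ci) || !length(cj)) return(0)
  w <- 0
  for (a in ci) for (b in cj)
    w <- max(w, relation_weight(entity_relation(a, b, "class", ont), cfg))
  if (ai$kind %in% c("object_property", "data_property") &&
      aj$kind %in% c("object_property", "data_property"))
    w <- max(w, relation_weight(
      entity_relation(ai$predicate, aj$predicate, "property", ont), cfg))
  w
}

# secondary, tie-breaking signal: does the pair also match at the predicate
# level (same/equivalent/hierarchy-related class or property name)?
atom_pair_pred_score <- function(ai, aj, ont, cfg) {
  if (ai$kind == "builtin" || aj$kind == "builtin") return(0)
  if (ai$kind == "class" && aj$kind == "class")
    return(relation_weight(entity_relation(ai$predicate, aj$predicate, "class", ont), cfg))
  if (ai$kind != "class" && aj$kind != "class")
    return(relation_weight(entity_relation(ai$predicate, aj$predicate, "property", ont), cfg))
  0
}

cp_direction_score <- function(from, to, ont, cfg) {
  cd <- 0; pred <- 0
  for (ai in from$conclusion) for (aj in to$premise) {
    cd <- max(cd, atom_pair_weight(ai, aj, ont, cfg))
    pred <- max(pred, atom_pair_pred_score(ai, aj, ont, cfg))
  }
  list(cd = cd, pred = pred)
}

# lexicographically smaller id first keeps direction tie-breaks independent of
# file order
id_before <- function(a, b) order(c(a, b))[1] == 1

#' Conclusion-premise confidence (first technique)
#'
#' Scores the dependency between two statements from the strongest relation
#' between an atom of one statement's conclusion and an atom of the other's
#' premise, in both directions, and returns the direction with the higher
#' confidence. A confidence tie is broken first by the predicate-level match
#' score of the best atom pair (the direction in which a conclusion predicate
#' is literally consumed by a premise wins), then towards the statement with
#' the smaller id; only the final fallback is flagged as a tie.
#'
#' @param sx,sy distinct [sc_statement()]s.
#' @param ont an `sc_ontology`.
#' @param cfg an [sc_config()].
#' @return an `sc_relation` with `technique = "CP"`.
#' @export
cp_confidence <- function(sx, sy, ont, cfg = sc_config()) {
  fx <- cp_direction_score(sx, sy, ont, cfg)
  fy <- cp_direction_score(sy, sx, ont, cfg)
  if (fx$cd > fy$cd) return(new_relation(sx$id, sy$id, fx$cd, "CP"))
  if (fy$cd > fx$cd) return(new_relation(sy$id, sx$id, fy$cd, "CP"))
  if (fx$pred > fy$pred) return(new_relation(sx$id, sy$id, fx$cd, "CP"))
  if (fy$pred > fx$pred) return(new_relation(sy$id, sx$id, fy$cd, "CP"))
  if (id_before(sx$id, sy$id)) new_relation(sx$id, sy$id, fx$cd, "CP", tie = TRUE)
  else new_relation(sy$id, sx$id, fy$cd, "CP", tie = TRUE)
}

conclusion_classes <- function(s, ont) {
  unique(unlist(lapply(s$conclusion, referenced_classes, ont = ont)))
}

cc_direction_score <- function(cx, cy, ont, cfg) {
  if (!length(cx) || !length(cy)) return(0)
  links <- linking_properties(cx, cy, ont)
  if (!nrow(links)) return(0)
  if (any(links$link == "direct")) return(1.0)
  relation_weight("ancestor", cfg)
}

#' Conclusion-conclusion confidence (second technique)
#'
#' Scores the dependency between two statements from the declared object
#' properties that link the classes referenced by one conclusion to the
#' classes referenced by the other: a direct linking property scores 1, a link
#' requiring a subclass/superclass substitution scores the hierarchy weight,
#' no link scores 0. The higher-confidence direction is returned; an exact tie
#' orients towards the smaller statement id and is flagged.
#'
#' @inheritParams cp_confidence
#' @return an `sc_relation` with `technique = "CC"`.
#' @export
cc_confidence <- function(sx, sy, ont, cfg = sc_config()) {
  cx <- conclusion_classes(sx, ont)
  cy <- conclusion_classes(sy, ont)
  fx <- cc_direction_score(cx, cy, ont, cfg)
  fy <- cc_direction_score(cy, cx, ont, cfg)
  if (fx > fy) return(new_relation(sx$id, sy$id, fx, "CC"))
  if (fy > fx) return(new_relation(sy$id, sx$id, fy, "CC"))
  if (id_before(sx$id, sy$id)) new_relation(sx$id, sy$id, fx, "CC", tie = TRUE)
  else new_relation(sy$id, sx$id, fy, "CC", tie = TRUE)
}

#' Filter the two candidate relations of a statement pair
#'
#' Multiplies each technique's confidence by its coefficient and keeps the
#' relation with the higher product; equal products prefer the
#' conclusion-conclusion relation (the technique carrying the higher
#' coefficient). When the winning technique could not decide a direction (its
#' two directions scored the same confidence) but the other technique did,
#' the winner adopts that decisive direction: a tie carries no directional
#' evidence, while a strict conclusion-to-premise consumption does. Returns
#' `NULL` when neither product exceeds the edge threshold.
#'
#' @param cp,cc `sc_relation`s for the same unordered pair.
#' @param cfg an [sc_config()].
#' @return the winning `sc_relation` (with a `product` field) or `NULL`.
#' @export
filter_relation <- function(cp, cc, cfg = sc_config()) {
  stopifnot(cp$technique == "CP", cc$technique == "CC")
  p_cp <- cp$confidence * cfg$c_cp
  p_cc <- cc$confidence * cfg$c_cc
  if (p_cp <= cfg$threshold && p_cc <= cfg$threshold) return(NULL)
  win <- if (p_cc >= p_cp) cc else cp
  other <- if (p_cc >= p_cp) cp else cc
  if (win$tie && !other$tie && other$confidence > 0) {
    win$src <- other$src
    win$dst <- other$dst
    win$tie <- FALSE
  }
  win$product <- max(p_cp, p_cc)
  win
}

#' Build the statement dependency graph
#'
#' Runs both scoring techniques on every unordered statement pair, filters to
#' at most one directed relation per pair, and assembles the dependency graph.
#' Deterministic for fixed inputs and invariant (up to node order) under
#' permutations of the strategy file.
#'
#' @param strategy an `sc_strategy`.
#' @param ont an `sc_ontology`.
#' @param cfg an [sc_config()].
#' @return an `sc_depgraph` with `nodes`, an edge data.frame (`src`, `dst`,
#'   `confidence`, `technique`, `tie`, `product`) and the threshold used.
#' @export
build_graph <- function(strategy, ont, cfg = sc_config()) {
  sts <- strategy$statements
  ids <- strategy_ids(strategy)
  rows <- list()
  n <- length(sts)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      cp <- cp_confidence(sts[[i]], sts[[j]], ont, cfg)
      cc <- cc_confidence(sts[[i]], sts[[j]], ont, cfg)
      win <- filter_relation(cp, cc, cfg)
      if (!is.null(win))
        rows[[length(rows) + 1]] <- data.frame(
          src = win$src, dst = win$dst, confidence = win$confidence,
          technique = win$technique, tie = win$tie, product = win$product,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(src = character(), dst = character(), confidence = numeric(),
               technique = character(), tie = logical(), product = numeric(),
               stringsAsFactors = FALSE)
  structure(list(nodes = ids, edges = edges, threshold = cfg$threshold),
            class = "sc_depgraph")
}

graph_preds <- function(g, id) sort(unique(g$edges$src[g$edges$dst == id]))
graph_succs <- function(g, id) sort(unique(g$edges$dst[g$edges$src == id]))

has_edge <- function(g, a, b) any(g$edges$src == a & g$edges$dst == b)

edge_is_tie <- function(g, a, b) {
  hit <- g$edges$src == a & g$edges$dst == b
  any(hit) && all(g$edges$tie[hit])
}

#' @export
print.sc_depgraph <- function(x, ...) {
  cat(sprintf("<dependency graph: %d statements, %d relations>\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -> %s  [%s %.2f]\n", x$edges$src[i], x$edges$dst[i],
                  x$edges$technique[i], x$edges$confidence[i]))
  invisible(x)
}

#' Group statements by arc signature
#'
#' Partitions the graph's statements into groups whose members share identical
#' incoming and outgoing arcs. Arcs between the members of a candidate group
#' are set aside when comparing signatures, and a merge is accepted only when
#' every such internal arc was a tie-broken (symmetric-confidence) relation:
#' mutually dependent parallel statements coalesce while genuine one-way
#' chains stay apart. Statements with no arcs at all remain singletons.
#'
#' @param g an `sc_depgraph`.
#' @return a list of `sc_group`s (`id`, `members`, `in_arcs`, `out_arcs`, the
#'   latter two as group ids); the list carries the member-to-group map in
#'   attribute `membership`.
#' @export
group_statements <- function(g) {
  ids <- g$nodes
  preds <- lapply(setNames(ids, ids), function(v) graph_preds(g, v))
  succs <- lapply(setNames(ids, ids), function(v) graph_succs(g, v))
  isolated <- vapply(ids, function(v) !length(preds[[v]]) && !length(succs[[v]]),
                     logical(1))

  # initial partition of non-isolated nodes by exact signature
  keyed <- split(ids[!isolated], vapply(ids[!isolated], function(v)
    paste(paste(preds[[v]], collapse = ","), "|",
          paste(succs[[v]], collapse = ",")), character(1)))
  groups <- unname(lapply(keyed, identity))
  groups <- c(groups, lapply(ids[isolated], identity))

  ext_sig <- function(members) {
    ps <- lapply(members, function(v) setdiff(preds[[v]], members))
    ss <- lapply(members, function(v) setdiff(succs[[v]], members))
    ok <- all(vapply(ps, function(x) identical(x, ps[[1]]), logical(1))) &&
      all(vapply(ss, function(x) identical(x, ss[[1]]), logical(1)))
    list(ok = ok, p = ps[[1]], s = ss[[1]])
  }

  mergeable <- function(a, b) {
    m <- sort(c(a, b))
    if (any(m %in% ids[isolated])) return(FALSE)
    sig <- ext_sig(m)
    if (!sig$ok) return(FALSE)
    # all arcs inside the union must be tie-broken relations
    inner <- g$edges$src %in% m & g$edges$dst %in% m
    all(g$edges$tie[inner])
  }

  changed <- TRUE
  while (changed) {
    changed <- FALSE
    ng <- length(groups)
    for (i in seq_len(ng)) {
      if (i > length(groups)) break
      j <- i + 1
      while (j <= length(groups)) {
        if (mergeable(groups[[i]], groups[[j]])) {
          groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          changed <- TRUE
        } else j <- j + 1
      }
    }
  }

  # deterministic order by smallest member id
  groups <- groups[order(vapply(groups, min, character(1)))]
  membership <- setNames(rep(NA_character_, length(ids)), ids)
  gids <- sprintf("G%02d", seq_along(groups))
  for (k in seq_along(groups)) membership[groups[[k]]] <- gids[[k]]
  out <- lapply(seq_along(groups), function(k) {
    members <- sort(groups[[k]])
    epred <- unique(unlist(lapply(members, function(v) setdiff(preds[[v]], members))))
    esucc <- unique(unlist(lapply(members, function(v) setdiff(succs[[v]], members))))
    structure(list(id = gids[[k]], members = members,
                   in_arcs = sort(unique(membership[epred])),
                   out_arcs = sort(unique(membership[esucc]))),
              class = "sc_group")
  })
  attr(out, "membership") <- membership
  out
}

#' @export
print.sc_group <- function(x, ...) {
  cat(sprintf("<group %s: {%s} in={%s} out={%s}>\n", x$id,
              paste(x$members, collapse = ","),
              paste(x$in_arcs, collapse = ","),
              paste(x$out_arcs, collapse = ",")))
  invisible(x)
}

#' Export the dependency graph
#'
#' Writes DOT or GraphML with nodes labelled by statement id and edges
#' labelled `technique:confidence`.
#'
#' @param g an `sc_depgraph`.
#' @param path output file.
#' @param format `"dot"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  ig <- igraph::graph_from_data_frame(
    if (nrow(g$edges)) g$edges[, c("src", "dst")] else
      data.frame(src = character(), dst = character()),
    directed = TRUE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE))
  if (nrow(g$edges))
    ig <- igraph::set_edge_attr(ig, "label",
                                value = sprintf("%s:%.2f", g$edges$technique,
                                                g$edges$confidence))
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}

#' Export statement groups as JSON
#'
#' @param groups result of [group_statements()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_groups <- function(groups, path) {
  obj <- lapply(groups, function(gr)
    list(members = gr$members, in_arcs = gr$in_arcs, out_arcs = gr$out_arcs))
  names(obj) <- vapply(groups, `[[`, character(1), "id")
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
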