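#' @importFrom stats setNames
#' @importFrom utils head tail
NULL

new_class_def <- function(name) {
  list(name = name, parents = character(), equivalents = character(),
       disjoints = character())
}

new_property_def <- function(name, kind) {
  list(name = name, kind = kind, domain = NA_character_, range = NA_character_,
       parents = character(), equivalents = character(), inverse = NA_character_,
       data_range = NULL)
}

#' Load an ontology schema
#'
#' Reads the line-based native schema dialect into an ontology model holding
#' class and property taxonomies, declared equivalences, disjointness, inverse
#' properties and data ranges. Symmetric closures (disjointness, equivalence)
#' and the involutive inverse are applied on load, and every cross-reference is
#' checked against the declared names.
#'
#' The native dialect is one declaration per line, `#` starts a comment:
#' ```
#' class Patient < Person
#' class DiabetesType1 disjoint DiabetesType2
#' class Meal equiv Repast
#' objprop hasFood domain Patient range Food
#' objprop hasLunch < hasFood
#' objprop hasPatient inverse hasDoctor
#' dataprop age domain Person range integer[0..150]
#' dataprop hasSymptomsT2 domain Person range {True,False}
#' ```
#' Repeated lines for one entity accumulate into a single definition.
#'
#' @param path path to a schema file.
#' @param format only `"native"` is supported; the argument mirrors the loader
#'   interface so an OWL ingester can slot in behind the same model.
#' @return an object of class `sc_ontology` with components `classes` and
#'   `properties` (named lists of definitions).
#' @seealso [entity_relation()], [referenced_classes()], [linking_properties()]
#' @export
load_ontology <- function(path, format = c("native", "owl")) {
  format <- match.arg(format)
  if (format == "owl")
    stop("OWL loading is not available in this build; use the native format")
  if (!file.exists(path)) stop("ontology file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  parse_ontology_lines(lines, source = path)
}

#' Parse ontology schema text
#'
#' @param text a character vector of schema lines (or a single string with
#'   embedded newlines).
#' @param source label used in error messages.
#' @return an `sc_ontology`.
#' @export
parse_ontology <- function(text, source = "<text>") {
  parse_ontology_lines(unlist(strsplit(text, "\n", fixed = TRUE)), source)
}

parse_ontology_lines <- function(lines, source) {
  classes <- list()
  properties <- list()
  # deferred cross-entity assertions, checked after all declarations are seen
  defer <- list()

  strip <- function(x) {
    x <- sub("#.*$", "", x)
    trimws(x)
  }

  for (i in seq_along(lines)) {
    ln <- strip(lines[[i]])
    if (ln == "") next
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    kw <- toks[[1]]
    err <- function(msg) stop(sprintf("%s:%d: %s", source, i, msg), call. = FALSE)
    if (length(toks) < 2) err("declaration needs a name")
    name <- toks[[2]]
    rest <- toks[-(1:2)]
    if (kw == "class") {
      if (is.null(classes[[name]])) classes[[name]] <- new_class_def(name)
      j <- 1
      while (j <= length(rest)) {
        op <- rest[[j]]
        if (j + 1 > length(rest)) err(sprintf("'%s' needs an operand", op))
        val <- rest[[j + 1]]
        if (op == "<") {
          classes[[name]]$parents <- union(classes[[name]]$parents, val)
          defer[[length(defer) + 1]] <- list(kind = "class", name = val, where = i)
        } else if (op == "disjoint") {
          classes[[name]]$disjoints <- union(classes[[name]]$disjoints, val)
          defer[[length(defer) + 1]] <- list(kind = "class", name = val, where = i)
        } else if (op == "equiv") {
          classes[[name]]$equivalents <- union(classes[[name]]$equivalents, val)
          defer[[length(defer) + 1]] <- list(kind = "class", name = val, where = i)
        } else err(sprintf("unknown class operator '%s'", op))
        j <- j + 2
      }
    } else if (kw %in% c("objprop", "dataprop")) {
      pkind <- if (kw == "objprop") "object" else "data"
      if (is.null(properties[[name]])) properties[[name]] <- new_property_def(name, pkind)
      if (properties[[name]]$kind != pkind)
        err(sprintf("property '%s' redeclared with a different kind", name))
      j <- 1
      while (j <= length(rest)) {
        op <- rest[[j]]
        if (j + 1 > length(rest)) err(sprintf("'%s' needs an operand", op))
        val <- rest[[j + 1]]
        if (op == "domain") {
          properties[[name]]$domain <- val
          defer[[length(defer) + 1]] <- list(kind = "class", name = val, where = i)
        } else if (op == "range") {
          if (pkind == "object") {
            properties[[name]]$range <- val
            defer[[length(defer) + 1]] <- list(kind = "class", name = val, where = i)
          } else {
            properties[[name]]$data_range <- parse_data_range(val, err)
            properties[[name]]$range <- val
          }
        } else if (op == "<") {
          properties[[name]]$parents <- union(properties[[name]]$parents, val)
          defer[[length(defer) + 1]] <- list(kind = "prop", name = val, pk = pkind, where = i)
        } else if (op == "equiv") {
          properties[[name]]$equivalents <- union(properties[[name]]$equivalents, val)
          defer[[length(defer) + 1]] <- list(kind = "prop", name = val, pk = pkind, where = i)
        } else if (op == "inverse") {
          if (pkind != "object") err("inverse applies to object properties only")
          properties[[name]]$inverse <- val
          defer[[length(defer) + 1]] <- list(kind = "prop", name = val, pk = "object", where = i)
        } else err(sprintf("unknown property operator '%s'", op))
        j <- j + 2
      }
    } else {
      err(sprintf("unknown declaration '%s' (expected class/objprop/dataprop)", kw))
    }
  }

  for (d in defer) {
    ok <- if (d$kind == "class") !is.null(classes[[d$name]]) else !is.null(properties[[d$name]])
    if (!ok)
      stop(sprintf("%s:%d: reference to undeclared %s '%s'",
                   source, d$where, if (d$kind == "class") "class" else "property",
                   d$name), call. = FALSE)
  }

  ont <- structure(list(classes = classes, properties = properties),
                   class = "sc_ontology")
  finalize_ontology(ont)
}

parse_data_range <- function(val, err) {
  m <- regmatches(val, regexec("^(integer|decimal)\\[(-?[0-9.]+)\\.\\.(-?[0-9.]+)\\]$", val))[[1]]
  if (length(m) == 4) {
    lo <- as.numeric(m[[3]]); hi <- as.numeric(m[[4]])
    if (is.na(lo) || is.na(hi) || lo > hi) err(sprintf("bad interval '%s'", val))
    return(list(type = m[[2]], lo = lo, hi = hi))
  }
  if (grepl("^\\{.*\\}$", val)) {
    vals <- strsplit(gsub("[{}]", "", val), ",", fixed = TRUE)[[1]]
    return(list(type = "enum", values = trimws(vals)))
  }
  if (val %in% c("integer", "decimal", "string", "boolean"))
    return(list(type = val))
  err(sprintf("unparseable data range '%s'", val))
}

# Symmetric/involutive closures plus precomputed equivalence groups and
# ancestor sets; validates acyclicity and disjointness sanity.
finalize_ontology <- function(ont) {
  # symmetric disjointness and equivalence for classes
  for (nm in names(ont$classes)) {
    for (d in ont$classes[[nm]]$disjoints)
      ont$classes[[d]]$disjoints <- union(ont$classes[[d]]$disjoints, nm)
    for (e in ont$classes[[nm]]$equivalents)
      ont$classes[[e]]$equivalents <- union(ont$classes[[e]]$equivalents, nm)
  }
  for (nm in names(ont$properties)) {
    for (e in ont$properties[[nm]]$equivalents)
      ont$properties[[e]]$equivalents <- union(ont$properties[[e]]$equivalents, nm)
    inv <- ont$properties[[nm]]$inverse
    if (!is.na(inv)) {
      other <- ont$properties[[inv]]$inverse
      if (!is.na(other) && other != nm)
        stop(sprintf("inverse of '%s' conflicts: '%s' vs '%s'", inv, other, nm))
      ont$properties[[inv]]$inverse <- nm
    }
  }
  for (nm in names(ont$classes))
    if (nm %in% ont$classes[[nm]]$parents)
      stop(sprintf("cyclic hierarchy: class '%s' is its own parent", nm))
  for (nm in names(ont$properties))
    if (nm %in% ont$properties[[nm]]$parents)
      stop(sprintf("cyclic hierarchy: property '%s' is its own parent", nm))
  ont$class_equiv <- equivalence_groups(ont$classes)
  ont$prop_equiv <- equivalence_groups(ont$properties)
  ont$class_anc <- ancestor_sets(ont$classes, ont$class_equiv)
  ont$prop_anc <- ancestor_sets(ont$properties, ont$prop_equiv)
  # invariants: no class disjoint with itself, an equivalent or an ancestor
  for (nm in names(ont$classes)) {
    bad <- intersect(ont$classes[[nm]]$disjoints,
                     c(nm, ont$class_equiv[[nm]], ont$class_anc[[nm]]))
    if (length(bad))
      stop(sprintf("class '%s' declared disjoint with itself/equivalent/ancestor '%s'",
                   nm, bad[[1]]))
  }
  ont
}

# reflexive-symmetric-transitive closure of declared equivalences
equivalence_groups <- function(defs) {
  nms <- names(defs)
  rep_of <- setNames(nms, nms)
  find <- function(x) { while (rep_of[[x]] != x) x <- rep_of[[x]]; x }
  for (nm in nms) for (e in defs[[nm]]$equivalents) {
    ra <- find(nm); rb <- find(e)
    if (ra != rb) rep_of[[rb]] <- ra
  }
  roots <- vapply(nms, find, character(1))
  lapply(setNames(nms, nms), function(nm) nms[roots == roots[[nm]]])
}

# ancestor closure through parents of any equivalence-group member; errors on
# a cyclic hierarchy
ancestor_sets <- function(defs, equiv) {
  nms <- names(defs)
  anc <- setNames(vector("list", length(nms)), nms)
  state <- setNames(integer(length(nms)), nms)  # 0 unseen, 1 active, 2 done
  visit <- function(nm) {
    if (state[[nm]] == 1L) stop(sprintf("cyclic hierarchy at '%s'", nm))
    if (state[[nm]] == 2L) return(anc[[nm]])
    state[[nm]] <<- 1L
    direct <- unique(unlist(lapply(equiv[[nm]], function(e) defs[[e]]$parents)))
    direct <- setdiff(direct, equiv[[nm]])
    up <- unique(unlist(c(list(direct), lapply(direct, visit))))
    # fold ancestors' equivalents in as ancestors too
    up <- unique(unlist(c(list(up), equiv[up])))
    anc[[nm]] <<- setdiff(up, equiv[[nm]])
    state[[nm]] <<- 2L
    anc[[nm]]
  }
  for (nm in nms) visit(nm)
  anc
}

is_declared <- function(ont, name, kind) {
  if (kind == "class") !is.null(ont$classes[[name]]) else !is.null(ont$properties[[name]])
}

#' Semantic relation between two ontology entities
#'
#' Answers which relation holds between two declared classes or two declared
#' properties, with the precedence equal > equivalent > ancestor/descendant >
#' disjoint > none. `"ancestor"` means `a` is an ancestor of `b`. Hierarchy is
#' resolved through the full transitive closure and through declared
#' equivalences; disjointness (classes only) is inherited downwards.
#'
#' @param a,b entity names.
#' @param kind `"class"` or `"property"`.
#' @param ont an `sc_ontology`.
#' @return one of `"equal"`, `"equivalent"`, `"ancestor"`, `"descendant"`,
#'   `"disjoint"`, `"none"`.
#' @export
entity_relation <- function(a, b, kind = c("class", "property"), ont) {
  kind <- match.arg(kind)
  for (x in c(a, b)) if (!is_declared(ont, x, kind))
    stop(sprintf("unknown %s '%s'", kind, x))
  if (a == b) return("equal")
  equiv <- if (kind == "class") ont$class_equiv else ont$prop_equiv
  anc <- if (kind == "class") ont$class_anc else ont$prop_anc
  if (b %in% equiv[[a]]) return("equivalent")
  if (a %in% anc[[b]]) return("ancestor")
  if (b %in% anc[[a]]) return("descendant")
  if (kind == "class" && classes_disjoint(a, b, ont)) return("disjoint")
  "none"
}

classes_disjoint <- function(a, b, ont) {
  ups_a <- unique(c(a, ont$class_equiv[[a]], ont$class_anc[[a]]))
  ups_b <- unique(c(b, ont$class_equiv[[b]], ont$class_anc[[b]]))
  for (x in ups_a) {
    if (length(intersect(ont$classes[[x]]$disjoints, ups_b))) return(TRUE)
  }
  FALSE
}

#' Classes referenced by an atom
#'
#' A class atom references its class; an object-property atom references the
#' property's declared domain and range; a data-property atom references only
#' the domain; a comparison builtin references no class.
#'
#' @param atom an `sc_atom`.
#' @param ont an `sc_ontology`.
#' @return character vector of class names (possibly empty).
#' @export
referenced_classes <- function(atom, ont) {
  switch(atom$kind,
    class = atom$predicate,
    object_property = {
      p <- ont$properties[[atom$predicate]]
      if (is.null(p)) stop("undeclared property: ", atom$predicate)
      as.character(stats::na.omit(c(p$domain, p$range)))
    },
    data_property = {
      p <- ont$properties[[atom$predicate]]
      if (is.null(p)) stop("undeclared property: ", atom$predicate)
      as.character(stats::na.omit(c(p$domain)))
    },
    builtin = character(),
    stop("unknown atom kind: ", atom$kind)
  )
}

#' Object properties linking two class sets
#'
#' Scans the declared object properties for those whose domain is related (by
#' equality, equivalence or hierarchy) to some class in `src_classes` and whose
#' range is related to some class in `dst_classes`. A link is `direct` when both
#' the domain and the range match by equality or equivalence, and
#' `hierarchical` when a subclass/superclass substitution is needed on either
#' end.
#'
#' @param src_classes,dst_classes character vectors of declared class names.
#' @param ont an `sc_ontology`.
#' @return a data.frame with columns `property`, `src_class`, `dst_class`,
#'   `link` (`"direct"`/`"hierarchical"`); zero rows when no property links the
#'   two sets.
#' @export
linking_properties <- function(src_classes, dst_classes, ont) {
  for (cl in c(src_classes, dst_classes)) if (is.null(ont$classes[[cl]]))
    stop(sprintf("unknown class '%s'", cl))
  out <- list()
  hier_ok <- c("equal", "equivalent", "ancestor", "descendant")
  for (pn in names(ont$properties)) {
    p <- ont$properties[[pn]]
    if (p$kind != "object" || is.na(p$domain) || is.na(p$range)) next
    for (s in src_classes) {
      rs <- entity_relation(p$domain, s, "class", ont)
      if (!rs %in% hier_ok) next
      for (d in dst_classes) {
        rd <- entity_relation(p$range, d, "class", ont)
        if (!rd %in% hier_ok) next
        link <- if (rs %in% c("equal", "equivalent") && rd %in% c("equal", "equivalent"))
          "direct" else "hierarchical"
        out[[length(out) + 1]] <- data.frame(property = pn, src_class = s,
                                             dst_class = d, link = link,
                                             stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(property = character(), src_class = character(),
                      dst_class = character(), link = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Check a constant against a data property's declared range
#'
#' @param prop name of a declared data property.
#' @param value the constant to check (number or string).
#' @param ont an `sc_ontology`.
#' @return `TRUE`, `FALSE`, or `NA` when the property declares no range
#'   (indeterminate, distinct from illegal).
#' @export
check_value_legal <- function(prop, value, ont) {
  p <- ont$properties[[prop]]
  if (is.null(p)) stop(sprintf("unknown property '%s'", prop))
  if (p$kind != "data") stop(sprintf("'%s' is not a data property", prop))
  dr <- p$data_range
  if (is.null(dr)) return(NA)
  if (dr$type %in% c("integer", "decimal")) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) return(FALSE)
    if (dr$type == "integer" && v != round(v)) return(FALSE)
    if (is.null(dr$lo)) return(TRUE)
    return(v >= dr$lo && v <= dr$hi)
  }
  if (dr$type == "enum") return(as.character(value) %in% dr$values)
  if (dr$type == "boolean") return(as.character(value) %in% c("True", "False", "true", "false"))
  if (dr$type == "string") return(is.character(value) || !is.na(as.character(value)))
  NA
}

#' @export
print.sc_ontology <- function(x, ...) {
  cat(sprintf("<ontology: %d classes, %d properties>\n",
              length(x$classes), length(x$properties)))
  invisible(x)
}
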