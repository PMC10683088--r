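# Builtin comparison vocabulary. The rule dialect in the wild mixes several
# spellings for the same comparison; everything normalises to a canonical
# operator at parse time.
BUILTIN_ALIASES <- c(
  equalOrGreaterThan = "GE", greaterThanOrEqual = "GE", GE = "GE",
  equalOrLessThan = "LE", lessThanOrEqual = "LE", LE = "LE",
  moreThan = "GT", greaterThan = "GT", isGreaterThan = "GT", GT = "GT",
  lessThan = "LT", isLessThan = "LT", LT = "LT",
  equal = "EQ", EQ = "EQ",
  notEqual = "NE", NE = "NE"
)

#' Construct a term
#'
#' Terms are variables (bare lowercase identifiers), individuals (identifiers
#' starting with an uppercase letter, or lowercase identifiers containing `-`,
#' as in `high-level`), numbers, or quoted strings.
#'
#' @param kind one of `"variable"`, `"individual"`, `"number"`, `"string"`.
#' @param value identifier or literal (numbers kept as their source text so
#'   serialisation preserves them exactly).
#' @return an `sc_term`.
#' @export
sc_term <- function(kind, value) {
  structure(list(kind = kind, value = as.character(value)), class = "sc_term")
}

parse_term <- function(txt) {
  txt <- trimws(txt)
  if (grepl('^".*"$', txt)) return(sc_term("string", gsub('^"|"$', "", txt)))
  if (grepl("^-?[0-9]+(\\.[0-9]+)?$", txt)) return(sc_term("number", txt))
  if (grepl("^[a-z][A-Za-z0-9_]*$", txt)) return(sc_term("variable", txt))
  if (grepl("^[A-Za-z][A-Za-z0-9_-]*$", txt)) return(sc_term("individual", txt))
  stop(sprintf("unparseable term '%s'", txt), call. = FALSE)
}

term_string <- function(t) {
  if (t$kind == "string") sprintf('"%s"', t$value) else t$value
}

#' Construct an atom
#'
#' @param kind `"class"`, `"object_property"`, `"data_property"` or
#'   `"builtin"`.
#' @param predicate predicate name (canonical comparison name for builtins).
#' @param args list of [sc_term()]s; one for class atoms, two otherwise.
#' @return an `sc_atom`.
#' @export
sc_atom <- function(kind, predicate, args) {
  want <- if (kind == "class") 1L else 2L
  if (length(args) != want)
    stop(sprintf("atom %s/%s: expected %d argument(s), got %d",
                 kind, predicate, want, length(args)))
  structure(list(kind = kind, predicate = predicate, args = args),
            class = "sc_atom")
}

atom_string <- function(a) {
  sprintf("%s(%s)", a$predicate,
          paste(vapply(a$args, term_string, character(1)), collapse = ","))
}

#' @export
format.sc_atom <- function(x, ...) atom_string(x)

#' @export
print.sc_atom <- function(x, ...) { cat(atom_string(x), "\n"); invisible(x) }

atom_vars <- function(atoms) {
  unique(unlist(lapply(atoms, function(a)
    vapply(Filter(function(t) t$kind == "variable", a$args),
           function(t) t$value, character(1)))))
}

#' Construct a statement
#'
#' @param id unique label, e.g. `"S01"`.
#' @param premise,conclusion nonempty lists of [sc_atom()]s.
#' @param provenance `"original"` or `"added"`.
#' @param ordinal declaration position within the strategy.
#' @return an `sc_statement`.
#' @export
sc_statement <- function(id, premise, conclusion, provenance = "original",
                         ordinal = NA_integer_) {
  if (!length(premise) || !length(conclusion))
    stop(sprintf("statement %s: premise and conclusion must be nonempty", id))
  unsafe <- setdiff(atom_vars(conclusion), atom_vars(premise))
  if (length(unsafe))
    warning(sprintf("statement %s: conclusion variable(s) %s not bound by the premise",
                    id, paste(unsafe, collapse = ", ")), call. = FALSE)
  structure(list(id = id, premise = premise, conclusion = conclusion,
                 provenance = provenance, ordinal = ordinal),
            class = "sc_statement")
}

statement_string <- function(s) {
  sprintf("%s: %s -> %s", s$id,
          paste(vapply(s$premise, atom_string, character(1)), collapse = ", "),
          paste(vapply(s$conclusion, atom_string, character(1)), collapse = ", "))
}

#' @export
print.sc_statement <- function(x, ...) { cat(statement_string(x), "\n"); invisible(x) }

#' @export
print.sc_strategy <- function(x, ...) {
  cat(sprintf("<strategy '%s': %d statements>\n", x$source, length(x$statements)))
  for (s in x$statements) cat(" ", statement_string(s), "\n")
  invisible(x)
}

new_strategy <- function(statements, source = "<memory>") {
  ids <- vapply(statements, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate statement id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(statements) <- ids
  structure(list(statements = statements, source = source), class = "sc_strategy")
}

strategy_ids <- function(strategy) {
  vapply(strategy$statements, `[[`, character(1), "id")
}

#' Parse a strategy file or text
#'
#' One statement per line in the form `ID: atom, atom, ... -> atom, ...`;
#' `#` starts a comment. Atom kinds are resolved against the ontology: a unary
#' atom whose predicate is a declared class is a class atom; a binary atom is an
#' object-property, data-property or builtin atom depending on the declaration
#' (builtin spellings normalise to canonical comparison operators `GE`, `LE`,
#' `GT`, `LT`, `EQ`, `NE`). A conclusion variable that the premise does not
#' bind raises a load-time warning, not an error.
#'
#' @param text strategy source text (character vector of lines or one string).
#' @param ont an `sc_ontology` used to resolve predicates.
#' @param source label for error messages.
#' @param provenance provenance tag applied to every parsed statement.
#' @return an `sc_strategy`.
#' @export
parse_strategy <- function(text, ont, source = "<text>", provenance = "original") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  statements <- list()
  ordinal <- 0L
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[[i]]))
    if (ln == "") next
    err <- function(msg) stop(sprintf("%s:%d: %s", source, i, msg), call. = FALSE)
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)[[:space:]]*:[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) != 3) err("expected 'ID: premise -> conclusion'")
    id <- m[[2]]
    body <- m[[3]]
    parts <- strsplit(body, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2) err("expected exactly one '->'")
    ordinal <- ordinal + 1L
    prem <- parse_atom_list(parts[[1]], ont, err)
    conc <- parse_atom_list(parts[[2]], ont, err)
    if (!length(prem)) err("empty premise")
    if (!length(conc)) err("empty conclusion")
    statements[[length(statements) + 1]] <-
      sc_statement(id, prem, conc, provenance = provenance, ordinal = ordinal)
  }
  new_strategy(statements, source = source)
}

#' Load a strategy file
#'
#' @param path path to a strategy file in the rule dialect.
#' @inheritParams parse_strategy
#' @return an `sc_strategy`.
#' @export
load_strategy <- function(path, ont, provenance = "original") {
  if (!file.exists(path)) stop("strategy file not found: ", path)
  parse_strategy(readLines(path, warn = FALSE, encoding = "UTF-8"), ont,
                 source = path, provenance = provenance)
}

# split "a(x), b(x,y)" at top-level commas (commas inside parentheses separate
# arguments, not atoms)
split_atoms <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L; buf <- character(); out <- character()
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      out <- c(out, paste(buf, collapse = "")); buf <- character()
    } else buf <- c(buf, ch)
  }
  out <- c(out, paste(buf, collapse = ""))
  out <- trimws(out)
  out[out != ""]
}

parse_atom_list <- function(txt, ont, err) {
  lapply(split_atoms(txt), function(atxt) {
    m <- regmatches(atxt, regexec("^([A-Za-z][A-Za-z0-9_-]*)\\((.*)\\)$", atxt))[[1]]
    if (length(m) != 3) err(sprintf("unparseable atom '%s'", atxt))
    pred <- m[[2]]
    args <- lapply(split_atoms(m[[3]]), parse_term)
    resolve_atom(pred, args, ont, err, atxt)
  })
}

resolve_atom <- function(pred, args, ont, err, atxt) {
  n <- length(args)
  if (n == 1L) {
    if (is.null(ont$classes[[pred]]))
      err(sprintf("'%s': unary predicate '%s' is not a declared class", atxt, pred))
    return(sc_atom("class", pred, args))
  }
  if (n == 2L) {
    p <- ont$properties[[pred]]
    if (!is.null(p))
      return(sc_atom(if (p$kind == "object") "object_property" else "data_property",
                     pred, args))
    if (pred %in% names(BUILTIN_ALIASES))
      return(sc_atom("builtin", BUILTIN_ALIASES[[pred]], args))
    err(sprintf("'%s': binary predicate '%s' is neither a declared property nor a comparison builtin",
                atxt, pred))
  }
  err(sprintf("'%s': atoms have one or two arguments", atxt))
}

#' Serialize a strategy back to the rule dialect
#'
#' Inverse of [parse_strategy()]: parsing the result yields an atom-for-atom
#' identical strategy (builtins appear under their canonical operator names;
#' numeric literals are preserved exactly as parsed).
#'
#' @param s an `sc_strategy`.
#' @return a single string of dialect text.
#' @export
serialize_strategy <- function(s) {
  header <- sprintf("# strategy: %s (%d statements)", s$source, length(s$statements))
  body <- vapply(s$statements, statement_string, character(1))
  paste(c(header, body), collapse = "\n")
}
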