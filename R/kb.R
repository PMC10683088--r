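# Anomalies knowledge base: persistent findings (cycles, probable conflicts)
# and expert verdicts, consulted on later runs so validated false positives
# are not re-reported. Entries are keyed by a canonical readable string
# (kind family + normalised members) that is stable under cycle rotation and
# pair reordering, which keeps the JSON file deterministic and diff-able.

KB_SCHEMA_VERSION <- 1L

kind_family <- function(kind) {
  if (kind %in% c("cycle_real", "cycle_fake")) return("cycle")
  if (kind %in% c("conflict_probable", "conflict_false", "conflict_strong"))
    return("conflict")
  kind
}

canonical_members <- function(kind, members) {
  if (kind_family(kind) == "cycle") canonical_cycle(members) else sort(members)
}

kb_key <- function(kind, members) {
  paste(c(kind_family(kind), canonical_members(kind, members)), collapse = "|")
}

kb_clock <- function() {
  clk <- getOption("stratcheck.clock", NULL)
  if (is.function(clk)) clk() else format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Create an empty anomalies knowledge base
#'
#' @param path file the knowledge base saves to (optional until [save_kb()]).
#' @return an `sc_kb`.
#' @export
new_kb <- function(path = NULL) {
  structure(list(entries = list(), path = path), class = "sc_kb")
}

#' Record an anomaly in the knowledge base
#'
#' Upserts by canonical key. Fake cycles enter as `confirmed` (the
#' classification is mechanical); real cycles and probable conflicts enter as
#' `pending_expert`. Re-detection never downgrades an expert verdict
#' (`confirmed` / `false_positive` are kept).
#'
#' @param kb an `sc_kb`.
#' @param anomaly an anomaly record with persistable kind (`cycle_real`,
#'   `cycle_fake`, `conflict_probable`, `conflict_false`).
#' @return list with the updated `kb` and the affected `entry`.
#' @export
kb_record <- function(kb, anomaly) {
  persistable <- c("cycle_real", "cycle_fake", "conflict_probable", "conflict_false")
  if (!anomaly$kind %in% persistable)
    stop(sprintf("anomaly kind '%s' is not persistable", anomaly$kind))
  key <- kb_key(anomaly$kind, anomaly$members)
  now <- kb_clock()
  old <- kb$entries[[key]]
  if (is.null(old)) {
    entry <- list(key = key, kind = anomaly$kind,
                  members = canonical_members(anomaly$kind, anomaly$members),
                  status = if (anomaly$kind == "cycle_fake") "confirmed"
                           else "pending_expert",
                  created = now, updated = now,
                  evidence = anomaly$evidence)
  } else {
    entry <- old
    if (old$status == "pending_expert") {
      entry$kind <- anomaly$kind
      entry$evidence <- anomaly$evidence
      entry$updated <- now
    }
  }
  kb$entries[[key]] <- entry
  list(kb = kb, entry = entry)
}

#' Look up an anomaly in the knowledge base
#'
#' Lookup is insensitive to cycle rotation and pair order, and matches any
#' kind of the same family (a pair saved as a false conflict is found when a
#' probable conflict is queried).
#'
#' @param kb an `sc_kb`.
#' @param kind anomaly kind.
#' @param members member statement ids.
#' @return the entry, or `NULL` when unseen.
#' @export
kb_is_known <- function(kb, kind, members) {
  kb$entries[[kb_key(kind, members)]]
}

#' Set an expert verdict on a knowledge-base entry
#'
#' @param kb an `sc_kb`.
#' @param key entry key (as listed by [kb_entries()]).
#' @param status `"pending_expert"`, `"confirmed"`, or `"false_positive"`.
#' @return list with the updated `kb` and `entry`.
#' @export
kb_set_status <- function(kb, key,
                          status = c("confirmed", "false_positive", "pending_expert")) {
  status <- match.arg(status)
  entry <- kb$entries[[key]]
  if (is.null(entry)) stop(sprintf("unknown knowledge-base key '%s'", key))
  entry$status <- status
  entry$updated <- kb_clock()
  if (status == "false_positive" && kind_family(entry$kind) == "conflict")
    entry$kind <- "conflict_false"
  kb$entries[[key]] <- entry
  list(kb = kb, entry = entry)
}

#' List knowledge-base entries
#'
#' @param kb an `sc_kb`.
#' @return a data.frame with key, kind, members, status and timestamps.
#' @export
kb_entries <- function(kb) {
  es <- kb$entries[order(names(kb$entries))]
  data.frame(
    key = vapply(es, `[[`, character(1), "key"),
    kind = vapply(es, `[[`, character(1), "kind"),
    members = vapply(es, function(e) paste(e$members, collapse = ","), character(1)),
    status = vapply(es, `[[`, character(1), "status"),
    created = vapply(es, `[[`, character(1), "created"),
    updated = vapply(es, `[[`, character(1), "updated"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Save the knowledge base as canonical JSON
#'
#' @param kb an `sc_kb`.
#' @param path target file; defaults to the path the kb was created with.
#' @return `path`, invisibly.
#' @export
save_kb <- function(kb, path = kb$path) {
  if (is.null(path)) stop("no path to save the knowledge base to")
  entries <- kb$entries[order(names(kb$entries))]
  obj <- list(schema_version = KB_SCHEMA_VERSION, entries = unname(entries))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a knowledge base from JSON
#'
#' @param path file written by [save_kb()].
#' @return an `sc_kb`.
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) stop("knowledge base file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != KB_SCHEMA_VERSION)
    stop("unsupported knowledge-base schema version")
  kb <- new_kb(path)
  for (e in obj$entries) {
    e$members <- unlist(e$members)
    kb$entries[[e$key]] <- e
  }
  kb
}

#' @export
print.sc_kb <- function(x, ...) {
  cat(sprintf("<anomalies knowledge base: %d entries>\n", length(x$entries)))
  if (length(x$entries)) print(kb_entries(x))
  invisible(x)
}
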