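# Full verification pipeline: redundancy first (equivalence, subsumption,
# transitivity), then cycles, conflicts, inaccessible statements and illegal
# values. The dependency graph and the statement groups are recomputed after
# every phase that deleted statements, so later phases always prune candidates
# against the current strategy.

#' Run the full anomaly-resolution pipeline
#'
#' Phases run in the order equivalence, subsumption, transitivity, cycles,
#' conflicts, inaccessible statements, illegal values; redundancy is removed
#' first so the later, more expensive phases see a smaller strategy. The
#' result collects every anomaly record per phase, the cleaned strategy, the
#' updated knowledge base, and the configuration snapshot. Re-running the
#' pipeline on its own output deletes nothing further.
#'
#' @param strategy an `sc_strategy`.
#' @param ont an `sc_ontology`.
#' @param kb an `sc_kb`, or `NULL` for a fresh in-memory one.
#' @param cfg an [sc_config()].
#' @return an `sc_report` with fields `input_ids`, `phases` (named list of
#'   record lists), `records` (flat), `strategy` (output), `deleted`, `kb`,
#'   `config`.
#' @export
run_pipeline <- function(strategy, ont, kb = NULL, cfg = sc_config()) {
  if (is.null(kb)) kb <- new_kb()
  input_ids <- strategy_ids(strategy)
  phases <- list()

  graph <- build_graph(strategy, ont, cfg)
  groups <- group_statements(graph)
  refresh <- function(changed) {
    if (changed) {
      graph <<- build_graph(strategy, ont, cfg)
      groups <<- group_statements(graph)
    }
  }

  step <- resolve_equivalence(strategy, groups, ont, cfg)
  phases$equivalence <- step$records
  strategy <- step$strategy
  refresh(length(step$records) > 0)

  step <- resolve_subsumption(strategy, groups, graph, ont, cfg)
  phases$subsumption <- step$records
  strategy <- step$strategy
  refresh(length(step$records) > 0)

  step <- resolve_transitivity(strategy, graph, groups, ont, cfg)
  phases$transitivity <- step$records
  strategy <- step$strategy
  refresh(length(step$records) > 0)

  step <- resolve_cycles(strategy, graph, ont, kb, cfg)
  phases$cycles <- step$records
  kb <- step$kb

  step <- detect_conflicts(strategy, groups, ont, kb, cfg)
  phases$conflicts <- step$records
  kb <- step$kb
  strategy <- step$strategy
  refresh(any(grepl("^deleted:", vapply(step$records, `[[`, character(1), "action"))))

  step <- detect_inaccessible(strategy, groups, graph, ont, cfg)
  phases$inaccessible <- step$records
  strategy <- step$strategy

  phases$illegal_values <- check_illegal_values(strategy, ont)

  records <- unlist(unname(phases), recursive = FALSE)
  deleted <- setdiff(input_ids, strategy_ids(strategy))
  structure(list(input_ids = input_ids, phases = phases, records = records,
                 strategy = strategy, deleted = deleted, kb = kb,
                 config = cfg),
            class = "sc_report")
}

#' @export
print.sc_report <- function(x, ...) {
  cat(sprintf("<verification report: %d -> %d statements, %d finding(s)>\n",
              length(x$input_ids), length(x$strategy$statements),
              length(x$records)))
  for (ph in names(x$phases)) {
    recs <- x$phases[[ph]]
    if (!length(recs)) next
    cat(sprintf("  %s:\n", ph))
    for (r in recs)
      cat(sprintf("    %s [%s] %s\n", r$kind,
                  paste(r$members, collapse = ","), r$action))
  }
  invisible(x)
}

#' Write a verification report as JSON
#'
#' The JSON mirrors the report structure: input/output statement ids, the
#' per-phase records (kind, members, action, case, evidence), the cleaned
#' strategy re-serialised in the rule dialect, and the configuration
#' snapshot. A `generated_at` header field carries the only timestamp.
#'
#' @param report an `sc_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  obj <- list(
    generated_at = kb_clock(),
    input_statements = report$input_ids,
    output_statements = strategy_ids(report$strategy),
    deleted = report$deleted,
    phases = lapply(report$phases, function(recs)
      lapply(recs, function(r)
        list(kind = r$kind, members = r$members, action = r$action,
             case = r$case, evidence = r$evidence))),
    cleaned_strategy = serialize_strategy(report$strategy),
    config = unclass(report$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
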