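# Cycle detection and real/fake classification. Every elementary directed
# cycle is enumerated exactly once (anchored DFS: a cycle is reported from its
# smallest node, visiting only nodes that sort after the anchor), then
# classified by forward chaining the cycle's statements over generated
# witnesses: reaching a fixpoint within the round bound means the loop in the
# graph does not loop on instances.

#' Enumerate elementary cycles of the dependency graph
#'
#' @param graph an `sc_depgraph`.
#' @return list of character vectors, each a cycle in canonical rotation
#'   (starting at its smallest statement id); empty for a DAG.
#' @export
detect_cycles <- function(graph) {
  nodes <- sort(graph$nodes)
  succs <- lapply(setNames(nodes, nodes), function(v) graph_succs(graph, v))
  cycles <- list()
  for (anchor in nodes) {
    path <- anchor
    on_path <- character()
    dfs <- function(v) {
      for (w in succs[[v]]) {
        if (w == anchor) {
          cycles[[length(cycles) + 1]] <<- path
        } else if (w > anchor && !w %in% path) {
          path <<- c(path, w)
          dfs(w)
          path <<- utils::head(path, -1)
        }
      }
    }
    dfs(anchor)
  }
  cycles
}

canonical_cycle <- function(cycle) {
  k <- which(cycle == min(cycle))[[1]]
  if (k == 1) cycle else c(cycle[k:length(cycle)], cycle[seq_len(k - 1)])
}

#' Classify a cycle as real or fake
#'
#' A cycle already recorded as fake in the anomalies knowledge base is
#' skipped. Otherwise the cycle's statements are instantiated on generated
#' witness objects (premise atoms grounded with variables shared by name,
#' numeric probes around every comparison threshold) and forward-chained in
#' isolation with a round budget of `2 * |cycle| + 2`: a loop that is real
#' keeps producing facts every lap, so reaching the fixpoint inside the
#' budget classifies the cycle as fake.
#'
#' @param cycle character vector of statement ids (a cycle in the graph).
#' @param strategy the `sc_strategy` containing them.
#' @param ont an `sc_ontology`.
#' @param kb an `sc_kb` or `NULL`.
#' @param cfg an [sc_config()].
#' @return `"fake"`, `"real"`, or `"skipped_known"`.
#' @export
classify_cycle <- function(cycle, strategy, ont, kb = NULL, cfg = sc_config()) {
  cycle <- canonical_cycle(cycle)
  if (!is.null(kb)) {
    known <- kb_is_known(kb, "cycle_fake", cycle)
    if (!is.null(known) && known$kind == "cycle_fake") return("skipped_known")
  }
  sts <- unname(strategy$statements[cycle])
  seed <- unlist(lapply(sts, `[[`, "premise"), recursive = FALSE)
  all_atoms <- unlist(lapply(sts, function(s) c(s$premise, s$conclusion)),
                      recursive = FALSE)
  store <- witness_store(seed, ont, threshold_atoms = all_atoms)
  run <- forward_chain(sts, store, ont, max_rounds = 2L * length(cycle) + 2L)
  if (run$reached_fixpoint) "fake" else "real"
}

# cycle phase of the pipeline: detect, classify, persist; cycles are never
# deleted automatically
resolve_cycles <- function(strategy, graph, ont, kb, cfg = sc_config()) {
  records <- list()
  for (cyc in detect_cycles(graph)) {
    cyc <- canonical_cycle(cyc)
    verdict <- classify_cycle(cyc, strategy, ont, kb, cfg)
    if (verdict == "skipped_known") {
      records[[length(records) + 1]] <- anomaly_record(
        "cycle_fake", cyc, "skipped_known",
        "cycle previously classified fake in the anomalies knowledge base")
      next
    }
    kind <- if (verdict == "fake") "cycle_fake" else "cycle_real"
    ev <- if (verdict == "fake")
      "forward chaining on witnesses reached a fixpoint inside the round budget"
    else "round budget exhausted without fixpoint; the loop produces facts on instances"
    rec <- anomaly_record(kind, cyc, "saved_for_expert", ev)
    records[[length(records) + 1]] <- rec
    if (!is.null(kb)) kb <- kb_record(kb, rec)$kb
  }
  list(records = records, kb = kb)
}
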