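#' Verification configuration
#'
#' Bundles the tunable parameters of relation extraction and anomaly
#' resolution. Defaults follow the published calibration where one exists
#' (technique coefficients `c_cp = 0.5`, `c_cc = 1`; only `weight(equal) = 1`
#' and `weight(none) = 0` are fixed externally, the intermediate weights are
#' this package's strictly-ordered choice).
#'
#' @param c_cp coefficient applied to conclusion-premise confidences.
#' @param c_cc coefficient applied to conclusion-conclusion confidences.
#' @param weights named weight table over entity relations, values in
#'   \[0, 1\] with `equal = 1` and `none = 0`.
#' @param threshold minimum filtered product for an edge to survive
#'   (default 0: any strictly positive product is kept).
#' @param chain_bound maximum chain length considered during transitivity
#'   detection (printed worked cases use length 2; enumeration is exponential
#'   in this bound).
#' @param strong_conflict_policy `"delete_added"` (default; delete the
#'   provenance-tagged added statement, or the later-declared one when both
#'   carry the same tag), `"delete_later"`, or `"delete_none"` (flag only).
#' @param strict_boundary treat `GE(t)` vs `LE(t)` on one quantity as
#'   contradictory even though the satisfying sets share the boundary point
#'   (the conflict reading of complementary inclusive comparisons); set
#'   `FALSE` for pure interval-intersection semantics.
#' @param normalize_integer_builtins treat `GT(n)` as `GE(n+1)` (and `LT` as
#'   `LE`) on integer thresholds during correspondence, so statements that
#'   differ only in that spelling are detected as redundant. Off by default.
#' @param exhaustive_inaccessible scan every statement for unsatisfiable
#'   literals instead of only the groups with empty incoming or outgoing arcs.
#' @return an `sc_config` list.
#' @export
sc_config <- function(c_cp = 0.5, c_cc = 1.0,
                      weights = c(equal = 1, equivalent = 0.9,
                                  ancestor = 0.7, descendant = 0.7,
                                  disjoint = 0, none = 0),
                      threshold = 0,
                      chain_bound = 4L,
                      strong_conflict_policy = c("delete_added", "delete_later",
                                                 "delete_none"),
                      strict_boundary = TRUE,
                      normalize_integer_builtins = FALSE,
                      exhaustive_inaccessible = FALSE) {
  strong_conflict_policy <- match.arg(strong_conflict_policy)
  stopifnot(c_cp > 0, c_cp <= 1, c_cc > 0, c_cc <= 1,
            weights[["equal"]] == 1, weights[["none"]] == 0,
            all(weights >= 0 & weights <= 1),
            chain_bound >= 2)
  structure(list(c_cp = c_cp, c_cc = c_cc, weights = weights,
                 threshold = threshold, chain_bound = as.integer(chain_bound),
                 strong_conflict_policy = strong_conflict_policy,
                 strict_boundary = strict_boundary,
                 normalize_integer_builtins = normalize_integer_builtins,
                 exhaustive_inaccessible = exhaustive_inaccessible),
            class = "sc_config")
}

relation_weight <- function(rel, cfg) {
  w <- cfg$weights
  switch(rel,
         equal = w[["equal"]],
         equivalent = w[["equivalent"]],
         ancestor = w[["ancestor"]],
         descendant = w[["descendant"]],
         disjoint = w[["disjoint"]],
         none = w[["none"]],
         0)
}
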