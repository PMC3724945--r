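# Steady-configuration search and edge-addition repair.
#
# A configuration is steady when its self-transition probability is
# positive: every deterministic module must reproduce its current value and
# every tied module contributes a factor p_i (stay high) or 1 - p_i (stay
# low). A steady configuration is absorbing when no module ties, i.e. the
# self-probability is exactly one.
#
# For majority-rule networks the search factors through the deterministic
# (odd in-degree) modules: their joint steadiness constraints discard most
# assignments before the probabilistic nodes are considered.

steady_row <- function(net, values) {
  n <- length(net$nodes)
  keep_rule <- net$rule %in% c("IMR", "INMR")
  factors <- frac(1)
  tied <- character(0)
  expr <- character(0)
  for (i in seq_len(n)) {
    nd <- net$nodes[[i]]
    if (nd %in% names(net$clamped)) {
      if (values[i] != net$clamped[[nd]]) return(NULL)
      next
    }
    u <- contribution_sum(net, nd, values)
    cur_high <- values[i] > 0
    if (u > 0L) { if (!cur_high) return(NULL); next }
    if (u < 0L) { if (cur_high) return(NULL); next }
    # tie
    p <- frac_idx(net$tie_prob, i)
    stay <- if (keep_rule) p else if (cur_high) p else frac_one_minus(p)
    if (frac_num(stay) == 0) return(NULL)
    factors <- frac_mul(factors, stay)
    tied <- c(tied, nd)
    expr <- c(expr, if (keep_rule || cur_high) paste0("p[", nd, "]")
              else paste0("(1-p[", nd, "])"))
  }
  list(prob = factors, tied = tied,
       expr = if (length(expr) == 0L) "1" else paste(expr, collapse = "*"))
}

#' Enumerate all steady configurations of a network
#'
#' Scans the diagonal of the transition matrix over all `2^n` configurations
#' (clamped nodes are held at their clamp; configurations violating a clamp
#' have self-transition probability zero and are excluded) and reports every
#' configuration with positive self-transition probability, together with
#' the exact probability expression as a product of tie factors.
#'
#' @param net A [grn] with at most 20 nodes.
#' @return A tibble with columns `configuration` (string in node order),
#'   `self_prob`, `self_prob_expr`, `tied_nodes` (list column) and
#'   `absorbing` (`TRUE` when the self-probability is one).
#' @examples
#' steady_configurations(yeast_network("mr_pruned", clamp_input = "off"))
#' @export
steady_configurations <- function(net) {
  stopifnot(inherits(net, "grn"))
  n <- length(net$nodes)
  if (n > 20L) {
    stop("brute-force bound exceeded (n > 20); use the staged search ",
         "(deterministic_core_candidates + extend_core)", call. = FALSE)
  }
  rep <- grn_representation(net)
  free <- setdiff(net$nodes, names(net$clamped))
  m <- length(free)
  free_pos <- match(free, net$nodes)
  base <- integer(n)
  if (length(net$clamped) > 0L) {
    base[match(names(net$clamped), net$nodes)] <- net$clamped
  }
  rows <- list()
  for (ix in 0:(2^m - 1L)) {
    values <- base
    if (m > 0L) {
      bits <- as.integer(bitwAnd(ix %/% 2^((m - 1L):0), 1L))
      values[free_pos] <- bits_to_values(bits, rep)
    }
    res <- steady_row(net, values)
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      configuration = format_configuration(values, rep),
      self_prob = frac_num(res$prob),
      self_prob_exact = frac_format(res$prob),
      self_prob_expr = res$expr,
      tied_nodes = list(res$tied),
      absorbing = length(res$tied) == 0L
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(configuration = character(), self_prob = numeric(),
                          self_prob_exact = character(),
                          self_prob_expr = character(),
                          tied_nodes = list(), absorbing = logical()))
  }
  dplyr::bind_rows(rows)
}

deterministic_nodes <- function(net) {
  cls <- node_is_probabilistic(net)
  cls$node[!cls$probabilistic & !cls$clamped]
}

# does every deterministic module reproduce its value in `values`?
core_violations <- function(net, core, values) {
  bad <- character(0)
  for (nd in core) {
    u <- contribution_sum(net, nd, values)
    i <- match(nd, net$nodes)
    if ((u > 0L && values[i] < 1L) || (u < 0L && values[i] > 0L) || u == 0L) {
      bad <- c(bad, nd)
    }
  }
  bad
}

#' Candidate assignments of the deterministic modules
#'
#' Enumerates all assignments of the deterministic (odd in-degree,
#' unclamped) nodes under MR/IMR. A candidate is satisfiable when some
#' assignment of the remaining nodes makes every deterministic module
#' reproduce its value (exhaustive search over the remaining nodes).
#' Discarded candidates report the modules that fail for every completion.
#'
#' @param net A [grn] with rule MR or IMR.
#' @return A tibble with columns `candidate` (string over the deterministic
#'   nodes, in node order), `core_nodes` (list), `satisfiable`,
#'   `n_witnesses`, and `violated` (list of modules never steady).
#' @export
deterministic_core_candidates <- function(net) {
  stopifnot(inherits(net, "grn"))
  if (!net$rule %in% c("MR", "IMR")) {
    stop("the deterministic/probabilistic split requires rule MR or IMR",
         call. = FALSE)
  }
  core <- deterministic_nodes(net)
  rep <- grn_representation(net)
  others <- setdiff(net$nodes, core)
  others_free <- setdiff(others, names(net$clamped))
  n <- length(net$nodes)
  base <- integer(n)
  if (length(net$clamped) > 0L) {
    base[match(names(net$clamped), net$nodes)] <- net$clamped
  }
  core_pos <- match(core, net$nodes)
  oth_pos <- match(others_free, net$nodes)
  k <- length(core); m <- length(others_free)
  if (k == 0L) {
    return(tibble::tibble(candidate = "", core_nodes = list(character(0)),
                          satisfiable = TRUE, n_witnesses = 1L,
                          violated = list(character(0))))
  }
  rows <- list()
  for (ci in 0:(2^k - 1L)) {
    cbits <- as.integer(bitwAnd(ci %/% 2^((k - 1L):0), 1L))
    nw <- 0L
    violated <- NULL
    for (oi in 0:(2^m - 1L)) {
      values <- base
      values[core_pos] <- bits_to_values(cbits, rep)
      if (m > 0L) {
        obits <- as.integer(bitwAnd(oi %/% 2^((m - 1L):0), 1L))
        values[oth_pos] <- bits_to_values(obits, rep)
      }
      bad <- core_violations(net, core, values)
      if (length(bad) == 0L) {
        nw <- nw + 1L
      }
      violated <- if (is.null(violated)) bad else intersect(violated, bad)
      if (m == 0L) break
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      candidate = format_configuration(bits_to_values(cbits, rep), rep),
      core_nodes = list(core),
      satisfiable = nw > 0L,
      n_witnesses = nw,
      violated = list(if (nw > 0L) character(0) else violated)
    )
  }
  dplyr::bind_rows(rows)
}

#' Steady extensions of a deterministic-core candidate
#'
#' Extends an assignment of the deterministic nodes to full steady
#' configurations. Values of the remaining nodes are first forced by
#' constraint propagation (a module whose known inputs already decide its
#' outcome pins its node); the residual free nodes are closed by exhaustive
#' search. The result equals the restriction of [steady_configurations()]
#' to the candidate (cross-checked in the package tests).
#'
#' @param net A [grn] with rule MR or IMR.
#' @param candidate A candidate string as returned by
#'   [deterministic_core_candidates()] (assignment of the deterministic
#'   nodes in node order).
#' @return A tibble in the format of [steady_configurations()]; zero rows
#'   when the candidate has no steady extension.
#' @export
extend_core <- function(net, candidate) {
  stopifnot(inherits(net, "grn"))
  core <- deterministic_nodes(net)
  rep <- grn_representation(net)
  cvals <- parse_configuration(candidate, rep)
  stopifnot(length(cvals) == length(core))
  assigned <- stats::setNames(rep(NA_integer_, length(net$nodes)), net$nodes)
  assigned[core] <- cvals
  for (nd in names(net$clamped)) assigned[nd] <- net$clamped[[nd]]

  adj <- signed_adjacency(net)
  low <- if (rep == "spin") -1L else 0L
  # propagate: a node is pinned when its module's outcome is decided by the
  # already-known inputs regardless of the unknown ones
  repeat {
    changed <- FALSE
    for (i in seq_along(net$nodes)) {
      nd <- net$nodes[[i]]
      if (!is.na(assigned[i]) || nd %in% core) next
      inc <- which(adj[, i] != 0L)
      known <- inc[!is.na(assigned[inc])]
      unknown <- inc[is.na(assigned[inc])]
      u_known <- sum(adj[known, i] * assigned[known])
      slack <- if (rep == "spin") length(unknown) else
        sum(abs(adj[unknown, i])) # boolean values are 0/1
      if (abs(u_known) > slack) {
        forced <- if (u_known > 0L) 1L else low
        assigned[i] <- forced
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  free <- net$nodes[is.na(assigned)]
  m <- length(free)
  rows <- list()
  for (oi in 0:(2^m - 1L)) {
    values <- assigned
    if (m > 0L) {
      obits <- as.integer(bitwAnd(oi %/% 2^((m - 1L):0), 1L))
      values[match(free, net$nodes)] <- bits_to_values(obits, rep)
    }
    res <- steady_row(net, unname(values))
    if (is.null(res)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      configuration = format_configuration(values, rep),
      self_prob = frac_num(res$prob),
      self_prob_exact = frac_format(res$prob),
      self_prob_expr = res$expr,
      tied_nodes = list(res$tied),
      absorbing = length(res$tied) == 0L
    )
    if (m == 0L) break
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(configuration = character(), self_prob = numeric(),
                          self_prob_exact = character(),
                          self_prob_expr = character(),
                          tied_nodes = list(), absorbing = logical()))
  }
  dplyr::bind_rows(rows)
}

#' Suggest single-edge additions that stabilise a target configuration
#'
#' For each node tied at the target configuration, lists every single added
#' edge that turns the module's zero contribution sum into a nonzero sum of
#' the correct sign: a positive edge from a node whose value pushes toward
#' the target value, or a negative edge from a node with the opposite value.
#' Existing (source, target) pairs are excluded. Suggestions are ranked per
#' tied node by source name and sign.
#'
#' @param net A [grn].
#' @param target Target configuration (vector in the rule's representation
#'   or a configuration string).
#' @return A tibble with columns `fixes` (the tied node), `source`, `sign`
#'   and `rationale`.
#' @export
suggest_stabilizing_edges <- function(net, target) {
  stopifnot(inherits(net, "grn"))
  rep <- grn_representation(net)
  if (is.character(target) && length(target) == 1L) {
    target <- parse_configuration(target, rep)
  }
  res <- steady_row(net, target)
  if (is.null(res)) {
    core <- deterministic_nodes(net)
    bad <- core_violations(net, core, target)
    stop("target is not steady; violating deterministic modules: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(res$tied) == 0L) {
    return(tibble::tibble(fixes = character(), source = character(),
                          sign = integer(), rationale = character()))
  }
  rows <- list()
  for (nd in res$tied) {
    i <- match(nd, net$nodes)
    want_high <- target[i] > 0
    for (src in net$nodes) {
      exists <- any(net$edges$source == src & net$edges$target == nd)
      if (exists) next
      j <- match(src, net$nodes)
      src_high <- target[j] > 0
      # contribution of the new edge at the target configuration must match
      # the node's target value
      sgn <- if (rep == "spin") {
        if (src_high == want_high) 1L else -1L
      } else {
        # boolean: an OFF source contributes nothing, so only ON sources help
        if (!src_high) next
        if (want_high) 1L else -1L
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fixes = nd, source = src, sign = sgn,
        rationale = sprintf("%s edge from %s (value %s at target) makes %s deterministic",
                            if (sgn > 0L) "positive" else "negative", src,
                            if (src_high) "high" else "low", nd)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$fixes, out$source, out$sign), ]
}

#' Apply edge additions and removals to a network
#'
#' @param net A [grn].
#' @param add Data frame of edges to add (`source`, `target`, `sign`,
#'   optional `tag`), or `NULL`.
#' @param remove Data frame of edges to remove (`source`, `target`), or
#'   `NULL`; removing a non-existent edge is an error.
#' @return A new [grn] with the same nodes, rule, tie probabilities and
#'   clamps.
#' @export
apply_edits <- function(net, add = NULL, remove = NULL) {
  stopifnot(inherits(net, "grn"))
  edges <- net$edges
  if (!is.null(remove) && nrow(as.data.frame(remove)) > 0L) {
    remove <- as.data.frame(remove)
    for (r in seq_len(nrow(remove))) {
      hit <- which(edges$source == remove$source[[r]] &
                     edges$target == remove$target[[r]])
      if (length(hit) == 0L) {
        stop("cannot remove non-existent edge ", remove$source[[r]], " -> ",
             remove$target[[r]], call. = FALSE)
      }
      edges <- edges[-hit, ]
    }
  }
  if (!is.null(add) && nrow(as.data.frame(add)) > 0L) {
    edges <- dplyr::bind_rows(edges, normalize_edges(add))
  }
  grn(edges, nodes = net$nodes, rule = net$rule,
      tie_prob = stats::setNames(frac_format(net$tie_prob), net$nodes),
      clamped = if (length(net$clamped) > 0L) net$clamped else NULL)
}
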