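# Update-rule semantics: contribution sums and per-node next-value
# distributions for the four majority-rule variants.
#
# MR   (spin):    U_i = sum over incoming edges of sign * s_source;
#                 U > 0 -> +1, U < 0 -> -1, U = 0 -> +1 with probability p_i.
# IMR  (spin):    tie resolved toward the current value: keep s_i with
#                 probability p_i (p_i = 1 recovers the deterministic
#                 inertial rule).
# NMR  (Boolean): U_i = sum of sign * S_source with S in {0,1}; an absent
#                 regulator contributes nothing; tie -> 1 with probability p_i.
# INMR (Boolean): as NMR but the tie keeps the current value with
#                 probability p_i.
#
# A clamped node ignores its regulators and moves to its clamp value with
# probability one.

#' Signed contribution sum feeding a node's update
#'
#' @param net A [grn].
#' @param node Node identifier.
#' @param values Configuration in the rule's representation (spin for
#'   MR/IMR, Boolean for NMR/INMR), in node order.
#' @return Integer sum; an empty regulator set gives 0 (a perpetual tie
#'   under MR/NMR).
#' @export
contribution_sum <- function(net, node, values) {
  stopifnot(inherits(net, "grn"))
  if (!node %in% net$nodes) stop("unknown node: ", node, call. = FALSE)
  check_representation(net, values)
  incoming <- net$edges[net$edges$target == node, ]
  if (nrow(incoming) == 0L) return(0L)
  src <- match(incoming$source, net$nodes)
  as.integer(sum(incoming$sign * values[src]))
}

check_representation <- function(net, values) {
  if (length(values) != length(net$nodes)) {
    stop("configuration length does not match node count", call. = FALSE)
  }
  rep <- grn_representation(net)
  ok <- if (rep == "spin") all(values %in% c(-1L, 1L)) else all(values %in% c(0L, 1L))
  if (!ok) {
    stop("configuration values do not match the ", rep,
         " representation of rule ", net$rule, call. = FALSE)
  }
  invisible(rep)
}

# per-node probability that the next value is high, as an exact fraction
node_prob_high <- function(net, node, values) {
  i <- match(node, net$nodes)
  if (node %in% names(net$clamped)) {
    return(frac(as.double(net$clamped[[node]] > 0)))
  }
  u <- contribution_sum(net, node, values)
  if (u > 0L) return(frac(1))
  if (u < 0L) return(frac(0))
  p <- frac_idx(net$tie_prob, i)
  if (net$rule %in% c("IMR", "INMR")) {
    # keep current value with probability p
    if (values[i] > 0) p else frac_one_minus(p)
  } else {
    p
  }
}

#' Next-value distribution of every node for a configuration
#'
#' Applies the network's update rule synchronously and reports, for each
#' node, the probability that its next value is high (+1 in spin form, 1 in
#' Boolean form). Deterministic updates give probability 0 or 1; ties give
#' the node's tie probability (MR/NMR) or the keep-current probability
#' (IMR/INMR). Clamped nodes move to their clamp with probability one.
#'
#' @inheritParams contribution_sum
#' @param values Configuration vector in the rule's representation.
#' @return A tibble with columns `node`, `contribution`, `prob_high`
#'   (numeric) and `prob_high_exact` (fraction string).
#' @export
next_value_distribution <- function(net, values) {
  stopifnot(inherits(net, "grn"))
  check_representation(net, values)
  ph <- lapply(net$nodes, function(nd) node_prob_high(net, nd, values))
  ph <- do.call(frac_c, ph)
  tibble::tibble(
    node = net$nodes,
    contribution = vapply(net$nodes, function(nd) {
      if (nd %in% names(net$clamped)) NA_integer_
      else contribution_sum(net, nd, values)
    }, 0L),
    prob_high = frac_num(ph),
    prob_high_exact = frac_format(ph)
  )
}

#' Deterministic successor map at an extreme tie corner
#'
#' Fixing every probabilistic node's tie outcome to an extreme (tie
#' probability 0 or 1) makes the whole system deterministic; the result is
#' the successor function on the configuration space. For IMR/INMR corners,
#' outcome 1 means "keep the current value".
#'
#' @param net A [grn].
#' @param corner Tie outcome per node: a single 0/1 recycled to all nodes or
#'   a named vector. Nodes that never tie ignore their entry.
#' @return An integer vector `succ` of length `2^n` with 0-based state
#'   indices: state `i` (0-based) moves to `succ[i + 1]`.
#' @export
extreme_deterministic_map <- function(net, corner = 1L) {
  stopifnot(inherits(net, "grn"))
  n <- length(net$nodes)
  if (length(corner) == 1L && is.null(names(corner))) {
    corner <- stats::setNames(rep(as.integer(corner), n), net$nodes)
  }
  rep <- grn_representation(net)
  vapply(0:(2^n - 1L), function(ix) {
    values <- index_to_state(ix, n, rep)
    nxt <- vapply(seq_len(n), function(i) {
      nd <- net$nodes[[i]]
      ph <- frac_num(node_prob_high(net, nd, values))
      bit <- if (ph == 1) 1L else if (ph == 0) 0L else {
        keep <- net$rule %in% c("IMR", "INMR")
        out <- as.integer(corner[[nd]])
        if (keep) {
          if (out == 1L) config_bits(values[i]) else 1L - config_bits(values[i])
        } else out
      }
      bit
    }, 0L)
    as.integer(sum(nxt * 2^(n - seq_len(n))))
  }, 0L)
}
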