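# The budding-yeast cell-cycle network (Li et al. wiring).
#
# Eleven regulators of cell-cycle progression. Cln3 is the input (the start
# signal). The original model adds "self-degradation" negative self-loops to
# the five nodes that have no other negative regulator (Cln3, Cln1/2, Swi5,
# Cdc20, Mcm1/SFF); under the stochastic majority rule those loops can be
# discarded. The revised variant adds the two positive feedback edges
# Cln1/2 -> SBF and Clb5/6 -> MBF, which make the G1 state absorbing once
# the input is clamped OFF.

yeast_nodes <- c("Cln3", "MBF", "SBF", "Cln1_2", "Cdh1", "Swi5", "Cdc20",
                 "Clb5_6", "Sic1", "Clb1_2", "Mcm1_SFF")

yeast_core_edges <- function() {
  act <- matrix(c(
    "Cln3",     "MBF",
    "Cln3",     "SBF",
    "SBF",      "Cln1_2",
    "MBF",      "Clb5_6",
    "Clb5_6",   "Mcm1_SFF",
    "Clb5_6",   "Clb1_2",
    "Clb1_2",   "Mcm1_SFF",
    "Clb1_2",   "Cdc20",
    "Mcm1_SFF", "Clb1_2",
    "Mcm1_SFF", "Cdc20",
    "Mcm1_SFF", "Swi5",
    "Cdc20",    "Swi5",
    "Cdc20",    "Sic1",
    "Cdc20",    "Cdh1",
    "Swi5",     "Sic1"
  ), ncol = 2L, byrow = TRUE)
  inh <- matrix(c(
    "Cln1_2", "Sic1",
    "Cln1_2", "Cdh1",
    "Clb5_6", "Sic1",
    "Clb5_6", "Cdh1",
    "Clb1_2", "Sic1",
    "Clb1_2", "Cdh1",
    "Clb1_2", "Swi5",
    "Clb1_2", "MBF",
    "Clb1_2", "SBF",
    "Sic1",   "Clb5_6",
    "Sic1",   "Clb1_2",
    "Cdh1",   "Clb1_2",
    "Cdc20",  "Clb5_6",
    "Cdc20",  "Clb1_2"
  ), ncol = 2L, byrow = TRUE)
  tibble::tibble(
    source = c(act[, 1L], inh[, 1L]),
    target = c(act[, 2L], inh[, 2L]),
    sign = c(rep(1L, nrow(act)), rep(-1L, nrow(inh))),
    tag = NA_character_
  )
}

yeast_selfloop_nodes <- c("Cln3", "Cln1_2", "Swi5", "Cdc20", "Mcm1_SFF")

#' The budding-yeast cell-cycle network
#'
#' Returns the 11-node cell-cycle network in one of three variants:
#' `"original_with_selfloops"` keeps the five self-degradation loops of the
#' original model, `"mr_pruned"` (the default for majority-rule analyses)
#' discards them, and `"revised"` additionally carries the two positive
#' edges Cln1/2 -> SBF and Clb5/6 -> MBF (tagged `"revision"`).
#'
#' @param variant Network variant.
#' @param rule Update rule (default `"MR"`).
#' @param tie_prob Tie probability (single value or named; default `"1/2"`).
#' @param clamp_input Optional value for the Cln3 input clamp: `NULL` (free),
#'   `"off"` or `"on"`.
#' @return A [grn] over nodes Cln3, MBF, SBF, Cln1_2, Cdh1, Swi5, Cdc20,
#'   Clb5_6, Sic1, Clb1_2, Mcm1_SFF (slash replaced by underscore).
#' @examples
#' net <- yeast_network("mr_pruned")
#' node_is_probabilistic(net)
#' @export
yeast_network <- function(variant = c("mr_pruned", "original_with_selfloops", "revised"),
                          rule = "MR", tie_prob = "1/2", clamp_input = NULL) {
  variant <- match.arg(variant)
  edges <- yeast_core_edges()
  if (variant == "original_with_selfloops") {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      source = yeast_selfloop_nodes, target = yeast_selfloop_nodes,
      sign = -1L, tag = "self_degradation"))
  }
  if (variant == "revised") {
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      source = c("Cln1_2", "Clb5_6"), target = c("SBF", "MBF"),
      sign = 1L, tag = "revision"))
  }
  clamped <- NULL
  if (!is.null(clamp_input)) {
    spin <- rule %in% c("MR", "IMR")
    v <- switch(as.character(clamp_input),
                off = if (spin) -1L else 0L,
                on = 1L,
                as.integer(clamp_input))
    clamped <- stats::setNames(v, "Cln3")
  }
  grn(edges, nodes = yeast_nodes, rule = rule, tie_prob = tie_prob,
      clamped = clamped)
}

#' The G1 configuration of the yeast cell-cycle model
#'
#' The biological resting state: only Cdh1 and Sic1 are ON.
#'
#' @param representation `"spin"` or `"boolean"`.
#' @return Named configuration vector in yeast node order.
#' @export
yeast_g1 <- function(representation = c("spin", "boolean")) {
  representation <- match.arg(representation)
  on <- yeast_nodes %in% c("Cdh1", "Sic1")
  stats::setNames(bits_to_values(as.integer(on), representation), yeast_nodes)
}
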