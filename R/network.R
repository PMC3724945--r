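#' Construct a signed regulatory network
#'
#' A regulatory network is a signed directed graph together with an update
#' rule, one tie probability per node, and optional input clamps. Nodes are
#' ordered; the order is part of the object because configuration indexing
#' depends on it.
#'
#' @param edges A data frame with columns `source`, `target` and `sign`
#'   (`+1`/`-1`, or the tokens `"+"`, `"-"`, `"activate"`, `"inhibit"`), and
#'   optionally `tag` (free label, e.g. to mark self-degradation loops). An
#'   empty or `NULL` edge table yields a network with no interactions.
#' @param nodes Character vector fixing node identity and order. Defaults to
#'   the order of first appearance in `edges`.
#' @param rule Update rule: `"MR"` (majority, spin values -1/+1), `"IMR"`
#'   (inertial majority, spin), `"NMR"` (null majority, Boolean 0/1) or
#'   `"INMR"` (inertial null majority, Boolean).
#' @param tie_prob Tie-breaking probability per node: a single value recycled
#'   to all nodes or a named vector/list. Values may be numerics or exact
#'   fraction strings such as `"1/3"`; fractions keep all chain analytics
#'   exact. Default `"1/2"`.
#' @param clamped Named vector of input clamps, e.g. `c(Cln3 = -1)`. A clamped
#'   node ignores its regulators and never ties. Values are given in the
#'   rule's representation (spin for MR/IMR, Boolean for NMR/INMR); `0` is
#'   accepted as "low" for spin rules.
#'
#' @return An object of class `grn`.
#' @examples
#' net <- grn(tibble::tibble(source = c("A", "B"), target = c("B", "A"),
#'                           sign = c(1, -1)))
#' net
#' @export
grn <- function(edges = NULL, nodes = NULL, rule = c("MR", "IMR", "NMR", "INMR"),
                tie_prob = "1/2", clamped = NULL) {
  rule <- match.arg(rule)
  edges <- normalize_edges(edges)
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$source, edges$target)))
    if (length(nodes) == 0L) {
      stop("`nodes` must be given when `edges` is empty", call. = FALSE)
    }
  }
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  unknown <- setdiff(unique(c(edges$source, edges$target)), nodes)
  if (length(unknown) > 0L) {
    stop("edge endpoints not in node list: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(edges[c("source", "target")])) {
    stop("duplicate (source, target) pair in edge list", call. = FALSE)
  }

  tp <- resolve_tie_prob(tie_prob, nodes)
  bad <- frac_num(tp) < 0 | frac_num(tp) > 1
  if (any(bad)) {
    stop("tie probabilities must lie in [0, 1]", call. = FALSE)
  }

  clamped <- normalize_clamped(clamped, nodes, rule)

  structure(
    list(nodes = nodes, edges = edges, rule = rule,
         tie_prob = tp, clamped = clamped),
    class = "grn"
  )
}

normalize_edges <- function(edges) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    return(tibble::tibble(source = character(), target = character(),
                          sign = integer(), tag = character()))
  }
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("source", "target", "sign") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- parse_sign(edges$sign)
  if (!"tag" %in% names(edges)) edges$tag <- NA_character_
  edges[c("source", "target", "sign", "tag")]
}

parse_sign <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(-1, 1))) stop("edge sign must be +1 or -1", call. = FALSE)
    return(as.integer(x))
  }
  x <- trimws(as.character(x))
  out <- ifelse(x %in% c("+", "+1", "1", "activate", "activation"), 1L,
                ifelse(x %in% c("-", "-1", "inhibit", "inhibition", "repress"),
                       -1L, NA_integer_))
  if (anyNA(out)) {
    stop("unknown sign token: ", paste(unique(x[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

resolve_tie_prob <- function(tie_prob, nodes) {
  if (is.list(tie_prob)) tie_prob <- unlist(tie_prob)
  if (length(tie_prob) == 1L && is.null(names(tie_prob))) {
    tie_prob <- stats::setNames(rep(tie_prob, length(nodes)), nodes)
  }
  if (is.null(names(tie_prob)) && length(tie_prob) == length(nodes)) {
    names(tie_prob) <- nodes
  }
  missing <- setdiff(nodes, names(tie_prob))
  full <- character(length(nodes))
  names(full) <- nodes
  if (length(missing) > 0L) {
    # unnamed default for unlisted nodes
    full[missing] <- "1/2"
  }
  full[intersect(nodes, names(tie_prob))] <-
    as.character(tie_prob[intersect(nodes, names(tie_prob))])
  frac_parse(stats::setNames(full[nodes], nodes))
}

normalize_clamped <- function(clamped, nodes, rule) {
  if (is.null(clamped) || length(clamped) == 0L) {
    return(stats::setNames(integer(), character()))
  }
  clamped <- unlist(clamped)
  if (is.null(names(clamped)) || any(!names(clamped) %in% nodes)) {
    stop("`clamped` must be a named vector over declared nodes", call. = FALSE)
  }
  v <- as.integer(clamped)
  if (rule %in% c("MR", "IMR")) {
    v[v == 0L] <- -1L
    if (!all(v %in% c(-1L, 1L))) stop("spin clamp values must be -1/+1", call. = FALSE)
  } else {
    v[v == -1L] <- 0L
    if (!all(v %in% c(0L, 1L))) stop("Boolean clamp values must be 0/1", call. = FALSE)
  }
  stats::setNames(v, names(clamped))
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("<grn> %d nodes, %d edges, rule %s (%s representation)\n",
              length(x$nodes), nrow(x$edges), x$rule,
              if (x$rule %in% c("MR", "IMR")) "spin" else "Boolean"))
  cat("nodes:", paste(x$nodes, collapse = ", "), "\n")
  if (length(x$clamped) > 0L) {
    cat("clamped:", paste(names(x$clamped), "=", x$clamped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
format.grn <- function(x, ...) {
  sprintf("<grn: %d nodes, %d edges, %s>", length(x$nodes), nrow(x$edges), x$rule)
}

grn_representation <- function(net) {
  if (net$rule %in% c("MR", "IMR")) "spin" else "boolean"
}

#' In-degrees and determinism classification of every node
#'
#' Under MR/IMR a node's update is deterministic for every configuration
#' exactly when its in-degree (self-loops included) is odd; under NMR/INMR
#' every unclamped node ties in some configuration. Clamped nodes are always
#' deterministic.
#'
#' @param net A [grn].
#' @return A tibble with one row per node: `node`, `in_degree`,
#'   `probabilistic`, `clamped`.
#' @export
node_is_probabilistic <- function(net) {
  stopifnot(inherits(net, "grn"))
  indeg <- table(factor(net$edges$target, levels = net$nodes))
  clamped <- net$nodes %in% names(net$clamped)
  prob <- if (net$rule %in% c("MR", "IMR")) {
    as.integer(indeg) %% 2L == 0L
  } else {
    rep(TRUE, length(net$nodes))
  }
  prob[clamped] <- FALSE
  tibble::tibble(node = net$nodes, in_degree = as.integer(indeg),
                 probabilistic = prob, clamped = clamped)
}

# ---- file I/O ---------------------------------------------------------------

#' Read a regulatory network from a TSV edge list or JSON model file
#'
#' TSV files carry `source<TAB>target<TAB>sign` lines (sign tokens `+`, `-`,
#' `+1`, `-1`; `#` starts a comment); node order is order of first appearance.
#' JSON model files carry
#' `{"nodes": [...], "edges": [[src, tgt, sign], ...], "rule": "MR",
#' "tie_prob": {...}, "clamped": {...}}`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @param ... Passed to [grn()] (e.g. `rule`, `tie_prob`) for TSV input.
#' @return A [grn].
#' @export
read_grn <- function(path, format = c("auto", "tsv", "json"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "tsv") {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L)) {
      stop("malformed TSV edge line (need source<TAB>target<TAB>sign)", call. = FALSE)
    }
    edges <- tibble::tibble(
      source = vapply(parts, `[[`, "", 1L),
      target = vapply(parts, `[[`, "", 2L),
      sign = vapply(parts, `[[`, "", 3L),
      tag = vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else NA_character_, "")
    )
    return(grn(edges, ...))
  }
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  edges <- NULL
  if (!is.null(spec$edges) && length(spec$edges) > 0L) {
    em <- spec$edges
    if (is.list(em) && !is.data.frame(em)) em <- do.call(rbind, em)
    em <- as.data.frame(em, stringsAsFactors = FALSE)
    names(em) <- c("source", "target", "sign")[seq_len(ncol(em))]
    edges <- em
  }
  grn(edges,
      nodes = spec$nodes,
      rule = if (is.null(spec$rule)) "MR" else spec$rule,
      tie_prob = if (is.null(spec$tie_prob)) "1/2" else unlist(spec$tie_prob),
      clamped = if (is.null(spec$clamped)) NULL else unlist(spec$clamped))
}

#' Write a regulatory network to disk
#'
#' @param net A [grn].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"tsv"` (edge list only) or
#'   `"json"` (full model: rule, tie probabilities, clamps).
#' @return `path`, invisibly.
#' @export
write_grn <- function(net, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(net, "grn"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "tsv") {
    sign <- ifelse(net$edges$sign > 0, "+", "-")
    tag <- ifelse(is.na(net$edges$tag), "", paste0("\t", net$edges$tag))
    writeLines(c("# source\ttarget\tsign",
                 paste0(net$edges$source, "\t", net$edges$target, "\t", sign, tag)),
               path)
  } else {
    spec <- list(
      nodes = net$nodes,
      edges = unname(apply(net$edges, 1L, function(r) {
        list(r[["source"]], r[["target"]], as.integer(r[["sign"]]))
      })),
      rule = net$rule,
      tie_prob = as.list(stats::setNames(frac_format(net$tie_prob), net$nodes))
    )
    if (length(net$clamped) > 0L) spec$clamped <- as.list(net$clamped)
    jsonlite::write_json(spec, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Tidy the edge table of a network
#'
#' @param x A [grn].
#' @param ... Unused.
#' @return The edge tibble (`source`, `target`, `sign`, `tag`).
#' @method tidy grn
#' @export
tidy.grn <- function(x, ...) x$edges

#' One-row summary of a network
#'
#' @param x A [grn].
#' @param ... Unused.
#' @method glance grn
#' @export
glance.grn <- function(x, ...) {
  cls <- node_is_probabilistic(x)
  tibble::tibble(
    nodes = length(x$nodes),
    edges = nrow(x$edges),
    rule = x$rule,
    n_probabilistic = sum(cls$probabilistic),
    n_clamped = length(x$clamped)
  )
}
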