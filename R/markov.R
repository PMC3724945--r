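# Exact construction and analysis of the finite Markov chain on the
# configuration space: transition matrix, attractors (terminal strongly
# connected components), extended absorbing classification, fundamental
# matrix, absorption probabilities, stationary distribution and mean
# return times.

signed_adjacency <- function(net) {
  n <- length(net$nodes)
  a <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) {
    a[cbind(match(net$edges$source, net$nodes),
            match(net$edges$target, net$nodes))] <- net$edges$sign
  }
  a
}

#' Build the synchronous transition model of a network
#'
#' Entry (x -> y) is the product over nodes of the probability that the node
#' moves to its value in y given configuration x: ties are resolved
#' independently per node. Clamped nodes are frozen at their clamp value and
#' removed from the state space, so the chain lives on the `2^m`
#' configurations of the m free nodes. All probabilities are exact fractions
#' when every tie probability is an exact fraction.
#'
#' @param net A [grn].
#' @return An object of class `grn_tm` with fields `net`, `free` (free node
#'   names), `n_states`, `states` (labels), `transitions` (tibble `from`,
#'   `to` 0-based indices, `prob`, `num`, `den`) and `exact`.
#' @examples
#' m <- two_node_model("+", "+", "+", "+", p = "1/2", q = "1/2")
#' tm <- transition_model(m)
#' as_matrix(tm)
#' @export
transition_model <- function(net) {
  stopifnot(inherits(net, "grn"))
  free <- setdiff(net$nodes, names(net$clamped))
  m <- length(free)
  if (m > 16L) stop("state space too large (more than 2^16 states)", call. = FALSE)
  n <- length(net$nodes)
  rep <- grn_representation(net)
  free_pos <- match(free, net$nodes)
  clamp_pos <- match(names(net$clamped), net$nodes)

  n_states <- as.integer(2^m)
  # values matrix: n_states x n, full configurations with clamps filled in
  bits <- matrix(0L, n_states, m)
  ix <- 0:(n_states - 1L)
  for (j in seq_len(m)) bits[, j] <- bitwAnd(ix %/% 2^(m - j), 1L)
  values <- matrix(0L, n_states, n)
  values[, free_pos] <- bits_to_values(bits, rep)
  if (length(clamp_pos) > 0L) {
    values[, clamp_pos] <- matrix(net$clamped, n_states, length(clamp_pos), byrow = TRUE)
  }

  adj <- signed_adjacency(net)
  u <- values %*% adj # contribution sums, state x node
  keep_rule <- net$rule %in% c("IMR", "INMR")
  p_num <- net$tie_prob$num
  p_den <- net$tie_prob$den
  exact <- all(frac_is_exact(net$tie_prob)[free_pos])

  from <- to <- integer(0)
  num <- den <- prob <- numeric(0)
  pow <- 2^(m - seq_len(m))
  for (s in seq_len(n_states)) {
    us <- u[s, free_pos]
    cur_high <- bits[s, ] == 1L
    # deterministic part of the next bit vector
    nxt <- ifelse(us > 0L, 1L, 0L)
    tied <- which(us == 0L)
    # tie factor for high outcome: p (MR/NMR); keep-current for IMR/INMR
    if (length(tied) > 0L) {
      gp <- free_pos[tied]
      ph_num <- p_num[gp]; ph_den <- p_den[gp]
      if (keep_rule) {
        low <- !cur_high[tied]
        ph_num[low] <- ifelse(is.na(ph_den[low]), 1 - ph_num[low],
                              ph_den[low] - ph_num[low])
      }
      ph <- ph_num / ifelse(is.na(ph_den), 1, ph_den)
      # drop ties that are degenerate (extreme tie probability)
      fixed_hi <- ph == 1
      fixed_lo <- ph == 0
      nxt[tied[fixed_hi]] <- 1L
      nxt[tied[fixed_lo]] <- 0L
      live <- !(fixed_hi | fixed_lo)
      tied <- tied[live]; ph <- ph[live]
      ph_num <- ph_num[live]; ph_den <- ph_den[live]
    }
    k <- length(tied)
    if (k == 0L) {
      from <- c(from, s - 1L); to <- c(to, as.integer(sum(nxt * pow)))
      num <- c(num, 1); den <- c(den, 1); prob <- c(prob, 1)
      next
    }
    n_out <- as.integer(2^k)
    base <- as.integer(sum(nxt[-tied] * pow[-tied]))
    for (o in 0:(n_out - 1L)) {
      obits <- bitwAnd(o %/% 2^(k - seq_len(k)), 1L)
      tgt <- base + as.integer(sum(obits * pow[tied]))
      f_num <- ifelse(obits == 1L, ph_num,
                      ifelse(is.na(ph_den), 1 - ph_num, ph_den - ph_num))
      f_den <- ifelse(is.na(ph_den), 1, ph_den)
      pr <- prod(ifelse(obits == 1L, ph, 1 - ph))
      from <- c(from, s - 1L); to <- c(to, tgt)
      num <- c(num, prod(f_num)); den <- c(den, prod(f_den))
      prob <- c(prob, pr)
    }
  }
  keep <- prob > 0
  labels <- vapply(seq_len(n_states), function(s) {
    format_configuration(bits_to_values(bits[s, ], rep), rep)
  }, "")
  tr <- tibble::tibble(from = from[keep], to = to[keep],
                       prob = prob[keep], num = num[keep], den = den[keep])
  if (!exact) tr$den <- NA_real_
  structure(
    list(net = net, free = free, n_states = n_states, states = labels,
         transitions = tr, exact = exact, representation = rep),
    class = "grn_tm"
  )
}

#' @export
print.grn_tm <- function(x, ...) {
  cat(sprintf("<grn_tm> %d states (%d free nodes), %d transitions, %s arithmetic\n",
              x$n_states, length(x$free), nrow(x$transitions),
              if (x$exact) "exact" else "double"))
  invisible(x)
}

#' Dense transition matrix of a transition model
#'
#' @param tm A `grn_tm`.
#' @param exact Return a `ratmat` (internal exact form) instead of a numeric
#'   matrix. Requires the model to be exact.
#' @return A row-stochastic matrix with configuration labels.
#' @export
as_matrix <- function(tm, exact = FALSE) {
  stopifnot(inherits(tm, "grn_tm"))
  n <- tm$n_states
  if (exact) {
    if (!tm$exact) stop("transition model is not exact", call. = FALSE)
    mnum <- matrix(0, n, n); mden <- matrix(1, n, n)
    idx <- cbind(tm$transitions$from + 1L, tm$transitions$to + 1L)
    mnum[idx] <- tm$transitions$num
    mden[idx] <- tm$transitions$den
    return(ratmat(mnum, mden))
  }
  out <- matrix(0, n, n, dimnames = list(tm$states, tm$states))
  out[cbind(tm$transitions$from + 1L, tm$transitions$to + 1L)] <- tm$transitions$prob
  out
}

#' Support digraph of a transition model
#'
#' One arc per structurally positive transition. With `generic = TRUE` the
#' call asserts that every tie probability of the underlying network lies
#' strictly inside (0, 1), so the support does not depend on parameter
#' values.
#'
#' @param tm A `grn_tm`.
#' @param generic Require generic (interior) tie probabilities.
#' @return An igraph directed graph on the state labels.
#' @export
support_digraph <- function(tm, generic = FALSE) {
  stopifnot(inherits(tm, "grn_tm"))
  if (generic) {
    tp <- frac_num(tm$net$tie_prob)
    free_pos <- match(tm$free, tm$net$nodes)
    prob_nodes <- node_is_probabilistic(tm$net)
    relevant <- prob_nodes$probabilistic[match(tm$free, prob_nodes$node)]
    if (any(tp[free_pos][relevant] %in% c(0, 1))) {
      stop("generic support requested but a tie probability is extreme; ",
           "use the exact matrix instead", call. = FALSE)
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = tm$states[tm$transitions$from + 1L],
               to = tm$states[tm$transitions$to + 1L],
               weight = tm$transitions$prob),
    directed = TRUE,
    vertices = data.frame(name = tm$states)
  )
  g
}

#' Ergodic sets (attractors) of the chain
#'
#' The attractors are the terminal strongly connected components of the
#' support digraph. Each is labelled `fixed_point` (a single state with
#' self-probability one), `deterministic_cycle` (every member has a unique
#' successor; the period is the set size) or `stochastic`.
#'
#' @param tm A `grn_tm`.
#' @return A tibble with columns `set_id`, `type`, `period` (NA unless a
#'   deterministic cycle), `size`, and `states` (list column of labels).
#' @export
ergodic_sets <- function(tm) {
  stopifnot(inherits(tm, "grn_tm"))
  g <- support_digraph(tm)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  # terminal: no arc leaves the component
  el <- igraph::as_edgelist(g, names = FALSE)
  leaving <- unique(memb[el[, 1L]][memb[el[, 1L]] != memb[el[, 2L]]])
  terminal <- setdiff(seq_len(comp$no), leaving)
  outdeg <- tabulate(tm$transitions$from + 1L, nbins = tm$n_states)
  res <- lapply(terminal, function(cid) {
    states_ix <- which(memb == cid)
    labels <- tm$states[states_ix]
    det <- all(outdeg[states_ix] == 1L)
    if (det && length(states_ix) == 1L) {
      type <- "fixed_point"; period <- 1L
    } else if (det) {
      type <- "deterministic_cycle"; period <- length(states_ix)
    } else {
      type <- "stochastic"; period <- NA_integer_
    }
    tibble::tibble(type = type, period = period, size = length(states_ix),
                   states = list(labels))
  })
  out <- dplyr::bind_rows(res)
  out <- out[order(vapply(out$states, `[[`, "", 1L)), ]
  out$set_id <- seq_len(nrow(out))
  out[c("set_id", "type", "period", "size", "states")]
}

scc_period <- function(tm, states_ix) {
  # gcd of cycle lengths through a reference state, via BFS levels
  sub <- tm$transitions[(tm$transitions$from + 1L) %in% states_ix &
                          (tm$transitions$to + 1L) %in% states_ix, ]
  relabel <- match(seq_len(tm$n_states), states_ix)
  fr <- relabel[sub$from + 1L]; to <- relabel[sub$to + 1L]
  nstate <- length(states_ix)
  level <- rep(NA_integer_, nstate)
  level[1L] <- 0L
  queue <- 1L
  adj <- split(to, fr)
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[as.character(v)]]) {
      if (is.na(level[w])) { level[w] <- level[v] + 1L; queue <- c(queue, w) }
    }
  }
  g <- 0L
  for (i in seq_len(nrow(sub))) {
    d <- level[fr[i]] + 1L - level[to[i]]
    g <- as.integer(frac_gcd(g, abs(d)))
  }
  if (g == 0L) 1L else g
}

#' Classify the chain
#'
#' `absorbing_extended` when every ergodic set is deterministic (a fixed
#' point or a deterministic cycle); `regular` when a single aperiodic
#' ergodic set covers the whole configuration space; `mixed` otherwise.
#'
#' @param tm A `grn_tm`.
#' @return A character scalar.
#' @export
classify_chain <- function(tm) {
  es <- ergodic_sets(tm)
  if (all(es$type %in% c("fixed_point", "deterministic_cycle"))) {
    return("absorbing_extended")
  }
  if (nrow(es) == 1L && es$size[[1L]] == tm$n_states) {
    states_ix <- match(es$states[[1L]], tm$states)
    if (scc_period(tm, states_ix) == 1L) return("regular")
  }
  "mixed"
}

transient_states <- function(tm, es = ergodic_sets(tm)) {
  setdiff(tm$states, unlist(es$states))
}

#' Fundamental matrix of an absorbing chain
#'
#' For a chain whose ergodic sets are all fixed points, returns
#' `N = (I - Q)^(-1)` over the transient states: entry (i, j) is the
#' expected number of visits to j starting from i before absorption. When
#' deterministic cycles are present, Q is taken from the k-th matrix power
#' (k the lcm of the cycle periods) and the per-block visit counts are
#' scaled by k to be per step.
#'
#' @param tm A `grn_tm`; the chain must classify as `absorbing_extended`.
#' @param exact Use exact rational arithmetic (requires an exact model and
#'   at most 64 transient states). Default: automatic.
#' @return A numeric matrix with transient-state labels; when computed
#'   exactly, the exact fractions are attached as attribute `"exact"`
#'   (a `ratmat`).
#' @export
fundamental_matrix <- function(tm, exact = NULL) {
  es <- ergodic_sets(tm)
  if (!all(es$type %in% c("fixed_point", "deterministic_cycle"))) {
    stop("fundamental matrix requires an absorbing (extended) chain", call. = FALSE)
  }
  tr <- transient_states(tm, es)
  if (length(tr) == 0L) {
    out <- matrix(numeric(0), 0L, 0L)
    return(out)
  }
  periods <- es$period
  k <- Reduce(function(a, b) a * b / frac_gcd(a, b), periods, accumulate = FALSE)
  k <- as.integer(k)
  tr_ix <- match(tr, tm$states)
  if (is.null(exact)) exact <- tm$exact && length(tr) <= 64L && tm$n_states <= 64L
  if (exact) {
    tmat <- as_matrix(tm, exact = TRUE)
    if (k > 1L) tmat <- ratmat_power(tmat, k)
    q <- ratmat(tmat$num[tr_ix, tr_ix, drop = FALSE],
                tmat$den[tr_ix, tr_ix, drop = FALSE])
    iq <- ratmat_sub(ratmat_identity(length(tr_ix)), q)
    nmat <- ratmat_solve(iq)
    if (k > 1L) nmat <- ratmat_elementwise(nmat, ratmat_from_frac(
      frac(rep(k, length(tr_ix)^2)), length(tr_ix), length(tr_ix)), "*")
    out <- ratmat_numeric(nmat)
    dimnames(out) <- list(tr, tr)
    attr(out, "exact") <- nmat
    return(out)
  }
  tmat <- as_matrix(tm)
  if (k > 1L) {
    tk <- diag(nrow(tmat))
    for (i in seq_len(k)) tk <- tk %*% tmat
    tmat <- tk
  }
  q <- tmat[tr_ix, tr_ix, drop = FALSE]
  out <- k * solve(diag(length(tr_ix)) - q)
  dimnames(out) <- list(tr, tr)
  out
}

#' Absorption probabilities from each transient state into each ergodic set
#'
#' `B = N R`, with R the transient-to-ergodic block of the transition
#' matrix (of its k-th power when deterministic cycles are present). Rows
#' sum to one.
#'
#' @param tm A `grn_tm`; must classify as `absorbing_extended`.
#' @return A numeric matrix, transient states by ergodic sets (columns
#'   named by the first state of each set).
#' @export
absorption_probabilities <- function(tm) {
  es <- ergodic_sets(tm)
  if (!all(es$type %in% c("fixed_point", "deterministic_cycle"))) {
    stop("absorption probabilities require an absorbing (extended) chain",
         call. = FALSE)
  }
  tr <- transient_states(tm, es)
  if (length(tr) == 0L) return(matrix(numeric(0), 0L, nrow(es)))
  k <- as.integer(Reduce(function(a, b) a * b / frac_gcd(a, b), es$period))
  tmat <- as_matrix(tm)
  if (k > 1L) {
    tk <- diag(nrow(tmat))
    for (i in seq_len(k)) tk <- tk %*% tmat
    tmat <- tk
  }
  tr_ix <- match(tr, tm$states)
  nmat <- solve(diag(length(tr_ix)) - tmat[tr_ix, tr_ix, drop = FALSE])
  b_states <- nmat %*% tmat[tr_ix, -tr_ix, drop = FALSE]
  abs_states <- tm$states[-tr_ix]
  set_of <- rep(seq_len(nrow(es)), times = es$size)
  names(set_of) <- unlist(es$states)
  out <- matrix(0, length(tr), nrow(es),
                dimnames = list(tr, vapply(es$states, `[[`, "", 1L)))
  for (j in seq_along(abs_states)) {
    out[, set_of[[abs_states[[j]]]]] <- out[, set_of[[abs_states[[j]]]]] +
      b_states[, j]
  }
  out
}

#' Stationary distribution and mean return times
#'
#' Solves pi = pi T on an ergodic set and reports the mean return time of
#' every member state, `m_i = 1 / pi_i`. For a regular chain the set is the
#' whole space; otherwise `set_id` selects one ergodic set.
#'
#' @param tm A `grn_tm`.
#' @param set_id Ergodic set to analyse (default: the single set of a
#'   regular chain; required otherwise).
#' @return A tibble with columns `state`, `pi`, `pi_exact`, `mean_return`.
#' @export
stationary_distribution <- function(tm, set_id = NULL) {
  es <- ergodic_sets(tm)
  if (is.null(set_id)) {
    if (nrow(es) != 1L) {
      stop("chain has several ergodic sets; give `set_id`", call. = FALSE)
    }
    set_id <- 1L
  }
  states <- es$states[[set_id]]
  ix <- match(states, tm$states)
  ns <- length(ix)
  use_exact <- tm$exact && ns <= 64L
  if (use_exact && tm$n_states <= 256L) {
    tmat <- as_matrix(tm, exact = TRUE)
    a <- ratmat(t(tmat$num[ix, ix, drop = FALSE]), t(tmat$den[ix, ix, drop = FALSE]))
    # (T' - I) pi = 0 with sum(pi) = 1: replace last row by ones
    a <- ratmat_sub(a, ratmat_identity(ns))
    a$num[ns, ] <- 1; a$den[ns, ] <- 1
    rhs <- ratmat(matrix(0, ns, ns))
    rhs$num[ns, 1L] <- 1
    sol <- ratmat_solve(a, rhs)
    pi_frac <- frac(sol$num[, 1L], sol$den[, 1L])
    pi <- frac_num(pi_frac)
    mr <- frac_num(frac_div(frac(1), pi_frac))
    return(tibble::tibble(state = states, pi = pi,
                          pi_exact = frac_format(pi_frac), mean_return = mr))
  }
  tmat <- as_matrix(tm)[ix, ix, drop = FALSE]
  a <- t(tmat) - diag(ns)
  a[ns, ] <- 1
  rhs <- c(rep(0, ns - 1L), 1)
  pi <- solve(a, rhs)
  tibble::tibble(state = states, pi = pi, pi_exact = NA_character_,
                 mean_return = 1 / pi)
}

#' Full chain analysis
#'
#' Bundles classification, ergodic sets, transient states and, where
#' defined, the fundamental matrix, absorption probabilities and the
#' stationary distribution with mean return times.
#'
#' @param x A [grn] or a `grn_tm`.
#' @param ... Unused.
#' @return An object of class `grn_chain`.
#' @export
chain_analysis <- function(x, ...) {
  tm <- if (inherits(x, "grn_tm")) x else transition_model(x)
  es <- ergodic_sets(tm)
  cls <- classify_chain(tm)
  out <- list(tm = tm, classification = cls, ergodic_sets = es,
              transient = transient_states(tm, es),
              fundamental = NULL, absorption = NULL, stationary = NULL)
  if (cls == "absorbing_extended" && length(out$transient) > 0L) {
    out$fundamental <- fundamental_matrix(tm)
    out$absorption <- absorption_probabilities(tm)
  }
  if (cls == "regular") {
    out$stationary <- stationary_distribution(tm)
  }
  structure(out, class = "grn_chain")
}

#' @export
print.grn_chain <- function(x, ...) {
  cat(sprintf("<grn_chain> %s; %d ergodic set(s), %d transient state(s)\n",
              x$classification, nrow(x$ergodic_sets), length(x$transient)))
  print(x$ergodic_sets)
  invisible(x)
}

#' Per-state tidy view of a chain analysis
#'
#' @param x A `grn_chain`.
#' @param ... Unused.
#' @return A tibble with one row per state: `state`, `role` (transient or
#'   ergodic), `set_id`, `set_type`, and `pi`/`mean_return` for regular
#'   chains.
#' @method tidy grn_chain
#' @export
tidy.grn_chain <- function(x, ...) {
  es <- x$ergodic_sets
  erg <- tidyr::unnest(es[c("set_id", "type", "states")], "states")
  names(erg) <- c("set_id", "set_type", "state")
  out <- tibble::tibble(state = x$tm$states)
  out <- dplyr::left_join(out, erg, by = "state")
  out$role <- ifelse(is.na(out$set_id), "transient", "ergodic")
  if (!is.null(x$stationary)) {
    out <- dplyr::left_join(out, x$stationary[c("state", "pi", "mean_return")],
                            by = "state")
  }
  out
}

#' One-row summary of a chain analysis
#'
#' @param x A `grn_chain`.
#' @param ... Unused.
#' @method glance grn_chain
#' @export
glance.grn_chain <- function(x, ...) {
  tibble::tibble(
    states = x$tm$n_states,
    transitions = nrow(x$tm$transitions),
    classification = x$classification,
    n_ergodic_sets = nrow(x$ergodic_sets),
    n_fixed_points = sum(x$ergodic_sets$type == "fixed_point"),
    n_deterministic_cycles = sum(x$ergodic_sets$type == "deterministic_cycle"),
    n_transient = length(x$transient)
  )
}

#' Plot the stationary structure of a chain analysis
#'
#' Regular chains: bar chart of mean return times per state. Absorbing
#' chains: bar chart of ergodic-set sizes by type.
#'
#' @param object A `grn_chain`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grn_chain
#' @export
autoplot.grn_chain <- function(object, ...) {
  if (!is.null(object$stationary)) {
    df <- object$stationary
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$mean_return)) +
        ggplot2::geom_col() +
        ggplot2::labs(x = "configuration", y = "mean return time") +
        ggplot2::theme_minimal()
    )
  }
  df <- object$ergodic_sets
  df$label <- vapply(df$states, `[[`, "", 1L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$size,
                                   fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "attractor (first state)", y = "states in ergodic set") +
    ggplot2::theme_minimal()
}

#' Export a transition model
#'
#' `write_transition_csv()` writes the dense matrix with configuration
#' labels; `write_transition_dot()` writes the support digraph in DOT format
#' with probabilities as edge labels (exact fractions when available).
#'
#' @param tm A `grn_tm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(tm, path) {
  m <- as_matrix(tm)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_transition_csv
#' @export
write_transition_dot <- function(tm, path) {
  tr <- tm$transitions
  lab <- if (tm$exact) {
    ifelse(tr$den == 1, as.character(tr$num), paste0(tr$num, "/", tr$den))
  } else {
    formatC(tr$prob, digits = 6, format = "g")
  }
  lines <- c(
    "digraph chain {",
    paste0("  \"", tm$states[tr$from + 1L], "\" -> \"", tm$states[tr$to + 1L],
           "\" [label=\"", lab, "\"];"),
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}
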