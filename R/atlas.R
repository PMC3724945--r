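# The two-node model atlas.
#
# A module is one node together with its incoming interactions; here each of
# the two nodes carries a self-interaction (sign sigma) and a cross input
# from the other node (sign tau), giving four modules and sixteen composed
# models per rule. The atlas enumerates the models, partitions them into
# in-phase (IP) and out-of-phase (OP) families by the placement of their
# probabilistic transitions, groups them into isomorphism classes (equal
# Markov matrices up to state renaming and a bijective parameter
# correspondence), and realises each model as a random walk over its four
# extreme deterministic maps.

module_signs <- c("+" = 1L, "-" = -1L)

norm_sign <- function(x) {
  if (is.character(x)) x <- module_signs[[x]]
  stopifnot(x %in% c(-1L, 1L))
  as.integer(x)
}

module_label <- function(self_sign, cross_sign) {
  paste0("(", ifelse(self_sign > 0, "+", "-"),
         ",", ifelse(cross_sign > 0, "+", "-"), ")")
}

#' Build a two-node model from two modules
#'
#' Node `n1` is governed by `module 1` (self-sign `self1`, cross input from
#' `n2` with sign `cross1`) and symmetrically for `n2`. Tie probabilities are
#' `p` (node 1) and `q` (node 2).
#'
#' @param self1,cross1,self2,cross2 Signs, given as `"+"`/`"-"` or `+-1`.
#' @param p,q Tie probabilities (numbers or fraction strings). Defaults are
#'   the package's generic interior parameters 1/3 and 2/3.
#' @param rule Update rule.
#' @return A [grn] with nodes `n1`, `n2`.
#' @examples
#' two_node_model("+", "+", "+", "+") # mutual activation with self-activation
#' @export
two_node_model <- function(self1, cross1, self2, cross2,
                           p = "1/3", q = "2/3", rule = "MR") {
  s1 <- norm_sign(self1); c1 <- norm_sign(cross1)
  s2 <- norm_sign(self2); c2 <- norm_sign(cross2)
  grn(tibble::tibble(source = c("n1", "n2", "n2", "n1"),
                     target = c("n1", "n1", "n2", "n2"),
                     sign = c(s1, c1, s2, c2)),
      nodes = c("n1", "n2"), rule = rule,
      tie_prob = c(n1 = as.character(p), n2 = as.character(q)))
}

#' Enumerate the sixteen two-node models
#'
#' All ordered pairs of the four modules (self and cross signs in
#' `{+1, -1}`).
#'
#' @param rule Update rule.
#' @param p,q Tie probabilities used when the models are instantiated.
#' @return A tibble with 16 rows: `model` (label), the four signs, and
#'   `net` (list column of [grn] objects).
#' @export
enumerate_two_node_models <- function(rule = "MR", p = "1/3", q = "2/3") {
  signs <- c(1L, -1L)
  grid <- expand.grid(self1 = signs, cross1 = signs,
                      self2 = signs, cross2 = signs,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- tibble::as_tibble(grid)
  grid$model <- paste0(module_label(grid$self1, grid$cross1), "x",
                       module_label(grid$self2, grid$cross2))
  grid$net <- purrr::pmap(grid[c("self1", "cross1", "self2", "cross2")],
                          function(self1, cross1, self2, cross2) {
                            two_node_model(self1, cross1, self2, cross2,
                                           p = p, q = q, rule = rule)
                          })
  grid[c("model", "self1", "cross1", "self2", "cross2", "net")]
}

# update table of a module under MR: symbol per local configuration
# (s_self, s_cross) in the fixed order (+,+), (-,+), (-,-), (+,-):
# "+" deterministic high, "-" deterministic low, "T" tie.
module_table <- function(self_sign, cross_sign) {
  configs <- list(c(1L, 1L), c(-1L, 1L), c(-1L, -1L), c(1L, -1L))
  vapply(configs, function(cf) {
    u <- self_sign * cf[[1L]] + cross_sign * cf[[2L]]
    if (u > 0L) "+" else if (u < 0L) "-" else "T"
  }, "")
}

#' Row rotation acting on the four majority-rule modules
#'
#' With local configurations listed in the order (+,+), (-,+), (-,-), (+,-),
#' rotating the rows of a module's update table (modulo 4, top to bottom)
#' yields the table of another module. The four modules form a single orbit
#' and the fourth iterate is the identity.
#'
#' @param self_sign,cross_sign Module signs (`"+"`/`"-"` or `+-1`).
#' @return A list with the rotated module's `self_sign` and `cross_sign`.
#' @export
rho_rotate <- function(self_sign, cross_sign) {
  s <- norm_sign(self_sign); cr <- norm_sign(cross_sign)
  tab <- module_table(s, cr)
  rotated <- tab[c(4L, 1L, 2L, 3L)] # row k -> row k + 1 (mod 4)
  for (s2 in c(1L, -1L)) {
    for (c2 in c(1L, -1L)) {
      if (identical(module_table(s2, c2), rotated)) {
        return(list(self_sign = s2, cross_sign = c2))
      }
    }
  }
  stop("internal error: rotated table matches no module") # nocov
}

#' Phase of a two-node model: in phase (IP) or out of phase (OP)
#'
#' Decided operationally from the 4x4 matrix at generic parameters: IP
#' models have two rows with four probabilistic entries (both nodes tied)
#' and two deterministic rows, totalling ten transitions; OP models have two
#' probabilistic entries in every row (one node tied), totalling eight.
#' This coincides with the structural criterion sigma1 * tau1 == sigma2 *
#' tau2 (ties of the two nodes located in the same configurations), which is
#' asserted.
#'
#' @param net A two-node [grn] built by [two_node_model()].
#' @return `"IP"` or `"OP"`.
#' @export
model_phase <- function(net) {
  stopifnot(inherits(net, "grn"), length(net$nodes) == 2L)
  tm <- transition_model(net)
  m <- as_matrix(tm)
  per_row <- unname(rowSums(m > 0))
  phase <- if (identical(sort(per_row), c(1, 1, 4, 4))) {
    "IP"
  } else if (all(per_row == 2)) {
    "OP"
  } else {
    stop("two-node matrix fits neither the IP nor the OP row pattern",
         call. = FALSE)
  }
  e <- net$edges
  sig <- function(src, tgt) e$sign[e$source == src & e$target == tgt]
  structural <- if (sig("n1", "n1") * sig("n2", "n1") ==
                    sig("n2", "n2") * sig("n1", "n2")) "IP" else "OP"
  stopifnot(identical(phase, structural))
  phase
}

# the 8 injective parameter substitutions mapping (p, q) into
# {p, 1-p, q, 1-q} with distinct underlying parameters
parameter_substitutions <- function() {
  list(
    c("p", "q"), c("p", "1-q"), c("1-p", "q"), c("1-p", "1-q"),
    c("q", "p"), c("q", "1-p"), c("1-q", "p"), c("1-q", "1-p")
  )
}

apply_substitution <- function(sub, p, q) {
  lookup <- function(tok) switch(tok, "p" = p, "q" = q,
                                 "1-p" = frac_one_minus(p),
                                 "1-q" = frac_one_minus(q))
  list(p = lookup(sub[[1L]]), q = lookup(sub[[2L]]))
}

# exact 4x4 matrix of a two-node model evaluated at fraction parameters
two_node_matrix_at <- function(self1, cross1, self2, cross2, rule, p, q) {
  net <- two_node_model(self1, cross1, self2, cross2,
                        p = frac_format(p), q = frac_format(q), rule = rule)
  as_matrix(transition_model(net), exact = TRUE)
}

iso_test_points <- function() {
  list(list(p = frac(1, 3), q = frac(2, 7)),
       list(p = frac(2, 5), q = frac(3, 7)),
       list(p = frac(1, 7), q = frac(5, 11)))
}

all_state_permutations <- function() {
  perms <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    perms[[length(perms) + 1L]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  }
  perms
}

#' Test whether two two-node models are isomorphic
#'
#' Two models are equivalent when their Markov matrices coincide up to a
#' renaming of the four states and a bijective correspondence of the
#' parameters (p, q) into {p, 1-p, q, 1-q}. Matrix entries are polynomials
#' of degree at most one in each parameter, so exact agreement at three
#' generic rational points implies identity; the search is exhaustive over
#' the 24 state permutations and 8 parameter substitutions.
#'
#' @param a,b Two-node models (rows of [enumerate_two_node_models()] or
#'   [grn] objects with two nodes).
#' @return `TRUE` or `FALSE`, with attribute `witness` (list with
#'   `permutation` and `substitution`) on success.
#' @export
models_isomorphic <- function(a, b) {
  sig <- function(x) {
    e <- x$edges
    g <- function(src, tgt) e$sign[e$source == src & e$target == tgt]
    c(g("n1", "n1"), g("n2", "n1"), g("n2", "n2"), g("n1", "n2"))
  }
  sa <- sig(a); sb <- sig(b)
  pts <- iso_test_points()
  mats_a <- lapply(pts, function(pt) {
    two_node_matrix_at(sa[1], sa[2], sa[3], sa[4], a$rule, pt$p, pt$q)
  })
  perms <- all_state_permutations()
  for (sub in parameter_substitutions()) {
    mats_b <- lapply(pts, function(pt) {
      s <- apply_substitution(sub, pt$p, pt$q)
      two_node_matrix_at(sb[1], sb[2], sb[3], sb[4], b$rule, s$p, s$q)
    })
    for (perm in perms) {
      ok <- TRUE
      for (i in seq_along(pts)) {
        pa <- mats_a[[i]]
        pb <- mats_b[[i]]
        permuted <- ratmat(pb$num[perm, perm, drop = FALSE],
                           pb$den[perm, perm, drop = FALSE])
        if (!ratmat_equal(pa, permuted)) { ok <- FALSE; break }
      }
      if (ok) {
        res <- TRUE
        attr(res, "witness") <- list(permutation = perm, substitution = sub)
        return(res)
      }
    }
  }
  FALSE
}

#' Classify the sixteen two-node models into isomorphism classes
#'
#' Partitions the models by the transitive closure of [models_isomorphic()]
#' and attaches the structural class labels: within each phase family,
#' class 1 gathers the models with two self-activations, class 2 those with
#' two self-inhibitions, and class 3 the self-asymmetric models.
#'
#' @param rule Update rule (`"MR"` or `"IMR"` carry the canonical labels;
#'   `"NMR"`/`"INMR"` are classified by the same engine and labelled
#'   descriptively).
#' @return A tibble with one row per model: `model`, signs, `phase`,
#'   `class_id` (integer partition id) and `class` (label such as `"IP1"`).
#' @export
atlas_classes <- function(rule = "MR") {
  models <- enumerate_two_node_models(rule = rule)
  n <- nrow(models)
  spin_rule <- rule %in% c("MR", "IMR")
  models$phase <- if (spin_rule) {
    vapply(models$net, model_phase, "")
  } else {
    # the IP/OP row patterns are specific to the spin rules; the Boolean
    # variants are classified purely by the isomorphism search
    rep(NA_character_, n)
  }
  # precompute exact matrices at the three test points for every model and
  # every parameter substitution, so the pairwise search is pure comparison
  pts <- iso_test_points()
  subs <- parameter_substitutions()
  signs_of <- function(k) unlist(models[k, c("self1", "cross1", "self2", "cross2")])
  base_mats <- lapply(seq_len(n), function(k) {
    sg <- signs_of(k)
    lapply(pts, function(pt) {
      two_node_matrix_at(sg[1], sg[2], sg[3], sg[4], rule, pt$p, pt$q)
    })
  })
  sub_mats <- lapply(seq_len(n), function(k) {
    sg <- signs_of(k)
    lapply(subs, function(sub) {
      lapply(pts, function(pt) {
        s <- apply_substitution(sub, pt$p, pt$q)
        two_node_matrix_at(sg[1], sg[2], sg[3], sg[4], rule, s$p, s$q)
      })
    })
  })
  perms <- all_state_permutations()
  pair_isomorphic <- function(i, j) {
    for (s in seq_along(subs)) {
      for (perm in perms) {
        ok <- TRUE
        for (t in seq_along(pts)) {
          pb <- sub_mats[[j]][[s]][[t]]
          permuted <- ratmat(pb$num[perm, perm, drop = FALSE],
                             pb$den[perm, perm, drop = FALSE])
          if (!ratmat_equal(base_mats[[i]][[t]], permuted)) { ok <- FALSE; break }
        }
        if (ok) return(TRUE)
      }
    }
    FALSE
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (spin_rule && models$phase[[i]] != models$phase[[j]]) next
      if (find(i) == find(j)) next
      if (pair_isomorphic(i, j)) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  models$class_id <- as.integer(factor(roots, levels = unique(roots)))
  models$class <- if (spin_rule) {
    paste0(models$phase,
           ifelse(models$self1 > 0 & models$self2 > 0, "1",
                  ifelse(models$self1 < 0 & models$self2 < 0, "2", "3")))
  } else {
    paste0("class", models$class_id)
  }
  models[c("model", "self1", "cross1", "self2", "cross2", "phase",
           "class_id", "class", "net")]
}

#' Logical connectors realised at the extreme tie corners
#'
#' At extreme tie probabilities the model is deterministic and each node's
#' update is a Boolean function of the two node values; for models whose
#' cross inputs are activations this function is reported as AND/OR over
#' the (possibly negated) inputs.
#'
#' @param net A two-node model.
#' @return A tibble with one row per corner (`corner_n1`, `corner_n2` are
#'   the tie outcomes) and the matched connector per node (`"AND"`, `"OR"`,
#'   or the matched truth table as a string for non-canonical cases).
#' @export
logic_corner_table <- function(net) {
  stopifnot(inherits(net, "grn"), length(net$nodes) == 2L)
  configs <- lapply(0:3, index_to_state, n = 2L,
                    representation = grn_representation(net))
  connector_of <- function(outputs, inputs) {
    # outputs: next bit per configuration; inputs: 4 x 2 bit matrix
    and_tab <- inputs[, 1L] & inputs[, 2L]
    or_tab <- inputs[, 1L] | inputs[, 2L]
    if (identical(outputs == 1L, and_tab)) return("AND")
    if (identical(outputs == 1L, or_tab)) return("OR")
    paste(outputs, collapse = "")
  }
  inputs <- do.call(rbind, lapply(configs, config_bits))
  corners <- expand.grid(corner_n1 = c(0L, 1L), corner_n2 = c(0L, 1L))
  res <- lapply(seq_len(nrow(corners)), function(i) {
    corner <- c(n1 = corners$corner_n1[[i]], n2 = corners$corner_n2[[i]])
    succ <- extreme_deterministic_map(net, corner)
    next_bits <- do.call(rbind, lapply(succ, function(s) {
      config_bits(index_to_state(s, 2L, grn_representation(net)))
    }))
    tibble::tibble(
      corner_n1 = corner[["n1"]], corner_n2 = corner[["n2"]],
      connector_n1 = connector_of(next_bits[, 1L], inputs),
      connector_n2 = connector_of(next_bits[, 2L], inputs)
    )
  })
  dplyr::bind_rows(res)
}

#' Random-map realisation of a two-node model
#'
#' The chain can be realised as a random walk on the four extreme
#' deterministic maps (tie outcomes fixed high/low per node): at each step
#' one map is drawn -- with the product probabilities implied by independent
#' per-node tie resolutions -- and its unique transition applied. The
#' induced one-step law equals the model's transition matrix exactly.
#'
#' @param net A two-node model.
#' @return A list with `maps` (list of four successor vectors, named by the
#'   corner), `weights` (their probabilities), and `step(state_index)`
#'   (a sampling function; relies on the current RNG stream).
#' @export
random_map_sampler <- function(net) {
  stopifnot(inherits(net, "grn"), length(net$nodes) == 2L)
  p <- frac_num(frac_idx(net$tie_prob, 1L))
  q <- frac_num(frac_idx(net$tie_prob, 2L))
  corners <- list(c(n1 = 1L, n2 = 1L), c(n1 = 1L, n2 = 0L),
                  c(n1 = 0L, n2 = 1L), c(n1 = 0L, n2 = 0L))
  weights <- c(p * q, p * (1 - q), (1 - p) * q, (1 - p) * (1 - q))
  maps <- lapply(corners, function(cn) extreme_deterministic_map(net, cn))
  names(maps) <- vapply(corners, function(cn) paste0(cn[["n1"]], cn[["n2"]]), "")
  list(
    maps = maps,
    weights = stats::setNames(weights, names(maps)),
    step = function(state_index) {
      pick <- sample.int(4L, 1L, prob = weights)
      maps[[pick]][[state_index + 1L]]
    }
  )
}
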