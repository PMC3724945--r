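test_that("the two-node enumeration covers all module compositions", {
  models <- enumerate_two_node_models("MR")
  expect_equal(nrow(models), 16L)
  expect_equal(nrow(unique(models[c("self1", "cross1", "self2", "cross2")])), 16L)
  # every matrix is 4x4 row-stochastic
  for (net in models$net) {
    tm <- transition_model(net)
    expect_equal(tm$n_states, 4L)
    expect_rows_sum_to_one(tm)
  }
})

test_that("node symmetry partitions the models into 6 pairs + 4 fixed", {
  models <- enumerate_two_node_models("MR")
  key <- paste0(models$self1, models$cross1, ":", models$self2, models$cross2)
  swapped <- paste0(models$self2, models$cross2, ":", models$self1, models$cross1)
  orbit <- vapply(seq_len(16), function(i) {
    paste(sort(c(key[i], swapped[i])), collapse = "|")
  }, "")
  sizes <- table(table(orbit))
  expect_equal(unname(sizes[["1"]]), 4L) # self-symmetric models
  expect_equal(unname(sizes[["2"]]), 6L) # swapped pairs
})

test_that("the row rotation permutes the four modules in a single orbit", {
  start <- list(self_sign = 1L, cross_sign = 1L)
  seen <- character(0)
  cur <- start
  for (i in 1:4) {
    seen <- c(seen, paste0(cur$self_sign, ",", cur$cross_sign))
    cur <- rho_rotate(cur$self_sign, cur$cross_sign)
  }
  expect_equal(length(unique(seen)), 4L) # one orbit through all modules
  expect_equal(cur, list(self_sign = 1L, cross_sign = 1L)) # rho^4 = id
  # rho commutes with building the table: table(rho(m)) = rotated table(m)
  for (s in c(1L, -1L)) for (cr in c(1L, -1L)) {
    rot <- rho_rotate(s, cr)
    expect_equal(grnmr:::module_table(rot$self_sign, rot$cross_sign),
                 grnmr:::module_table(s, cr)[c(4L, 1L, 2L, 3L)])
  }
})

test_that("the phase partition is 8 IP / 8 OP and follows the row pattern", {
  models <- enumerate_two_node_models("MR")
  phase <- vapply(models$net, model_phase, "")
  expect_equal(sum(phase == "IP"), 8L)
  expect_equal(sum(phase == "OP"), 8L)
  # the structural criterion (ties in the same configurations) is asserted
  # inside model_phase; spot-check the quoted examples
  expect_equal(model_phase(model_of("a", "a")), "IP")
  expect_equal(model_phase(model_of("a", "b")), "OP")
})

test_that("isomorphism finds the documented witnesses and refuses IP vs OP", {
  m_aa <- model_of("a", "a")
  expect_true(isTRUE(models_isomorphic(m_aa, m_aa)))
  # the two IP1 members are isomorphic
  res <- models_isomorphic(m_aa, model_of("b", "b"))
  expect_true(isTRUE(res))
  expect_named(attr(res, "witness"), c("permutation", "substitution"))
  # no IP model is isomorphic to an OP model
  expect_false(isTRUE(models_isomorphic(m_aa, model_of("a", "b"))))
  expect_false(isTRUE(models_isomorphic(model_of("c", "c"), model_of("c", "d"))))
  # IP2 is not isomorphic to IP3 despite equal diagonals
  expect_false(isTRUE(models_isomorphic(model_of("c", "c"), model_of("a", "d"))))
})

test_that("MR models fall into 3 IP + 3 OP classes of sizes 2, 2, 4", {
  ac <- atlas_classes("MR")
  counts <- dplyr::count(ac, phase, class_id)
  expect_equal(nrow(counts), 6L)
  expect_equal(sort(counts$n[counts$phase == "IP"]), c(2L, 2L, 4L))
  expect_equal(sort(counts$n[counts$phase == "OP"]), c(2L, 2L, 4L))
  # structural labels are constant within each partition class
  expect_true(all(tapply(ac$class, ac$class_id,
                         function(x) length(unique(x))) == 1L))
  # quoted memberships: IP1 self-activations with symmetric cross,
  # IP2 self-inhibitions with symmetric cross
  expect_setequal(ac$model[ac$class == "IP1"],
                  c("(+,+)x(+,+)", "(+,-)x(+,-)"))
  expect_setequal(ac$model[ac$class == "IP2"],
                  c("(-,+)x(-,+)", "(-,-)x(-,-)"))
  expect_equal(sum(ac$class == "IP3"), 4L)
  expect_setequal(ac$model[ac$class == "OP1"],
                  c("(+,+)x(+,-)", "(+,-)x(+,+)"))
})

test_that("IMR produces the same class structure and members as MR", {
  mr <- atlas_classes("MR")
  imr <- atlas_classes("IMR")
  expect_equal(imr$phase, mr$phase)
  expect_equal(imr$class, mr$class)
  # identical partitions as set systems
  split_mr <- split(mr$model, mr$class_id)
  split_imr <- split(imr$model, imr$class_id)
  expect_setequal(
    unname(vapply(split_mr, function(x) paste(sort(x), collapse = "|"), "")),
    unname(vapply(split_imr, function(x) paste(sort(x), collapse = "|"), "")))
})

test_that("MR and IMR differ in the documented way on the OP3 example", {
  # loop probabilities of the model composing modules (-,-) and (+,-):
  # 1-p and p under MR, both equal to p under IMR
  p <- 1 / 3
  d_mr <- diag(as_matrix(transition_model(
    two_node_model("-", "-", "+", "-", p = "1/3", q = "1/3", rule = "MR"))))
  d_imr <- diag(as_matrix(transition_model(
    two_node_model("-", "-", "+", "-", p = "1/3", q = "1/3", rule = "IMR"))))
  expect_setequal(round(d_mr[d_mr > 0], 10), round(c(p, 1 - p), 10))
  expect_equal(unname(d_imr[d_imr > 0]), c(p, p))
})

test_that("NMR models built from balanced modules equal their MR counterparts", {
  for (mods in list(c("b", "b"), c("b", "c"), c("c", "b"), c("c", "c"))) {
    nm <- as_matrix(transition_model(
      model_of(mods[1], mods[2], p = "2/7", q = "3/5", rule = "NMR")), exact = TRUE)
    mm <- as_matrix(transition_model(
      model_of(mods[1], mods[2], p = "2/7", q = "3/5", rule = "MR")), exact = TRUE)
    # state labels differ (0/1 vs -/+) but the indexing bijection aligns them
    expect_true(ratmat_equal(nm, mm))
  }
})

test_that("the NMR census shows the restricted behaviour of the null rule", {
  models <- enumerate_two_node_models("NMR")
  es_all <- lapply(models$net, function(n) ergodic_sets(transition_model(n)))
  absorbing <- vapply(es_all, function(es) {
    all(es$type %in% c("fixed_point", "deterministic_cycle"))
  }, TRUE)
  small <- vapply(es_all, function(es) all(es$size <= 2L), TRUE)
  # eleven of sixteen models converge to a fixed point or a small cycle
  expect_equal(sum(small), 11L)
  # of these, nine are absorbing in the strict extended sense (the other two
  # end in a two-state ergodic set that is stochastic, not a deterministic
  # cycle); frozen from the hand enumeration of all sixteen models
  expect_equal(sum(absorbing), 9L)
  expect_true(all(absorbing | !small | vapply(es_all, function(es) {
    any(es$type == "stochastic" & es$size == 2L)
  }, TRUE)))
  # more absorbing models than under the MR (which has four)
  mr_absorbing <- vapply(enumerate_two_node_models("MR")$net, function(n) {
    all(ergodic_sets(transition_model(n))$type %in%
          c("fixed_point", "deterministic_cycle"))
  }, TRUE)
  expect_equal(sum(mr_absorbing), 4L)
  expect_gt(sum(absorbing), sum(mr_absorbing))
})

test_that("OP2 synchronous (period-3) transitions strengthen toward extremes", {
  # the period-3 cycle of the self-inhibition/asymmetric-cross model runs
  # through its synchronous transition (both nodes flip); its probability
  # grows monotonically as the parameters approach the extreme corner
  weight <- function(pv) {
    tm <- transition_model(two_node_model("-", "+", "-", "-",
                                          p = pv, q = pv, rule = "MR"))
    tmat <- as_matrix(tm)
    flip <- vapply(tm$states, function(s) chartr("+-", "-+", s), "")
    max(tmat[cbind(tm$states, flip)])
  }
  w <- vapply(c("1/2", "3/5", "7/10", "4/5", "9/10"), weight, 0)
  expect_true(all(diff(w) > 0))
})

test_that("the random-map mixture reproduces the transition matrix exactly", {
  for (pq in list(c("1/2", "1/2"), c("1/3", "2/3"))) {
    net <- ip1_model(p = pq[1], q = pq[2])
    rm <- random_map_sampler(net)
    expect_equal(sum(rm$weights), 1)
    mix <- matrix(0, 4, 4)
    for (k in seq_along(rm$maps)) {
      step <- rm$maps[[k]]
      for (s in 0:3) mix[s + 1, step[s + 1] + 1] <-
          mix[s + 1, step[s + 1] + 1] + rm$weights[[k]]
    }
    expect_equal(mix, unname(as_matrix(transition_model(net))),
                 tolerance = 1e-12)
  }
  # p = q = 1/2 draws the four extreme maps uniformly
  expect_equal(unname(random_map_sampler(ip1_model())$weights), rep(1 / 4, 4))
  # degenerate corner: only the ties-high map is ever drawn
  rm1 <- random_map_sampler(ip1_model(p = "1", q = "1"))
  expect_equal(unname(rm1$weights["11"]), 1)
  withr::with_seed(5, {
    draws <- vapply(1:20, function(i) rm1$step(1L), 0L)
    expect_true(all(draws == rm1$maps[["11"]][[2L]]))
  })
})
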