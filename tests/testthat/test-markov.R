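test_that("the mutual-activation matrix matches the per-node product law", {
  m <- ip1_model(p = "1/2", q = "1/2")
  tmat <- as_matrix(transition_model(m))
  # brute-force oracle: enumerate joint outcomes per row directly from the
  # per-node distributions
  oracle <- matrix(0, 4, 4)
  for (ix in 0:3) {
    values <- index_to_state(ix, 2, "spin")
    ph <- next_value_distribution(m, values)$prob_high
    for (o in 0:3) {
      bits <- c(o %/% 2, o %% 2)
      oracle[ix + 1, o + 1] <- prod(ifelse(bits == 1, ph, 1 - ph))
    }
  }
  expect_equal(unname(tmat), oracle)
  # row of (+,+) is a point mass on itself; rows of the two tied states are
  # uniform at p = q = 1/2
  expect_equal(unname(tmat["++", ]), c(0, 0, 0, 1))
  expect_equal(unname(tmat["+-", ]), rep(1 / 4, 4))
})

test_that("all 16 models x 4 rules x parameter points are row-stochastic exactly", {
  pts <- list(c("1/3", "2/3"), c("1/2", "1/2"), c("2/7", "5/9"),
              c("1/5", "4/5"), c("9/10", "1/10"))
  for (rule in c("MR", "IMR", "NMR", "INMR")) {
    for (pt in pts) {
      for (m1 in names(MODS)) for (m2 in names(MODS)) {
        tm <- transition_model(model_of(m1, m2, p = pt[1], q = pt[2], rule = rule))
        expect_true(tm$exact)
        expect_rows_sum_to_one(tm)
      }
    }
  }
})

test_that("IP models have 10 support transitions and OP models 8", {
  models <- enumerate_two_node_models("MR") # generic p = 1/3, q = 2/3
  n_arcs <- vapply(models$net, function(net) {
    igraph::ecount(support_digraph(transition_model(net), generic = TRUE))
  }, 0)
  phase <- vapply(models$net, model_phase, "")
  expect_equal(sort(unname(n_arcs[phase == "IP"])), rep(10, 8))
  expect_equal(sort(unname(n_arcs[phase == "OP"])), rep(8, 8))
})

test_that("generic support is refused at extreme tie probabilities", {
  tm <- transition_model(ip1_model(p = "1", q = "1/2"))
  expect_error(support_digraph(tm, generic = TRUE), "extreme")
  g <- support_digraph(transition_model(ip1_model()), generic = TRUE)
  expect_s3_class(g, "igraph")
})

test_that("class dynamics: IP1 two fixed points, IP2 a 2-cycle, IP3/OP regular", {
  es1 <- ergodic_sets(transition_model(ip1_model(p = "1/3", q = "2/3")))
  expect_equal(nrow(es1), 2L)
  expect_true(all(es1$type == "fixed_point"))
  expect_setequal(unlist(es1$states), c("--", "++"))

  es2 <- ergodic_sets(transition_model(ip2_model()))
  expect_equal(nrow(es2), 1L)
  expect_equal(es2$type, "deterministic_cycle")
  expect_equal(es2$period, 2L)

  tm3 <- transition_model(ip3_model())
  es3 <- ergodic_sets(tm3)
  expect_equal(nrow(es3), 1L)
  expect_equal(es3$size, 4L)
  expect_equal(classify_chain(tm3), "regular")

  expect_equal(classify_chain(transition_model(ip1_model(p = "1/3", q = "2/3"))),
               "absorbing_extended")
  expect_equal(classify_chain(transition_model(ip2_model())),
               "absorbing_extended")
  for (op in list(op1_model(p = "1/3", q = "2/3"), op2_model(),
                  model_of("a", "c"), model_of("b", "d"))) {
    expect_equal(classify_chain(transition_model(op)), "regular")
  }
})

test_that("a single-state chain classifies as absorbing", {
  net <- grn(tibble::tibble(source = "A", target = "B", sign = 1L),
             nodes = c("A", "B"), clamped = c(A = 1L, B = 1L))
  tm <- transition_model(net)
  expect_equal(tm$n_states, 1L)
  expect_equal(classify_chain(tm), "absorbing_extended")
})

test_that("the fundamental matrix solves (I - Q) N = I exactly", {
  tm <- transition_model(ip1_model(p = "1/2", q = "1/2"))
  n <- fundamental_matrix(tm)
  expect_equal(unname(n[, ]), matrix(c(3 / 2, 1 / 2, 1 / 2, 3 / 2), 2, 2))
  expect_equal(unname(rowSums(n)), c(2, 2))
  # exact residual check: N (I - Q) = I in rational arithmetic
  n_exact <- attr(n, "exact")
  tmat <- as_matrix(tm, exact = TRUE)
  tr_ix <- match(rownames(n), tm$states)
  q <- ratmat(tmat$num[tr_ix, tr_ix], tmat$den[tr_ix, tr_ix])
  iq <- ratmat_sub(ratmat_identity(2L), q)
  expect_true(ratmat_equal(ratmat_mul(n_exact, iq), ratmat_identity(2L)))
  # generic parameters: exact residual again, values against a double solve
  tm2 <- transition_model(ip1_model(p = "1/3", q = "2/3"))
  n2 <- fundamental_matrix(tm2)
  tmat2 <- as_matrix(tm2)
  tr2 <- match(rownames(n2), tm2$states)
  expect_equal(unname(n2[, ]),
               unname(solve(diag(2) - tmat2[tr2, tr2])),
               tolerance = 1e-12)
})

test_that("Q = 0 gives N = I", {
  # B's only regulator is a clamped activator: the transient state jumps
  # straight into the absorbing one
  net <- grn(tibble::tibble(source = "A", target = "B", sign = 1L),
             nodes = c("A", "B"), clamped = c(A = 1L))
  tm <- transition_model(net)
  n <- fundamental_matrix(tm)
  expect_equal(unname(n[, , drop = FALSE]), matrix(1))
})

test_that("fundamental matrix is refused on non-absorbing chains", {
  expect_error(fundamental_matrix(transition_model(ip3_model())), "absorbing")
})

test_that("absorption probabilities are row-stochastic and symmetric for IP1", {
  tm <- transition_model(ip1_model(p = "1/2", q = "1/2"))
  b <- absorption_probabilities(tm)
  expect_equal(unname(rowSums(b)), c(1, 1))
  expect_equal(unname(b["+-", ]), c(1 / 2, 1 / 2))
})

test_that("stationary distributions give mean return times 1/pi", {
  # OP1 at p = q = 1/2: uniform, all mean return times 4
  st <- stationary_distribution(transition_model(op1_model()))
  expect_equal(st$pi, rep(1 / 4, 4))
  expect_equal(st$mean_return, rep(4, 4))
  expect_true(all(st$pi_exact == "1/4"))
  # a deterministic 4-cycle has mean return time 4 exactly
  cyc <- grn(tibble::tibble(source = c("n1", "n2"), target = c("n2", "n1"),
                            sign = c(1L, -1L)), nodes = c("n1", "n2"))
  st2 <- stationary_distribution(transition_model(cyc), set_id = 1L)
  expect_equal(st2$mean_return, rep(4, 4))
  # pi sums to one and m = 1/pi on a generic regular model
  st3 <- stationary_distribution(transition_model(ip3_model()))
  expect_true(frac_eq(Reduce(frac_add,
                             lapply(strsplit(st3$pi_exact, "/"), function(p) {
                               frac(as.numeric(p[1]),
                                    if (length(p) > 1) as.numeric(p[2]) else 1)
                             })), frac(1)))
  expect_equal(st3$mean_return * st3$pi, rep(1, 4))
})

test_that("IP3 deterministic transitions weight their targets' return times", {
  # each deterministic transition r -> t(r) puts extra stationary weight on
  # its target: the mean return time to the source r is always larger than
  # the mean return time to its target, across a parameter grid
  grid <- c("1/5", "2/5", "1/2", "3/5", "4/5")
  for (pv in grid) for (qv in grid) {
    tm <- transition_model(ip3_model(p = pv, q = qv))
    tmat <- as_matrix(tm)
    st <- stationary_distribution(tm)
    mr <- stats::setNames(st$mean_return, st$state)
    det_rows <- rownames(tmat)[apply(tmat, 1, function(r) any(r == 1))]
    expect_equal(length(det_rows), 2L)
    for (r in det_rows) {
      target <- colnames(tmat)[tmat[r, ] == 1]
      expect_gt(mr[[r]], mr[[target]])
    }
  }
})

test_that("conjugating T by the global flip with p -> 1-p leaves MR invariant", {
  for (mods in list(c("a", "d"), c("c", "b"), c("a", "a"))) {
    tm <- transition_model(model_of(mods[1], mods[2], p = "2/7", q = "3/5"))
    tm_m <- transition_model(model_of(mods[1], mods[2], p = "5/7", q = "2/5"))
    flip <- vapply(tm$states, function(s) {
      chartr("+-", "-+", s)
    }, "")
    perm <- match(flip, tm$states)
    a <- as_matrix(tm)
    b <- as_matrix(tm_m)[perm, perm]
    expect_equal(unname(a), unname(b), tolerance = 1e-12)
  }
})

test_that("chain analysis bundles tidy and glance views", {
  ca <- chain_analysis(ip1_model(p = "1/2", q = "1/2"))
  expect_s3_class(ca, "grn_chain")
  td <- tidy(ca)
  expect_equal(nrow(td), 4L)
  expect_equal(sum(td$role == "transient"), 2L)
  g <- glance(ca)
  expect_equal(g$classification, "absorbing_extended")
  expect_equal(g$n_fixed_points, 2L)
  p <- autoplot(ca)
  expect_s3_class(p, "ggplot")
  ca2 <- chain_analysis(ip3_model())
  expect_s3_class(autoplot(ca2), "ggplot")
  expect_equal(glance(ca2)$classification, "regular")
})

test_that("transition models export to CSV and DOT", {
  tm <- transition_model(ip1_model(p = "1/2", q = "1/2"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_transition_csv(tm, csv)
  m <- utils::read.csv(csv, row.names = 1, check.names = FALSE)
  expect_equal(unname(as.matrix(m)), unname(as_matrix(tm)))
  dot <- withr::local_tempfile(fileext = ".dot")
  write_transition_dot(tm, dot)
  lines <- readLines(dot)
  expect_equal(length(grep("->", lines)), nrow(tm$transitions))
  expect_true(any(grepl("1/4", lines)))
})
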