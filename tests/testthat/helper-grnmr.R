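# Shared builders for the test suite. All fixtures are constructed in code.

# internal exact-fraction helpers, aliased for brevity
frac <- grnmr:::frac
frac_add <- grnmr:::frac_add
frac_eq <- grnmr:::frac_eq
frac_num <- grnmr:::frac_num
ratmat_equal <- grnmr:::ratmat_equal
ratmat_mul <- grnmr:::ratmat_mul
ratmat_sub <- grnmr:::ratmat_sub
ratmat_identity <- grnmr:::ratmat_identity
ratmat <- grnmr:::ratmat

# the four modules by family: self/cross sign pairs
MODS <- list(a = c("+", "+"), b = c("+", "-"), c = c("-", "+"), d = c("-", "-"))

model_of <- function(m1, m2, p = "1/3", q = "2/3", rule = "MR") {
  two_node_model(MODS[[m1]][1], MODS[[m1]][2], MODS[[m2]][1], MODS[[m2]][2],
                 p = p, q = q, rule = rule)
}

ip1_model <- function(p = "1/2", q = "1/2", rule = "MR") model_of("a", "a", p, q, rule)
ip2_model <- function(p = "1/3", q = "2/3") model_of("c", "c", p, q)
ip3_model <- function(p = "1/3", q = "2/3") model_of("a", "d", p, q)
op1_model <- function(p = "1/2", q = "1/2") model_of("a", "b", p, q)
op2_model <- function(p = "1/3", q = "2/3") model_of("c", "d", p, q)

# exact row-stochasticity check on a transition model
expect_rows_sum_to_one <- function(tm) {
  tr <- tm$transitions
  for (s in unique(tr$from)) {
    rows <- tr[tr$from == s, ]
    total <- frac(0)
    for (i in seq_len(nrow(rows))) {
      total <- frac_add(total, frac(rows$num[[i]], rows$den[[i]]))
    }
    expect_true(frac_eq(total, frac(1)))
  }
}

# restrict a steady_configurations result to a core candidate
steady_restricted_to <- function(steady, net, candidate) {
  core <- grnmr:::deterministic_nodes(net)
  pos <- match(core, net$nodes)
  keep <- vapply(steady$configuration, function(cf) {
    bits <- strsplit(cf, "")[[1]][pos]
    identical(paste(bits, collapse = ""), candidate)
  }, TRUE)
  steady[keep, ]
}
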