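# Exact fraction arithmetic on integer-valued doubles.
#
# Probabilities in this package are products and sums of per-node tie factors
# p_i / (1 - p_i). When the tie probabilities are supplied as exact fractions
# ("1/3", "1/2"), every transition probability is a rational number whose
# numerator and denominator stay far below 2^53, so plain doubles holding
# integers give exact arithmetic. Values are kept reduced (gcd = 1, den > 0);
# a fraction with den = NA marks an inexact (double) value and poisons
# exactness downstream.

frac_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' @noRd
frac <- function(num, den = 1) {
  stopifnot(length(num) == length(den) || length(den) == 1L)
  den <- rep_len(den, length(num))
  out <- list(num = as.double(num), den = as.double(den))
  class(out) <- "frac"
  frac_reduce(out)
}

frac_reduce <- function(x) {
  # a non-integer numerator or denominator cannot be handled exactly
  odd <- !is.na(x$den) & (x$num != round(x$num) | x$den != round(x$den))
  if (any(odd)) {
    x$num[odd] <- x$num[odd] / x$den[odd]
    x$den[odd] <- NA_real_
  }
  bad <- is.na(x$den) | is.na(x$num)
  neg <- !bad & x$den < 0
  x$num[neg] <- -x$num[neg]
  x$den[neg] <- -x$den[neg]
  nz <- !bad & x$num != 0
  if (any(nz)) {
    g <- mapply(frac_gcd, x$num[nz], x$den[nz])
    x$num[nz] <- x$num[nz] / g
    x$den[nz] <- x$den[nz] / g
  }
  z <- !bad & x$num == 0
  x$den[z] <- 1
  # overflow guard: fall back to inexact values
  over <- !bad & (abs(x$num) > 2^52 | x$den > 2^52)
  if (any(over)) {
    v <- x$num[over] / x$den[over]
    x$num[over] <- v
    x$den[over] <- NA_real_
  }
  x
}

frac_is_exact <- function(x) !is.na(x$den)

#' Parse tie probabilities given as numbers or fraction strings
#'
#' Accepts numerics (exact when they equal a fraction with denominator
#' up to 1024, e.g. 0.5, 0.25) and strings such as `"1/3"` (always exact).
#' @noRd
frac_parse <- function(x) {
  if (inherits(x, "frac")) return(x)
  if (is.character(x)) {
    has_slash <- grepl("/", x, fixed = TRUE)
    if (all(has_slash)) {
      parts <- strsplit(x, "/", fixed = TRUE)
      num <- vapply(parts, function(p) as.double(p[[1]]), 0)
      den <- vapply(parts, function(p) as.double(p[[2]]), 0)
      return(frac(num, den))
    }
    if (any(has_slash)) { # mixed: handle elementwise
      out <- lapply(x, frac_parse)
      return(do.call(frac_c, out))
    }
    x <- as.double(x) # decimal strings go through the small-fraction matcher
  }
  x <- as.double(x)
  num <- den <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    if (is.na(x[[i]])) next
    hit <- FALSE
    for (d in 1:1024) {
      n <- x[[i]] * d
      if (n == round(n)) { # exact in double arithmetic
        num[i] <- n; den[i] <- d; hit <- TRUE; break
      }
    }
    if (!hit) { num[i] <- x[[i]]; den[i] <- NA_real_ }
  }
  frac(num, ifelse(is.na(den), NA_real_, den))
}

frac_len <- function(x) length(x$num)

frac_idx <- function(x, i) frac(x$num[i], x$den[i])

frac_c <- function(...) {
  xs <- list(...)
  frac(unlist(lapply(xs, `[[`, "num")), unlist(lapply(xs, `[[`, "den")))
}

frac_num <- function(x) ifelse(is.na(x$den), x$num, x$num / x$den)

frac_bin <- function(a, b, op) {
  if (!inherits(a, "frac")) a <- frac_parse(a)
  if (!inherits(b, "frac")) b <- frac_parse(b)
  n <- max(frac_len(a), frac_len(b))
  an <- rep_len(a$num, n); ad <- rep_len(a$den, n)
  bn <- rep_len(b$num, n); bd <- rep_len(b$den, n)
  inex <- is.na(ad) | is.na(bd)
  av <- ifelse(is.na(ad), an, an / ad)
  bv <- ifelse(is.na(bd), bn, bn / bd)
  num <- den <- numeric(n)
  switch(op,
    "+" = { num <- an * bd + bn * ad; den <- ad * bd },
    "-" = { num <- an * bd - bn * ad; den <- ad * bd },
    "*" = { num <- an * bn; den <- ad * bd },
    "/" = { num <- an * bd; den <- ad * bn }
  )
  if (any(inex)) {
    v <- switch(op, "+" = av + bv, "-" = av - bv, "*" = av * bv, "/" = av / bv)
    num[inex] <- v[inex]
    den[inex] <- NA_real_
  }
  frac(num, den)
}

frac_add <- function(a, b) frac_bin(a, b, "+")
frac_sub <- function(a, b) frac_bin(a, b, "-")
frac_mul <- function(a, b) frac_bin(a, b, "*")
frac_div <- function(a, b) frac_bin(a, b, "/")
frac_one_minus <- function(a) frac_sub(frac(1), a)

frac_eq <- function(a, b) {
  d <- frac_bin(a, b, "-")
  ifelse(is.na(d$den), abs(d$num) < 1e-12, d$num == 0)
}

frac_prod <- function(x) {
  out <- frac(1)
  for (i in seq_len(frac_len(x))) out <- frac_mul(out, frac_idx(x, i))
  out
}

frac_sum <- function(x) {
  out <- frac(0)
  for (i in seq_len(frac_len(x))) out <- frac_add(out, frac_idx(x, i))
  out
}

frac_format <- function(x) {
  ifelse(is.na(x$den), formatC(x$num, digits = 15, format = "g"),
         ifelse(x$den == 1, formatC(x$num, format = "d", flag = ""),
                paste0(x$num, "/", x$den)))
}

#' @export
format.frac <- function(x, ...) frac_format(x)

#' @export
print.frac <- function(x, ...) {
  cat("<frac> ", paste(frac_format(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

# ---- dense rational matrices ------------------------------------------------
# Stored as a pair of plain matrices (num, den). Only used for small systems
# (two-node chains, transient blocks); larger problems use doubles via Matrix.

ratmat <- function(num, den = NULL) {
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  structure(list(num = num, den = den), class = "ratmat")
}

ratmat_identity <- function(n) ratmat(diag(1, nrow = n))

ratmat_get <- function(m, i, j) frac(m$num[i, j], m$den[i, j])

ratmat_set <- function(m, i, j, x) {
  m$num[i, j] <- x$num
  m$den[i, j] <- x$den
  m
}

ratmat_from_frac <- function(x, nrow, ncol) {
  ratmat(matrix(x$num, nrow, ncol), matrix(x$den, nrow, ncol))
}

ratmat_numeric <- function(m) {
  out <- m$num / m$den
  out[is.na(m$den)] <- m$num[is.na(m$den)]
  out
}

ratmat_elementwise <- function(a, b, op) {
  x <- frac_bin(frac(as.vector(a$num), as.vector(a$den)),
                frac(as.vector(b$num), as.vector(b$den)), op)
  ratmat(matrix(x$num, nrow(a$num)), matrix(x$den, nrow(a$num)))
}

ratmat_sub <- function(a, b) ratmat_elementwise(a, b, "-")

ratmat_mul <- function(a, b) {
  n <- nrow(a$num); k <- ncol(a$num); p <- ncol(b$num)
  stopifnot(k == nrow(b$num))
  out <- ratmat(matrix(0, n, p))
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      acc <- frac(0)
      for (l in seq_len(k)) {
        acc <- frac_add(acc, frac_mul(ratmat_get(a, i, l), ratmat_get(b, l, j)))
      }
      out <- ratmat_set(out, i, j, acc)
    }
  }
  out
}

# Gauss-Jordan solve A X = B in exact rationals (partial pivot on first
# nonzero entry; exactness makes pivot magnitude irrelevant).
ratmat_solve <- function(a, b = NULL) {
  n <- nrow(a$num)
  if (is.null(b)) b <- ratmat_identity(n)
  for (col in seq_len(n)) {
    nz <- vapply(col:n, function(r) !frac_eq(ratmat_get(a, r, col), frac(0)), TRUE)
    if (!any(nz)) stop("singular rational matrix", call. = FALSE)
    piv <- (col:n)[nz][[1L]]
    if (piv != col) {
      a$num[c(col, piv), ] <- a$num[c(piv, col), ]
      a$den[c(col, piv), ] <- a$den[c(piv, col), ]
      b$num[c(col, piv), ] <- b$num[c(piv, col), ]
      b$den[c(col, piv), ] <- b$den[c(piv, col), ]
    }
    pv <- ratmat_get(a, col, col)
    for (j in seq_len(n)) {
      a <- ratmat_set(a, col, j, frac_div(ratmat_get(a, col, j), pv))
      b <- ratmat_set(b, col, j, frac_div(ratmat_get(b, col, j), pv))
    }
    for (r in seq_len(n)) {
      if (r == col) next
      f <- ratmat_get(a, r, col)
      if (frac_eq(f, frac(0))) next
      for (j in seq_len(n)) {
        a <- ratmat_set(a, r, j,
                        frac_sub(ratmat_get(a, r, j), frac_mul(f, ratmat_get(a, col, j))))
        b <- ratmat_set(b, r, j,
                        frac_sub(ratmat_get(b, r, j), frac_mul(f, ratmat_get(b, col, j))))
      }
    }
  }
  b
}

ratmat_equal <- function(a, b) {
  all(frac_eq(frac(as.vector(a$num), as.vector(a$den)),
              frac(as.vector(b$num), as.vector(b$den))))
}

ratmat_power <- function(a, k) {
  out <- ratmat_identity(nrow(a$num))
  for (i in seq_len(k)) out <- ratmat_mul(out, a)
  out
}
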