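# Independent reference implementations used to cross-check the package.

# brute-force bond-vector set: closure of the base classes under axis
# permutation and sign inversion, built with expand.grid rather than the
# package's loop
oracle_bond_set <- function() {
  base <- list(c(2, 0, 0), c(2, 1, 0), c(2, 1, 1), c(2, 2, 1),
               c(3, 0, 0), c(3, 1, 0))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
  vecs <- character()
  for (b in base) for (p in perms) for (k in seq_len(nrow(signs)))
    vecs <- c(vecs, paste(b[p] * unlist(signs[k, ]), collapse = ","))
  unique(vecs)
}

# two axis-aligned 2x2x2 cubes (corners a, b) overlap iff every coordinate
# of the corner difference has magnitude <= 1
oracle_cubes_disjoint <- function(a, b) any(abs(a - b) > 1)

# brute-force conformation check, independent of dl_validate_conformation
oracle_conf_valid <- function(pos, allowed_keys) {
  n <- nrow(pos)
  if (n >= 2) {
    d <- pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE]
    if (!all(paste(d[, 1], d[, 2], d[, 3], sep = ",") %in% allowed_keys))
      return(FALSE)
  }
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (!oracle_cubes_disjoint(pos[i, ], pos[j, ])) return(FALSE)
  }
  TRUE
}

# AR(1) series with known integrated autocorrelation time (1+phi)/(2(1-phi))
oracle_ar1 <- function(n, phi, seed) {
  set.seed(seed)
  as.numeric(stats::filter(rnorm(n), phi, method = "recursive"))
}
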