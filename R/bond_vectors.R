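#' Allowed bond vectors of the bond-fluctuation model
#'
#' Returns the 108-element bond-vector set generated by closing the base
#' classes (2,0,0), (2,1,0), (2,1,1), (2,2,1), (3,0,0), (3,1,0) under all axis
#' permutations and sign inversions.  The admissible bond lengths are
#' 2, sqrt(5), sqrt(6), 3 and sqrt(10) lattice units; together with the
#' excluded-volume rule and single-site moves this set makes bond crossing
#' impossible, so the topological state of a conformation is preserved.
#'
#' @return An integer matrix with 108 rows (one bond vector per row) and
#'   columns `x`, `y`, `z`, of class `dl_bond_set`.
#' @examples
#' bv <- dl_allowed_bond_vectors()
#' nrow(bv)                    # 108
#' sort(unique(rowSums(bv^2))) # 4 5 6 9 10
#' @export
dl_allowed_bond_vectors <- function() {
  base <- rbind(c(2, 0, 0), c(2, 1, 0), c(2, 1, 1),
                c(2, 2, 1), c(3, 0, 0), c(3, 1, 0))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- matrix(0L, 0L, 3L)
  for (k in seq_len(nrow(base)))
    for (p in seq_len(nrow(perms)))
      for (s in seq_len(nrow(signs)))
        out <- rbind(out, as.integer(base[k, perms[p, ]] * signs[s, ]))
  out <- unique(out)
  colnames(out) <- c("x", "y", "z")
  class(out) <- c("dl_bond_set", class(out))
  out
}

#' Test bond vectors for membership in the allowed set
#'
#' @param v An integer 3-vector, or a matrix with one bond vector per row.
#' @return Logical vector, one entry per bond.
#' @examples
#' dl_bond_allowed(c(2, 0, 0))  # TRUE
#' dl_bond_allowed(c(2, 2, 2))  # FALSE
#' @export
dl_bond_allowed <- function(v) {
  if (is.null(dim(v))) v <- matrix(as.integer(v), nrow = 1L)
  storage.mode(v) <- "integer"
  if (ncol(v) != 3L) stop("bond vectors must have 3 components")
  cpp_bond_allowed(v)
}

#' @export
print.dl_bond_set <- function(x, ...) {
  cat("Bond-fluctuation-model bond-vector set:", nrow(x), "vectors\n")
  cat("squared lengths:", paste(sort(unique(rowSums(unclass(x)^2))), collapse = ", "), "\n")
  invisible(x)
}
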