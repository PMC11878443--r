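#' Proper rotation operators of a crystallographic point group
#'
#' Returns the finite set of rotational (proper) symmetry operations of a
#' point group, expressed as integer matrices acting on the crystal basis:
#' if the columns of an orientation matrix `M` are the cell vectors a, b, c,
#' then `M %*% S` is the symmetry-equivalent indexing choice under operator
#' `S`. Only proper rotations are returned -- improper operations invert
#' chirality and cannot relate alternative indexing settings of a chiral
#' lattice. The identity is always element 1.
#'
#' Supported symbols are the 11 proper (rotation-only) point groups:
#' `"1"`, `"2"`, `"3"`, `"4"`, `"6"`, `"222"`, `"32"`, `"422"`, `"622"`,
#' `"23"`, `"432"`. Trigonal/hexagonal groups use the hexagonal setting
#' (3- or 6-fold about c; for `"32"` the 2-fold along a).
#'
#' @param symbol Hermann-Mauguin rotational point-group symbol (character).
#' @return list of 3x3 integer matrices, closed under multiplication.
#' @export
point_group_rotations <- function(symbol) {
  sym <- gsub("[[:space:]]", "", as.character(symbol))
  gens <- pg_generators(sym)
  if (is.null(gens)) {
    stop(sprintf("unknown or non-rotational point-group symbol: '%s' (supported: %s)",
                 symbol, paste(names(.pg_table), collapse = ", ")))
  }
  group_closure(gens)
}

# integer generator matrices in the crystal basis (columns = images of a,b,c)
.pg_table <- local({
  two_c <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3)
  two_b <- matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), 3, 3)
  two_a <- matrix(c(1, 0, 0, 0, -1, 0, 0, 0, -1), 3, 3)
  four_c <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)      # a->b, b->-a
  three_c_hex <- matrix(c(0, 1, 0, -1, -1, 0, 0, 0, 1), 3, 3) # a->b, b->-a-b
  six_c_hex <- matrix(c(1, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)    # a->a+b, b->-a
  two_a_hex <- matrix(c(1, 0, 0, -1, -1, 0, 0, 0, -1), 3, 3)  # 2-fold along a, hex setting
  three_111 <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3)     # a->b->c->a
  list(
    "1"   = list(diag(3)),
    "2"   = list(two_b),
    "3"   = list(three_c_hex),
    "4"   = list(four_c),
    "6"   = list(six_c_hex),
    "222" = list(two_c, two_a),
    "32"  = list(three_c_hex, two_a_hex),
    "422" = list(four_c, two_a),
    "622" = list(six_c_hex, two_a_hex),
    "23"  = list(two_c, three_111),
    "432" = list(four_c, three_111)
  )
})

pg_generators <- function(sym) .pg_table[[sym]]

# closure of a generator set under matrix multiplication (finite groups only)
group_closure <- function(gens, max_order = 64) {
  key <- function(m) paste(as.integer(round(m)), collapse = ",")
  ops <- list(diag(3))
  seen <- key(diag(3))
  queue <- gens
  while (length(queue) > 0) {
    m <- queue[[1]]; queue <- queue[-1]
    k <- key(m)
    if (k %in% seen) next
    ops <- c(ops, list(matrix(as.numeric(round(m)), 3, 3)))
    seen <- c(seen, k)
    if (length(ops) > max_order) stop("group closure did not terminate")
    for (o in ops) {
      queue <- c(queue, list(m %*% o), list(o %*% m))
    }
  }
  ops
}
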