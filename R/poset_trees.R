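# 2-d poset trees, order trees, linear-extension counting, and the
# edge/subtree switching machinery that underlies the 2^(n(n-1)/2) census.
#
# Each cycle i >= 2 lands between two pre-existing folds (or a structure end,
# node 0); an edge pair records the position inequality.  The major edge
# comes from the larger-labelled bound, the minor edge from the smaller.  A
# node is "plain" when the kept word prefix ends with the smaller bounding
# label, "flipped" when it ends with the larger; the chaining rule (a major
# child of a plain node inherits its minor parent, of a flipped node its
# major parent) is what makes subtree switching work.

#' Build the 2-d poset tree of a fold sequence
#'
#' Nodes are cycles `1..n` plus the root 0 (the structure ends, position 0).
#' Node i's major and minor parents are the labels bounding the segment its
#' fold lands on; the flip flag records whether the kept word prefix ends
#' with the larger (`flipped`) or smaller (`plain`) bounding label.
#'
#' @param r a fold sequence (full or reduced).
#' @return A list of class `"poset_tree"` with integer vectors `major`,
#'   `minor` (parent labels, 0 = root) and logical `flipped`, each indexed by
#'   cycle; node 1 hangs from the root alone and is plain.
#' @examples
#' build_poset_tree(c(1, 1, 2, 2, 1))
#' @export
build_poset_tree <- function(r) {
  assert_fold_sequence(r)
  n <- length(r)
  s <- cumsum(r)
  words <- word_evolution(r)
  major <- integer(n); minor <- integer(n); flipped <- logical(n)
  major[1L] <- 0L; minor[1L] <- 0L; flipped[1L] <- FALSE
  for (i in seq_len(n)[-1L]) {
    Wp <- words[[i - 1L]]
    K <- length(Wp)
    letter <- function(j) if (j < 1L || j > K) 0L else Wp[j]
    p <- letter(s[i] - 1L)  # last kept symbol (0 = inserting at the start)
    q <- letter(s[i])
    major[i] <- max(p, q)
    minor[i] <- min(p, q)
    flipped[i] <- p > q
  }
  structure(list(n = n, major = major, minor = minor, flipped = flipped),
            class = "poset_tree")
}

#' @export
print.poset_tree <- function(x, ...) {
  cat(sprintf("2-d poset tree on %d cycles\n", x$n))
  for (i in seq_len(x$n)) {
    cat(sprintf("  node %d: major %d, minor %d, %s\n", i, x$major[i],
                x$minor[i], if (x$flipped[i]) "flipped" else "plain"))
  }
  invisible(x)
}

# Audit the chaining rule on a constructed tree: a node whose major parent m
# (>= 2) is plain must have minor parent = m's minor parent; if m is flipped,
# = m's major parent.  Children of node 1 have minor parent 0.
check_poset_chaining <- function(p) {
  for (i in seq_len(p$n)[-1L]) {
    m <- p$major[i]
    expect <- if (m <= 1L) 0L else if (p$flipped[m]) p$major[m] else p$minor[m]
    if (p$minor[i] != expect) return(FALSE)
  }
  TRUE
}

#' Order tree (major-edge skeleton) of a 2-d poset tree
#'
#' Dropping the minor edges leaves an ordinary rooted tree: nodes on one
#' root path carry totally ordered breakpoint positions, nodes on distinct
#' branches are incomparable.
#'
#' @param p a `"poset_tree"` (or a fold sequence, which is converted first).
#' @return A list of class `"order_tree"`: `parent` is an integer vector over
#'   nodes `1..N` (node 1 = root, `parent[1] = 0`), `labels` maps nodes back
#'   to cycle labels (root = 0, extra roots introduced by subtree switching
#'   are `NA`).
#' @examples
#' order_tree(build_poset_tree(c(1, 1, 2, 2, 1)))
#' @export
order_tree <- function(p) {
  if (!inherits(p, "poset_tree")) p <- build_poset_tree(p)
  n <- p$n
  parent <- c(0L, p$major + 1L)  # node j = cycle j - 1; root node 1 = cycle 0
  structure(list(parent = parent, labels = c(0L, seq_len(n))),
            class = "order_tree")
}

#' @export
print.order_tree <- function(x, ...) {
  cat(sprintf("order tree on %d nodes (root + %d)\n",
              length(x$parent), length(x$parent) - 1L))
  invisible(x)
}

# Subtree sizes (self-inclusive) for every node of a parent-vector tree.
tree_subtree_sizes <- function(parent) {
  N <- length(parent)
  size <- rep(1L, N)
  depth <- integer(N)
  for (i in seq_len(N)) {
    j <- i; d <- 0L
    while (parent[j] != 0L) { j <- parent[j]; d <- d + 1L }
    depth[i] <- d
  }
  for (i in order(depth, decreasing = TRUE)) {
    if (parent[i] != 0L) size[parent[i]] <- size[parent[i]] + size[i]
  }
  size
}

#' Count the linear extensions of an order tree
#'
#' Evaluates `Phi(T) = n! / prod_b m_b`, where the product runs over the
#' non-root nodes and `m_b` is the size of the subtree rooted at `b`.  This
#' equals the number of breakpoint-position orders compatible with the fold
#' partial order.
#'
#' @param t an `"order_tree"`, a `"poset_tree"`, or a fold sequence.
#' @return An exact integer count (as numeric; an error is raised if the
#'   count would exceed the exactly-representable double range).
#' @examples
#' count_orders(c(1, 1, 2, 2, 1))  # 4
#' @export
count_orders <- function(t) {
  if (!inherits(t, "order_tree")) t <- order_tree(t)
  parent <- t$parent
  n <- length(parent) - 1L
  if (n == 0L) return(1)
  if (n > 18L) stop("exact factorial counts beyond n = 18 exceed double precision")
  sizes <- tree_subtree_sizes(parent)[-1L]  # drop the root
  phi <- factorial(n) / prod(sizes)
  stopifnot(abs(phi - round(phi)) < 1e-6)
  round(phi)
}

# Directed predecessor sets of the fold-position poset: preds[[i]] = folds
# whose positions must be smaller than fold i's.
poset_predecessors <- function(r) {
  n <- length(r)
  bounds <- fold_bounds(r)
  preds <- rep(list(integer(0)), n)
  for (i in seq_len(n)[-1L]) {
    lo <- bounds[[i]][["lo"]]; hi <- bounds[[i]][["hi"]]
    if (lo >= 1L) preds[[i]] <- c(preds[[i]], lo)
    if (hi >= 1L) preds[[hi]] <- c(preds[[hi]], i)
  }
  preds
}

#' Enumerate all rank orders compatible with a fold sequence
#'
#' Generates every linear extension of the breakpoint-position partial order
#' and reports each as a rank vector (rank 1 = outermost fold).  The number
#' of rows always equals [count_orders()].
#'
#' @param r a fold sequence (full or reduced; the poset is taken on all its
#'   cycles).
#' @return An integer matrix, one row per order, column i = rank of fold i.
#' @examples
#' enumerate_orders(c(1, 1, 2))       # two orders
#' nrow(enumerate_orders(c(1, 1, 2, 2, 1)))  # 4
#' @export
enumerate_orders <- function(r) {
  assert_fold_sequence(r)
  n <- length(r)
  preds <- poset_predecessors(r)
  res <- list()
  asc <- integer(n)
  placed <- logical(n)
  rec <- function(depth) {
    if (depth > n) {
      res[[length(res) + 1L]] <<- asc
      return(invisible(NULL))
    }
    for (i in seq_len(n)[!placed]) {
      if (all(placed[preds[[i]]])) {
        placed[i] <<- TRUE; asc[depth] <<- i
        rec(depth + 1L)
        placed[i] <<- FALSE
      }
    }
  }
  rec(1L)
  out <- matrix(0L, nrow = length(res), ncol = n)
  for (j in seq_along(res)) {
    # asc lists folds from smallest to largest position; rank 1 = largest.
    out[j, res[[j]]] <- n:1
  }
  out
}

#' Root-containing subtrees of an order tree
#'
#' @param t an `"order_tree"` (or anything [order_tree()] accepts).
#' @return A list of integer vectors of cycle labels (each containing 0, the
#'   root), one per connected root-containing subtree.
#' @examples
#' length(root_subtrees(c(1, 1, 2, 2, 1)))  # 9
#' @export
root_subtrees <- function(t) {
  if (!inherits(t, "order_tree")) t <- order_tree(t)
  parent <- t$parent
  N <- length(parent)
  kids <- lapply(seq_len(N), function(i) which(parent == i))
  grow <- function(node) {
    # all subtrees rooted at `node` containing `node`
    opts <- list(integer(0))
    for (k in kids[[node]]) {
      sub <- grow(k)
      new <- list()
      for (o in opts) {
        new[[length(new) + 1L]] <- o
        for (s in sub) new[[length(new) + 1L]] <- c(o, s)
      }
      opts <- new
    }
    lapply(opts, function(o) c(node, o))
  }
  lapply(grow(1L), function(nodes) sort(t$labels[nodes]))
}

#' Subtree switching
#'
#' The tree operation behind the evolution census: introducing a new first
#' fold into an n-cycle evolution corresponds to choosing a root-containing
#' subtree `s` of its order tree and (i) switching every flipped major edge
#' inside `s` to its minor edge, (ii) switching every plain major edge
#' adjacent to `s` (parent in `s`, child outside), then (iii) prepending a
#' fresh root.  Summed over all choices of `s`, the extension counts satisfy
#' `sum_s Phi(T_s) = 2^n Phi(T)`.
#'
#' @param p a `"poset_tree"` (the flags and minor edges are needed).
#' @param s integer vector of cycle labels forming a connected subtree of the
#'   order tree that contains the root label 0.
#' @return The switched `"order_tree"` (with the fresh root as node 1).
#' @examples
#' p <- build_poset_tree(c(1, 1, 2, 2, 1))
#' sum(sapply(root_subtrees(p), function(s) count_orders(subtree_switch(p, s))))  # 128
#' @export
subtree_switch <- function(p, s) {
  if (!inherits(p, "poset_tree")) p <- build_poset_tree(p)
  s <- as.integer(s)
  if (!(0L %in% s)) stop("the subtree must contain the root (label 0)")
  n <- p$n
  if (any(s < 0L | s > n)) stop("subtree labels out of range")
  # connectivity in the order tree: every non-root member's major parent is a member
  for (i in setdiff(s, 0L)) {
    if (!(p$major[i] %in% s)) {
      stop("subtree is not connected to the root in the order tree")
    }
  }
  newpar <- p$major
  for (i in seq_len(n)) {
    m <- p$major[i]
    inside <- (i %in% s) && (m %in% s)
    adjacent <- (m %in% s) && !(i %in% s)
    if ((inside && p$flipped[i]) || (adjacent && !p$flipped[i])) {
      newpar[i] <- p$minor[i]
    }
  }
  # nodes: 1 = fresh root, 2 = old root (label 0), i + 2 = cycle i
  parent <- c(0L, 1L, newpar + 2L)
  structure(list(parent = parent, labels = c(NA_integer_, 0L, seq_len(n))),
            class = "order_tree")
}
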