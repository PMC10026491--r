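#' Define a two-biomarker subgroup grid
#'
#' A grid of `K` ordered levels of Biomarker1 by `J` ordered levels of
#' Biomarker2.  Subgroup `(k, j)` uses 1-based levels, and treatment efficacy
#' is assumed non-decreasing in each coordinate (marginal monotonicity), which
#' induces the product partial order on the `K * J` subgroups.
#'
#' @param K integer, number of Biomarker1 levels (>= 1).
#' @param J integer, number of Biomarker2 levels (>= 1).
#' @return An object of class `subgroup_grid` with elements `K` and `J`.
#' @examples
#' g <- subgroup_grid(3, 4)
#' g
#' @export
subgroup_grid <- function(K, J) {
  K <- as.integer(K); J <- as.integer(J)
  if (length(K) != 1L || length(J) != 1L || is.na(K) || is.na(J) ||
      K < 1L || J < 1L) {
    stop("K and J must be single integers >= 1", call. = FALSE)
  }
  structure(list(K = K, J = J), class = "subgroup_grid")
}

#' @export
print.subgroup_grid <- function(x, ...) {
  cat(sprintf("subgroup grid: %d x %d (%d subgroups)\n", x$K, x$J, x$K * x$J))
  invisible(x)
}

as_grid <- function(grid) {
  if (inherits(grid, "subgroup_grid")) return(grid)
  stop("expected a 'subgroup_grid' object", call. = FALSE)
}

# Normalise a high-efficacy set given as a logical K x J matrix or a
# two-column (k, j) index matrix into a logical K x J membership matrix.
high_set_matrix <- function(grid, high_set) {
  K <- grid$K; J <- grid$J
  if (is.logical(high_set) && is.matrix(high_set)) {
    if (!all(dim(high_set) == c(K, J))) {
      stop("logical high_set must be a K x J matrix", call. = FALSE)
    }
    return(high_set)
  }
  m <- matrix(FALSE, K, J)
  if (length(high_set) == 0L) return(m)
  idx <- as.matrix(high_set)
  if (ncol(idx) != 2L) stop("high_set must be a 2-column (k, j) matrix", call. = FALSE)
  if (any(idx[, 1] < 1 | idx[, 1] > K | idx[, 2] < 1 | idx[, 2] > J)) {
    stop("high_set indices out of grid bounds", call. = FALSE)
  }
  m[idx] <- TRUE
  m
}

#' Construct a subgroup division
#'
#' A division bipartitions the grid into a nonempty high-efficacy subset
#' (an up-set of the grid partial order) and its low-efficacy complement.
#'
#' @param grid a [subgroup_grid()].
#' @param high_set logical `K x J` membership matrix, or a two-column matrix
#'   of `(k, j)` indices of the high-efficacy subgroups.
#' @return An object of class `division` with elements `grid` and `high`
#'   (logical `K x J` matrix).
#' @examples
#' g <- subgroup_grid(2, 2)
#' division(g, rbind(c(2, 2)))
#' @export
division <- function(grid, high_set) {
  grid <- as_grid(grid)
  high <- high_set_matrix(grid, high_set)
  if (!is_up_set(high)) {
    stop("high_set must be a nonempty up-set of the grid", call. = FALSE)
  }
  new_division(grid, high)
}

new_division <- function(grid, high) {
  structure(list(grid = grid, high = high), class = "division")
}

# up-set check on a logical matrix: membership implies membership of the
# right and lower neighbours (transitively sufficient)
is_up_set <- function(high) {
  if (!any(high)) return(FALSE)
  K <- nrow(high); J <- ncol(high)
  if (K > 1L && any(high[-K, ] & !high[-1L, ])) return(FALSE)
  if (J > 1L && any(high[, -J] & !high[, -1L])) return(FALSE)
  TRUE
}

#' Validate a candidate high-efficacy set
#'
#' @inheritParams division
#' @return `TRUE` iff `high_set` is a nonempty up-set of the grid poset
#'   (i.e. a valid high-efficacy subset under marginal monotonicity).
#' @examples
#' g <- subgroup_grid(2, 2)
#' is_valid_division(g, rbind(c(2, 2)))  # TRUE
#' is_valid_division(g, rbind(c(1, 1)))  # FALSE: (2, 2) etc. missing
#' @export
is_valid_division <- function(grid, high_set) {
  grid <- as_grid(grid)
  is_up_set(high_set_matrix(grid, high_set))
}

#' @export
print.division <- function(x, ...) {
  cat(sprintf("division of %d x %d grid (%d high / %d low)\n",
              x$grid$K, x$grid$J, sum(x$high), sum(!x$high)))
  m <- matrix(as.integer(x$high), x$grid$K, x$grid$J,
              dimnames = list(paste0("k", seq_len(x$grid$K)),
                              paste0("j", seq_len(x$grid$J))))
  print(m)
  invisible(x)
}

#' High- and low-efficacy subgroup indices of a division
#'
#' @param x a [division()].
#' @return A two-column matrix of `(k, j)` indices, in row-major order.
#' @export
high_set <- function(x) {
  stopifnot(inherits(x, "division"))
  which(x$high, arr.ind = TRUE)[, c(1, 2), drop = FALSE]
}

#' @rdname high_set
#' @export
low_set <- function(x) {
  stopifnot(inherits(x, "division"))
  which(!x$high, arr.ind = TRUE)[, c(1, 2), drop = FALSE]
}

# canonical key of a division: row-major 0/1 string
division_key <- function(high) paste(as.integer(t(high)), collapse = "")

#' Enumerate all monotone subgroup divisions
#'
#' Deterministically enumerates every division of the grid whose
#' high-efficacy subset is a nonempty up-set.  An up-set of the `K x J`
#' product order is a column-suffix per row with non-decreasing suffix
#' lengths down the rows, so the count is `choose(K + J, K) - 1`.
#'
#' Divisions are returned in lexicographic order of the row-major membership
#' mask; the full-population division (all subgroups high-efficacy) is always
#' last.
#'
#' @param grid a [subgroup_grid()].
#' @return A list of [division()] objects of class `division_list`.
#' @examples
#' length(enumerate_divisions(subgroup_grid(2, 2)))  # 5
#' length(enumerate_divisions(subgroup_grid(3, 4)))  # 34
#' @export
enumerate_divisions <- function(grid) {
  grid <- as_grid(grid)
  K <- grid$K; J <- grid$J
  # all non-decreasing suffix-length vectors 0 <= c_1 <= ... <= c_K <= J
  counts <- list(integer(0))
  for (k in seq_len(K)) {
    counts <- unlist(lapply(counts, function(pfx) {
      lo <- if (length(pfx)) pfx[length(pfx)] else 0L
      lapply(lo:J, function(c) c(pfx, c))
    }), recursive = FALSE)
  }
  counts <- Filter(function(v) any(v > 0L), counts)
  masks <- lapply(counts, function(v) {
    m <- matrix(FALSE, K, J)
    for (k in seq_len(K)) if (v[k] > 0L) m[k, (J - v[k] + 1L):J] <- TRUE
    m
  })
  # canonical order: lexicographic on the row-major mask
  ord <- order_masks(masks)
  structure(lapply(masks[ord], function(m) new_division(grid, m)),
            class = c("division_list", "list"))
}

order_masks <- function(masks) {
  if (length(masks) <= 1L) return(seq_along(masks))
  bits <- do.call(rbind, lapply(masks, function(m) as.integer(t(m))))
  do.call(order, as.data.frame(bits))
}

#' @export
print.division_list <- function(x, ...) {
  cat(sprintf("%d subgroup divisions\n", length(x)))
  invisible(x)
}

#' Monte-Carlo sampling of monotone divisions
#'
#' Stochastic construction of monotone divisions: per draw, efficacy-ordering
#' variables `r(k, j)` are filled row by row as uniform draws on
#' `(max(r(k-1, j), r(k, j-1)), 1)` with boundary `r(k, 0) = r(0, j) = 0`,
#' so `r` respects the grid partial order.  Each distinct ordering of the
#' subgroups by `r` is partitioned into its candidate high-efficacy subsets
#' (the top `m` subgroups, `m = 1, ..., KJ`), and duplicate divisions are
#' discarded.  With enough draws this recovers [enumerate_divisions()]
#' exactly; the deterministic enumeration is the primary implementation and
#' this sampler serves as a fidelity cross-check.
#'
#' @param grid a [subgroup_grid()].
#' @param n_draws number of Monte-Carlo orderings to draw (>= 1).
#' @param seed integer seed.
#' @return A `division_list` in canonical (lexicographic) order.
#' @export
sample_divisions_mc <- function(grid, n_draws, seed = 1L) {
  grid <- as_grid(grid)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  K <- grid$K; J <- grid$J; m <- K * J
  set.seed(seed)
  seen_ord <- new.env(parent = emptyenv())
  seen_div <- new.env(parent = emptyenv())
  masks <- list()
  for (d in seq_len(n_draws)) {
    r <- matrix(0, K + 1L, J + 1L)  # row/col 1 are the zero boundary
    for (k in seq_len(K)) {
      for (j in seq_len(J)) {
        lo <- max(r[k, j + 1L], r[k + 1L, j])
        r[k + 1L, j + 1L] <- stats::runif(1L, lo, 1)
      }
    }
    rk <- r[-1L, -1L, drop = FALSE]
    ord <- order(rk)                      # cell linear indices by increasing r
    okey <- paste(ord, collapse = ",")
    if (!is.null(seen_ord[[okey]])) next
    seen_ord[[okey]] <- TRUE
    for (sz in seq_len(m)) {              # top-sz cells form a high subset
      cells <- ord[(m - sz + 1L):m]
      high <- matrix(FALSE, K, J); high[cells] <- TRUE
      dkey <- division_key(high)
      if (is.null(seen_div[[dkey]])) {
        seen_div[[dkey]] <- TRUE
        masks[[length(masks) + 1L]] <- high
      }
    }
  }
  ord <- order_masks(masks)
  structure(lapply(masks[ord], function(mm) new_division(grid, mm)),
            class = c("division_list", "list"))
}

#' Upper set of a subgroup
#'
#' All subgroups `(k', j')` with `k' >= k` and `j' >= j`: the subgroups to
#' which an effectiveness (or promise) judgement for `(k, j)` propagates
#' under marginal monotonicity.
#'
#' @param grid a [subgroup_grid()].
#' @param k,j 1-based subgroup levels.
#' @return Two-column matrix of `(k, j)` indices in row-major order.
#' @examples
#' upper_set(subgroup_grid(3, 4), 2, 3)
#' @export
upper_set <- function(grid, k, j) {
  grid <- as_grid(grid)
  if (k < 1 || k > grid$K || j < 1 || j > grid$J) {
    stop("subgroup index out of grid bounds", call. = FALSE)
  }
  ks <- k:grid$K; js <- j:grid$J
  cbind(k = rep(ks, each = length(js)), j = rep(js, times = length(ks)))
}
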