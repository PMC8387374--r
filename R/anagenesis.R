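#' Anagenetic rate matrix for range evolution along branches
#'
#' Along a phylogenetic branch a clone's range evolves by a continuous-time
#' Markov chain with two rates: the dispersal rate `d`, at which the range
#' expands by adding any one new area, and the extinction rate `e`, at which
#' the range contracts by losing any one of its areas. Because the null range
#' is removed from the state space, singleton ranges cannot contract: a clone
#' is always present in at least its sampling site, and every row of Q sums
#' to zero, so the transition matrix stays stochastic.
#'
#' @param space A [range_space()].
#' @param d Dispersal rate (>= 0), per unit branch length per addable area.
#' @param e Extinction rate (>= 0), per unit branch length per losable area.
#'
#' @return A dense `n_states x n_states` rate matrix with state labels as
#'   dimnames and the range space attached as attribute `"space"`.
#'
#' @examples
#' sp <- range_space(2)
#' rate_matrix(sp, d = 0.1, e = 0.05)
#' @export
rate_matrix <- function(space, d, e) {
  stopifnot(inherits(space, "range_space"))
  if (!is.finite(d) || !is.finite(e) || d < 0 || e < 0) {
    stop("rates `d` and `e` must be finite and non-negative", call. = FALSE)
  }
  n <- space$n_states
  Q <- matrix(0, n, n, dimnames = list(space$state_labels, space$state_labels))
  lookup <- state_lookup(space)
  for (i in seq_len(n)) {
    s <- space$states[[i]]
    if (length(s) < space$max_range_size) {
      for (a in setdiff(seq_len(space$n_areas), s)) {
        j <- lookup(c(s, a))
        Q[i, j] <- Q[i, j] + d
      }
    }
    if (length(s) > 1) {  # singletons cannot contract: null range removed
      for (a in s) {
        j <- lookup(setdiff(s, a))
        Q[i, j] <- Q[i, j] + e
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  attr(Q, "space") <- space
  Q
}

#' Branch transition probabilities P(t) = exp(Qt)
#'
#' @param Q A rate matrix from [rate_matrix()].
#' @param t Branch length (>= 0), in the tree's time-proxy units
#'   (mutations per site for clone trees).
#'
#' @return A stochastic matrix: entries in `[0, 1]`, rows summing to 1.
#' @export
transition_probs <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0) {
    stop("branch length `t` must be a single finite number >= 0",
         call. = FALSE)
  }
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- as.matrix(Matrix::expm(Q * t))
  # clip tiny numerical negatives
  P[P < 0] <- 0
  dimnames(P) <- dimnames(Q)
  P
}

# Fast repeated-exponential machinery used by the likelihood: one eigen
# decomposition per (d, e), then P(t) from a diagonal exponential per branch.
# Falls back to expm when Q is (numerically) defective.
make_propagator <- function(Q) {
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(err) NULL)
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(err) NULL)
    if (!is.null(Vi)) {
      recon <- Re(eg$vectors %*% (eg$values * Vi))
      if (max(abs(recon - Q)) < 1e-9 * (1 + max(abs(Q)))) {
        V <- eg$vectors
        lam <- eg$values
        return(function(t) {
          if (t == 0) return(diag(n))
          P <- Re(V %*% (exp(lam * t) * Vi))
          P[P < 0] <- 0
          P
        })
      }
    }
  }
  function(t) {
    if (t == 0) return(diag(n))
    P <- as.matrix(Matrix::expm(Q * t))
    P[P < 0] <- 0
    P
  }
}
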