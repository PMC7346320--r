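#' Linear-chain CRF scoring, partition function and Viterbi decoding
#'
#' The sequence model scores a label sequence `y` for a sentence of `n`
#' characters as the sum of emission and transition terms:
#' `score(x, y) = sum_i P[i, y_i] + sum_{i=1..n+1} A[y_{i-1}, y_i]`, where
#' `P` is the `n x k` emission matrix produced by the encoder, `A` is the
#' `(k+2) x (k+2)` transition matrix whose two augmented states are START
#' (row/column `k+1`) and STOP (`k+2`), `y_0 = START` and `y_{n+1} = STOP`.
#'
#' `crf_sequence_score()` evaluates that sum for one labeling;
#' `crf_log_partition()` returns `log sum_y exp(score(x, y))` over all `k^n`
#' labelings via the forward recursion in log space (the quantity needed for
#' maximum-likelihood training); `crf_viterbi()` returns the highest-scoring
#' labeling and its score (ties resolve to the smallest label index, which
#' `which.max` delivers deterministically).
#'
#' @param P Numeric `n x k` emission matrix (`n >= 1`).
#' @param A Numeric `(k+2) x (k+2)` transition matrix.
#' @param y Integer vector of length `n` with labels in `1..k`.
#' @return `crf_sequence_score()`: numeric scalar. `crf_log_partition()`:
#'   numeric scalar. `crf_viterbi()`: list with `path` (integer vector) and
#'   `score`.
#' @examples
#' P <- matrix(0, 3, 23); A <- matrix(0, 25, 25)
#' crf_sequence_score(P, A, c(1L, 1L, 1L))  # 0
#' crf_log_partition(P, A)                  # 3 * log(23)
#' @export
crf_sequence_score <- function(P, A, y) {
  k <- check_crf(P, A)
  n <- nrow(P)
  y <- as.integer(y)
  if (length(y) != n) stop("label sequence length must equal nrow(P)")
  if (any(y < 1L | y > k)) stop("labels must lie in 1..k")
  start <- k + 1L; stp <- k + 2L
  em <- sum(P[cbind(seq_len(n), y)])
  prev <- c(start, y[-n])
  tr <- sum(A[cbind(prev, y)]) + A[y[n], stp]
  em + tr
}

#' @rdname crf_sequence_score
#' @export
crf_log_partition <- function(P, A) {
  k <- check_crf(P, A)
  n <- nrow(P)
  start <- k + 1L; stp <- k + 2L
  alpha <- A[start, seq_len(k)] + P[1L, ]
  if (n > 1L) {
    At <- A[seq_len(k), seq_len(k), drop = FALSE]
    for (i in 2:n) {
      # alpha_j = logsumexp_i(alpha_i + A[i, j]) + P[t, j]
      m <- alpha + At                       # column j holds alpha + A[, j]
      cmax <- apply(m, 2L, max)
      alpha <- cmax + log(colSums(exp(sweep(m, 2L, cmax)))) + P[i, ]
    }
  }
  v <- alpha + A[seq_len(k), stp]
  mx <- max(v)
  mx + log(sum(exp(v - mx)))
}

#' @rdname crf_sequence_score
#' @export
crf_viterbi <- function(P, A) {
  k <- check_crf(P, A)
  n <- nrow(P)
  start <- k + 1L; stp <- k + 2L
  delta <- A[start, seq_len(k)] + P[1L, ]
  back <- matrix(0L, n, k)
  if (n > 1L) {
    At <- A[seq_len(k), seq_len(k), drop = FALSE]
    for (i in 2:n) {
      m <- delta + At
      bp <- apply(m, 2L, which.max)
      delta <- m[cbind(bp, seq_len(k))] + P[i, ]
      back[i, ] <- bp
    }
  }
  fin <- delta + A[seq_len(k), stp]
  last <- which.max(fin)
  path <- integer(n)
  path[n] <- last
  if (n > 1L) for (i in n:2) path[i - 1L] <- back[i, path[i]]
  list(path = path, score = fin[last])
}

check_crf <- function(P, A) {
  if (!is.matrix(P) || nrow(P) < 1L) stop("P must be a matrix with n >= 1 rows")
  k <- ncol(P)
  if (!is.matrix(A) || nrow(A) != k + 2L || ncol(A) != k + 2L) {
    stop("A must be a (k+2) x (k+2) matrix with k = ncol(P)")
  }
  k
}
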