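#' 1.5-entmax: sparse probability mapping
#'
#' Maps real scores to a point on the probability simplex, like softmax, but
#' with exact zeros for low-scoring entries. It is the maximizer over the
#' simplex of `p' z + H(p)` with the Tsallis 1.5-entropy
#' `H(p) = sum_j (p_j - p_j^1.5) / (1.5 * 0.5)`. The solution has the
#' closed-form characterization `p_i = pmax(0, z_i / 2 - tau)^2` with the
#' threshold `tau` chosen so the entries sum to one; `tau` is found by
#' bisection to `|sum(p) - 1| < 1e-8`. The mapping is invariant to adding a
#' constant to `z` and equivariant under permutations.
#'
#' @param z Numeric vector, or matrix (applied row-wise).
#' @param tol Bisection tolerance on `|sum(p) - 1|`.
#' @return Probability vector/matrix of the same shape; rows sum to 1 and
#'   are typically sparse.
#' @export
entmax15 <- function(z, tol = 1e-9) {
  vec <- is.null(dim(z))
  zm <- if (vec) matrix(z, nrow = 1) else as.matrix(z)
  if (anyNA(zm) || any(!is.finite(zm))) stop("entmax15: non-finite input")
  p <- .entmax15_mat(zm, tol)
  if (vec) drop(p) else p
}

# Row-wise bisection for tau. zm: B x d.
.entmax15_mat <- function(zm, tol = 1e-9) {
  zh <- zm / 2
  mx <- apply(zh, 1L, max)
  lo <- mx - 1        # sum(p) >= 1 here (p_max >= 1)
  hi <- mx            # sum(p) = 0 here
  for (iter in 1:100) {
    tau <- (lo + hi) / 2
    s <- pmax(zh - tau, 0)   # tau recycled down rows (column-major)
    rs <- rowSums(s * s)
    too_big <- rs > 1
    lo <- ifelse(too_big, tau, lo)
    hi <- ifelse(too_big, hi, tau)
    if (max(abs(rs - 1)) < tol) break
  }
  tau <- (lo + hi) / 2
  s <- pmax(zh - tau, 0)
  p <- s * s
  p / rowSums(p)   # exact simplex membership; preserves the zero pattern
}

# Backward pass: with s_i = sqrt(p_i) on the support, the Jacobian is
# J = diag(s) - s s' / sum(s), so J g = s * (g - sum(s*g)/sum(s)).
.entmax15_bwd <- function(dp, p) {
  s <- sqrt(p)
  ssum <- rowSums(s)
  dot <- rowSums(s * dp)
  s * (dp - dot / ssum)
}
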