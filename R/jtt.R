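# JTT empirical amino-acid substitution model. Constants (exchangeabilities
# and equilibrium frequencies, Jones-Taylor-Thornton 1992) are parsed from
# the bundled PAML-format file; the rate matrix is normalized to one
# expected substitution per site per unit time and eigendecomposed once so
# that P(t) = exp(Qt) is cheap for any t.

jtt_model <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- system.file("extdata", "jtt.dat", package = "zcdtools")
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines)]
    lines <- lines[nzchar(trimws(lines))]
    nums <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    tri <- nums[1:19]
    stopifnot(all(lengths(tri) == 1:19))
    pi_aa <- nums[[20]]
    stopifnot(length(pi_aa) == 20, abs(sum(pi_aa) - 1) < 1e-6)
    S <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
    for (i in 2:20) {
      S[i, 1:(i - 1)] <- tri[[i - 1]]
    }
    S <- S + t(S)
    Q <- S * rep(pi_aa, each = 20)      # Q_ij = s_ij * pi_j (i != j)
    diag(Q) <- -rowSums(Q)
    scale <- -sum(pi_aa * diag(Q))
    Q <- Q / scale
    # reversible Q: symmetrize with pi^(1/2) for a stable eigendecomposition
    sq <- sqrt(pi_aa)
    B <- diag(sq) %*% Q %*% diag(1 / sq)
    B <- (B + t(B)) / 2
    eig <- eigen(B, symmetric = TRUE)
    cache <<- list(
      pi = setNames(pi_aa, AA20), Q = Q,
      V = diag(1 / sq) %*% eig$vectors,     # P(t) = V diag(e^{lambda t}) Vinv
      Vinv = t(eig$vectors) %*% diag(sq),
      lambda = eig$values
    )
    cache
  }
})

#' JTT transition probability matrix
#'
#' Returns `P(t) = exp(Qt)` for the JTT rate matrix normalized to one
#' expected substitution per site per unit time, amino acids in the order
#' A R N D C Q E G H I L K M F P S T W Y V.
#'
#' @param t branch length in expected substitutions per site (`t >= 0`).
#' @return 20 x 20 row-stochastic matrix.
#' @export
jtt_prob_matrix <- function(t) {
  stopifnot(t >= 0)
  m <- jtt_model()
  P <- m$V %*% (exp(m$lambda * t) * m$Vinv)
  P[P < 0] <- 0
  dimnames(P) <- list(AA20, AA20)
  P
}

#' JTT equilibrium amino-acid frequencies
#' @return Named numeric vector of length 20 summing to 1.
#' @export
jtt_frequencies <- function() jtt_model()$pi

pair_counts <- function(a, b) {
  ok <- a %in% AA20 & b %in% AA20   # pairwise deletion: gaps and X dropped
  table(factor(a[ok], levels = AA20), factor(b[ok], levels = AA20))
}

#' Maximum-likelihood JTT distance between two aligned rows
#'
#' Estimates the evolutionary distance (expected substitutions per site)
#' between two equal-length aligned sequences under the JTT model:
#' maximizes over `t >= 0` the likelihood
#' `prod over ungapped column pairs (a, b) of pi_a * P_ab(t)`,
#' by bracketed scalar search to tolerance 1e-6. Columns where either row
#' has a gap or an unknown `X` are dropped (pairwise deletion). Distances
#' are capped at `cap`; a capped estimate is flagged via the `"saturated"`
#' attribute.
#'
#' @param row_a,row_b character vectors (or single strings) of equal
#'   aligned length.
#' @param cap saturation cap in substitutions per site (default 10).
#' @return Numeric distance, with attribute `saturated` (logical).
#' @export
jtt_distance <- function(row_a, row_b, cap = 10) {
  if (length(row_a) == 1 && is.character(row_a)) row_a <- strsplit(row_a, "", fixed = TRUE)[[1]]
  if (length(row_b) == 1 && is.character(row_b)) row_b <- strsplit(row_b, "", fixed = TRUE)[[1]]
  if (length(row_a) != length(row_b)) abort("aligned rows differ in length")
  N <- pair_counts(row_a, row_b)
  if (sum(N) == 0) abort("no shared ungapped columns between the two rows")
  if (sum(N) == sum(diag(N))) {
    return(structure(0, saturated = FALSE))
  }
  negll <- function(t) {
    P <- jtt_prob_matrix(t)
    lik <- jtt_model()$pi * P
    -sum(N * log(pmax(lik, 1e-300)))
  }
  opt <- optimize(negll, interval = c(1e-8, cap), tol = 1e-6)
  d <- opt$minimum
  saturated <- d > cap - 1e-3
  if (saturated) d <- cap
  structure(d, saturated = saturated)
}

#' Pairwise JTT distance matrix of an alignment
#'
#' Applies [jtt_distance()] to every pair of rows. Gap handling is
#' pairwise deletion by default; `deletion = "complete"` first removes
#' every column containing any gap or `X`.
#'
#' @param aln an [anchored_alignment()] or character matrix with row names.
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @param cap saturation cap passed to [jtt_distance()].
#' @return Symmetric numeric matrix (zero diagonal) with a logical
#'   `"saturated"` attribute matrix flagging capped entries.
#' @export
jtt_distance_matrix <- function(aln, deletion = c("pairwise", "complete"), cap = 10) {
  deletion <- match.arg(deletion)
  mat <- alignment_matrix(aln)
  if (is.null(rownames(mat))) abort("alignment matrix needs row names")
  if (deletion == "complete") {
    keep <- apply(mat, 2, function(col) all(col %in% AA20))
    mat <- mat[, keep, drop = FALSE]
  }
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  S <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- jtt_distance(mat[i, ], mat[j, ], cap = cap)
      D[i, j] <- D[j, i] <- as.numeric(d)
      S[i, j] <- S[j, i] <- attr(d, "saturated")
    }
  }
  structure(D, saturated = S)
}
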