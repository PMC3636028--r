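#' Normalized conditional entropy of labels given output posteriors
#'
#' Builds the joint distribution `p(l, k)` as the average over samples of
#' `1(label = l) * posterior_k` and returns `H(L | Z) / H(L)`:
#' 0 when each output identifies its label perfectly, 1 when the outputs
#' carry no label information.
#'
#' @param labels Vector of true hidden causes, one per sample.
#' @param posteriors `n x K` matrix; each row a probability vector over
#'   the outputs for that sample.
#' @return Scalar in `[0, 1]`.
#' @export
normalized_conditional_entropy <- function(labels, posteriors) {
  posteriors <- as.matrix(posteriors)
  stopifnot(nrow(posteriors) == length(labels),
            all(abs(rowSums(posteriors) - 1) < 1e-6))
  lev <- sort(unique(labels))
  if (length(lev) < 2L) stop("need at least two label classes (H(L) = 0)")
  joint <- vapply(lev, function(l) {
    colMeans(posteriors[labels == l, , drop = FALSE]) * mean(labels == l)
  }, numeric(ncol(posteriors)))  # K x L
  joint <- joint / sum(joint)
  pk <- rowSums(joint)
  pl <- colSums(joint)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  h_lz <- -sum(xlogx(joint)) + sum(xlogx(pk))
  h_l <- -sum(xlogx(pl))
  h_lz / h_l
}

#' Classify inputs by neuron-to-class assignment
#'
#' Assigns each output neuron to the class for which it fires most
#' strongly (class-conditional total spike counts), then classifies each
#' input by its most active neuron's assigned class.
#'
#' Ties are broken towards the lower index. A neuron that never fired is
#' assigned to the majority class, with a warning.
#'
#' @param counts `n_inputs x K` matrix of output spike counts per
#'   (labeled input, neuron).
#' @param labels True class per input.
#' @return List with `assignment` (class per neuron) and `error_rate`
#'   (fraction of inputs whose winning neuron's class differs from the
#'   label).
#' @export
classify_by_assignment <- function(counts, labels) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(labels))
  lev <- sort(unique(labels))
  by_class <- vapply(lev, function(l) {
    colSums(counts[labels == l, , drop = FALSE])
  }, numeric(ncol(counts)))  # K x L
  by_class <- matrix(by_class, ncol = length(lev))
  assignment <- lev[apply(by_class, 1, which.max)]
  dead <- rowSums(by_class) == 0
  if (any(dead)) {
    warning(sum(dead), " neuron(s) never fired; assigned to majority class")
    assignment[dead] <- lev[which.max(tabulate(match(labels, lev)))]
  }
  winner <- apply(counts, 1, which.max)
  list(assignment = assignment,
       error_rate = mean(assignment[winner] != labels))
}

#' Optimal label permutation for parameter-recovery comparisons
#'
#' Finds the assignment of estimated components to true components that
#' maximizes the total confusion weight: exhaustively over permutations
#' for `K <= 8`, greedily (largest weight first) for larger `K`.
#'
#' @param confusion `K x K` matrix; `confusion[k, l]` = weight of matching
#'   estimated component `k` to true component `l`.
#' @return Integer vector `perm` with `perm[k]` the true component matched
#'   to estimated component `k`.
#' @export
match_labels <- function(confusion) {
  confusion <- as.matrix(confusion)
  K <- nrow(confusion)
  stopifnot(ncol(confusion) == K)
  if (K <= 8L) {
    perms <- permutations(K)
    scores <- apply(perms, 1, function(p) {
      sum(confusion[cbind(seq_len(K), p)])
    })
    perms[which.max(scores), ]
  } else {
    perm <- integer(K)
    cf <- confusion
    for (step in seq_len(K)) {
      ij <- arrayInd(which.max(cf), dim(cf))
      perm[ij[1]] <- ij[2]
      cf[ij[1], ] <- -Inf
      cf[, ij[2]] <- -Inf
    }
    perm
  }
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}
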