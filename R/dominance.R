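#' Build a win/loss matrix from agonistic interactions
#'
#' Tallies resolved agonistic interactions into a square matrix where
#' `wins[i, j]` is the number of interactions `i` won against `j`.
#' Unresolved interactions (no submissive behaviour by either animal)
#' contribute nothing.
#'
#' @param agonistic A data frame with columns `individual_a`, `individual_b`,
#'   `winner` (`NA` allowed when unresolved) and logical `resolved`.
#' @param ids Optional character vector fixing the matrix order (and
#'   including individuals with no interactions). Defaults to the sorted
#'   union of participants.
#' @return A `win_loss_matrix`: integer matrix with zero diagonal and id
#'   dimnames.
#' @export
win_loss_matrix <- function(agonistic, ids = NULL) {
  stopifnot(all(c("individual_a", "individual_b", "resolved") %in% names(agonistic)))
  if (is.null(ids)) {
    ids <- sort(unique(c(agonistic$individual_a, agonistic$individual_b)))
  }
  res <- agonistic[agonistic$resolved, , drop = FALSE]
  if (nrow(res) > 0) {
    bad <- res$winner != res$individual_a & res$winner != res$individual_b
    if (any(bad | is.na(res$winner))) {
      stop("resolved interaction with winner not among the participants")
    }
  }
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(res) > 0) {
    loser <- ifelse(res$winner == res$individual_a, res$individual_b, res$individual_a)
    tab <- table(factor(res$winner, ids), factor(loser, ids))
    m <- m + unclass(tab)
    storage.mode(m) <- "integer"
  }
  structure(m, class = c("win_loss_matrix", class(m)))
}

# Number of individuals each animal dominates: majority of resolved wins in
# the pair; exact ties and unobserved pairs contribute 0.5 to each animal
# (the classical continuity correction for unknown relationships).
dominance_scores <- function(m) {
  n <- nrow(m)
  v <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (m[i, j] > m[j, i]) v[i] <- v[i] + 1
      else if (m[i, j] == m[j, i]) v[i] <- v[i] + 0.5
    }
  }
  names(v) <- rownames(m)
  v
}

#' Landau's index of dominance-hierarchy linearity
#'
#' \deqn{h = \frac{12}{N^3 - N} \sum_a \left( V_a - \frac{N-1}{2} \right)^2}
#' where \eqn{V_a} is the number of individuals animal `a` dominates
#' (majority of resolved wins in each pair; ties and unobserved pairs count
#' 0.5). `h` is 1 exactly when the dominance relation is a strict linear
#' order and 0 at maximal intransitivity.
#'
#' @param m A `win_loss_matrix` (or plain square matrix) for at least 3
#'   individuals.
#' @return Landau's h, a number in `[0, 1]`.
#' @export
landau_h <- function(m) {
  n <- nrow(m)
  if (is.null(n) || n < 3) stop("Landau's h needs at least 3 individuals")
  v <- dominance_scores(m)
  12 / (n^3 - n) * sum((v - (n - 1) / 2)^2)
}

#' Assign integer dominance ranks
#'
#' Ranks are `1..N` with the largest number for the most dominant mother
#' (the one dominating the most others) and 1 for the least dominant.
#' Ordering is by descending dominance score \eqn{V_a}; ties are broken by
#' total wins, then by id (lexically earlier id ranks higher), so the
#' result is deterministic.
#'
#' @param m A `win_loss_matrix` for at least 2 individuals.
#' @return Named integer vector: id -> rank, a permutation of `1..N`.
#' @export
assign_ranks <- function(m) {
  n <- nrow(m)
  if (is.null(n) || n < 2) stop("rank assignment needs at least 2 individuals")
  v <- dominance_scores(m)
  wins <- rowSums(m)
  ord <- order(-v, -wins, rownames(m))  # most dominant first
  ranks <- integer(n)
  ranks[ord] <- n:1
  names(ranks) <- rownames(m)
  ranks
}
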