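#' Per-parent offspring counts (ki vector) from a pedigree
#'
#' Counts, for every parent with at least one sampled offspring, the number
#' of sampled offspring attributed to it. Because every offspring has
#' exactly two parents, the counts always satisfy `sum(ki) == 2 * S` where
#' `S` is the number of sampled offspring. Parents with zero sampled
#' offspring are omitted: the PwoP estimator needs no information about
#' parents that contributed nothing.
#'
#' @param pedigree a `hatchery_pedigree` (see [simulate_pedigree()]) or any
#'   list with an `offspring` data frame holding columns `offspring_id`,
#'   `sire_id`, `dam_id`.
#' @param sampled_offspring character vector of offspring IDs to count;
#'   defaults to all offspring in the pedigree.
#' @return a named integer vector of counts (class `ki_vector`), with
#'   attribute `S` giving the number of sampled offspring.
#' @seealso [pwop_nb()], [ki_from_partition()]
#' @export
ki_vector <- function(pedigree, sampled_offspring = NULL) {
  off <- pedigree$offspring
  if (is.null(sampled_offspring)) sampled_offspring <- off$offspring_id
  if (length(sampled_offspring) == 0L) {
    stop("'sampled_offspring' is empty: ki vector undefined")
  }
  keep <- off$offspring_id %in% sampled_offspring
  if (sum(keep) != length(unique(sampled_offspring))) {
    stop("some sampled offspring are not present in the pedigree")
  }
  off <- off[keep, , drop = FALSE]
  ki <- table(c(off$sire_id, off$dam_id))
  out <- setNames(as.integer(ki), names(ki))
  attr(out, "S") <- nrow(off)
  class(out) <- "ki_vector"
  out
}

#' Effective number of breeders by parentage-without-parents (PwoP)
#'
#' Computes the single-cohort effective number of breeders from a vector of
#' per-parent offspring counts:
#' \deqn{N_b = \frac{2S - 1}{\sum_i k_i^2 / (2S) - 1}}
#' where `S` is the number of offspring and `k_i` the number of offspring
#' attributed to parent `i`. This is algebraically identical to the
#' Crow-Denniston inbreeding effective size
#' \eqn{(N\bar{k} - 1) / (\bar{k} - 1 + V_k/\bar{k})} evaluated over the
#' implied parent set, and is invariant to adding parents with `ki = 0`.
#'
#' When the denominator is non-positive (e.g., every parent contributed a
#' single offspring) the estimate is `Inf`; infinity is a first-class value
#' here, propagated rather than thrown, because downstream evaluation
#' summaries count and exclude infinite estimates explicitly.
#'
#' @param ki a [ki_vector()] or a bare numeric vector of per-parent counts.
#' @param S number of offspring; taken from the `S` attribute when present,
#'   otherwise inferred as `sum(ki) / 2`.
#' @return a single number, `> 0` or `Inf`.
#' @export
#' @examples
#' pwop_nb(rep(2, 10))          # 10 parents, ki = 2 each: Nb = 2 * 10 - 1
#' pwop_nb(c(10, 10))           # one pair produced everything: 19/9
pwop_nb <- function(ki, S = attr(ki, "S")) {
  ki <- as.numeric(ki)
  if (any(ki < 0)) stop("ki counts must be non-negative")
  if (is.null(S)) {
    if (sum(ki) %% 2 != 0) {
      stop("sum(ki) is odd: inconsistent pedigree (every offspring has two parents)")
    }
    S <- sum(ki) / 2
  }
  if (S < 1) stop("S must be at least 1")
  if (sum(ki) != 2 * S) {
    stop(sprintf("sum(ki) = %g but 2S = %g: inconsistent pedigree",
                 sum(ki), 2 * S))
  }
  denom <- sum(ki^2) / (2 * S) - 1
  if (denom <= 0) return(Inf)
  (2 * S - 1) / denom
}

#' Label all offspring dyads as full-sib, half-sib, or unrelated
#'
#' Exhaustively classifies every unordered pair of sampled offspring by the
#' number of shared parents: full-sib (`FS`, both), half-sib (`HS`, exactly
#' one), unrelated (`U`, none). Counts always sum to `choose(n, 2)`.
#'
#' @inheritParams ki_vector
#' @return an object of class `dyad_labels`: a list with `labels` (a data
#'   frame of pair indices `i`, `j` and factor `label`) and `counts` (named
#'   vector over `FS`, `HS`, `U`).
#' @export
label_dyads <- function(pedigree, sampled_offspring = NULL) {
  off <- pedigree$offspring
  if (is.null(sampled_offspring)) sampled_offspring <- off$offspring_id
  off <- off[match(sampled_offspring, off$offspring_id), , drop = FALSE]
  if (anyNA(off$offspring_id)) {
    stop("some sampled offspring are not present in the pedigree")
  }
  dyads_from_parents(off$offspring_id, off$sire_id, off$dam_id)
}

# Internal: dyad labels from parallel sire/dam vectors (shared by truth and
# reconstruction paths). Vectorised over all C(n, 2) pairs.
dyads_from_parents <- function(ids, sire, dam) {
  n <- length(ids)
  if (n < 2L) stop("need at least 2 offspring to form dyads")
  pr <- pair_index(n)
  same_s <- sire[pr$i] == sire[pr$j]
  same_d <- dam[pr$i] == dam[pr$j]
  lab <- ifelse(same_s & same_d, "FS", ifelse(same_s | same_d, "HS", "U"))
  lab <- factor(lab, levels = c("FS", "HS", "U"))
  counts <- setNames(as.integer(table(lab)), levels(lab))
  structure(list(
    ids = ids,
    labels = data.frame(i = pr$i, j = pr$j, label = lab),
    counts = counts
  ), class = "dyad_labels")
}

# Internal: row/column indices of all unordered pairs of 1..n, in a fixed
# canonical order (i < j, j varying fastest within i).
pair_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  j <- sequence(rev(seq_len(n - 1L)), from = seq_len(n - 1L) + 1L)
  list(i = i, j = j)
}

#' @export
print.dyad_labels <- function(x, ...) {
  n <- length(x$ids)
  cat(sprintf("Dyad labels for %d offspring (%d pairs)\n", n, nrow(x$labels)))
  print(x$counts)
  invisible(x)
}

#' @export
print.ki_vector <- function(x, ...) {
  cat(sprintf("ki vector: %d parents, S = %d offspring, sum(ki) = %d\n",
              length(x), attr(x, "S"), sum(x)))
  print(table(factor(unclass(x))))
  invisible(x)
}
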