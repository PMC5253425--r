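#' Deviation from Hardy-Weinberg proportions (Wright's F_IS)
#'
#' Estimates alpha, the nonrandom-mating correction used by the
#' sibship-assignment Nb estimator, as one minus the ratio of mean observed
#' heterozygosity to mean expected heterozygosity `2p(1-p)`, pooled over
#' loci (ratio of averages, which is more stable across ~100 SNPs than an
#' average of per-locus ratios). Positive alpha indicates a heterozygote
#' deficit.
#'
#' @param genotypes matrix of 0/1/2 codes (`NA` missing).
#' @param freqs per-locus allele frequencies; default estimated from the
#'   sample.
#' @return alpha in `[-1, 1]`.
#' @export
estimate_alpha <- function(genotypes, freqs = estimate_allele_freqs(genotypes)) {
  ho <- colMeans(genotypes == 1L, na.rm = TRUE)
  he <- 2 * freqs * (1 - freqs)
  poly <- he > 0
  if (!any(poly)) stop("all loci are monomorphic in the sample")
  alpha <- 1 - mean(ho[poly]) / mean(he[poly])
  max(-1, min(1, alpha))
}

#' Sibship frequencies from a partition or dyad labels
#'
#' Sample frequencies of paternal half-sib (`q1`: share sire only),
#' maternal half-sib (`q2`: share dam only), and full-sib (`q3`: share
#' both) dyads among all `choose(n, 2)` offspring pairs. The definitions
#' are exclusive, so `q1 + q3` is the probability of sharing a sire.
#'
#' @param x a [sibship_partition()], or a `dyad_labels` object for the
#'   sexless FS/HS/U split (half-sib frequency then divides evenly between
#'   `q1` and `q2`).
#' @return a list of class `sibship_frequencies` with `q1`, `q2`, `q3`,
#'   `n`, and `n_pairs`.
#' @export
sibship_frequencies <- function(x) {
  if (inherits(x, "sibship_partition")) {
    n <- length(x$offspring_id)
    if (n < 2L) stop("need at least 2 offspring")
    np <- choose(n, 2)
    pairs2 <- function(v) sum(choose(as.numeric(table(v)), 2))
    fs <- pairs2(paste(x$sire, x$dam, sep = "\r"))
    q1 <- (pairs2(x$sire) - fs) / np
    q2 <- (pairs2(x$dam) - fs) / np
    q3 <- fs / np
  } else if (inherits(x, "dyad_labels")) {
    n <- length(x$ids)
    np <- choose(n, 2)
    q3 <- x$counts["FS"] / np
    q1 <- q2 <- x$counts["HS"] / (2 * np)
  } else {
    stop("'x' must be a sibship_partition or dyad_labels object")
  }
  structure(list(q1 = unname(q1), q2 = unname(q2), q3 = unname(q3),
                 n = n, n_pairs = np),
            class = "sibship_frequencies")
}

#' @export
print.sibship_frequencies <- function(x, ...) {
  cat(sprintf(
    "Sibship frequencies (n = %d, %d pairs): Q1 = %.5g, Q2 = %.5g, Q3 = %.5g\n",
    x$n, x$n_pairs, x$q1, x$q2, x$q3))
  invisible(x)
}

#' Sibship-assignment (SA) estimator of the effective number of breeders
#'
#' Implements the sibship-frequency estimator
#' \deqn{N_b = \frac{1}{\frac{1+3\alpha}{4}(Q_1+Q_2+2Q_3) -
#'   \frac{\alpha}{2}\left(\frac{1}{N_1}+\frac{1}{N_2}\right)}}
#' where `Q1`, `Q2`, `Q3` are the paternal half-sib, maternal half-sib and
#' full-sib dyad frequencies and alpha the deviation from Hardy-Weinberg
#' proportions. The parental sex counts `N1`, `N2` are not observable from
#' offspring alone and are substituted by their sibship-implied values
#' `1/(Q1+Q3)` and `1/(Q2+Q3)`; when alpha is 0 or a sharing probability is
#' 0 the corresponding term drops. With `alpha = 0` the estimator reduces
#' to `4 / (Q1 + Q2 + 2 Q3)`.
#'
#' A non-positive denominator (e.g., no sibs found) yields `Inf`, which is
#' a value, not an error.
#'
#' @param q a [sibship_frequencies()] object (or list with `q1`, `q2`,
#'   `q3`).
#' @param alpha nonrandom-mating correction, see [estimate_alpha()];
#'   default 0 (random mating).
#' @return Nb estimate (positive real or `Inf`) of class `nb_estimate`.
#' @export
#' @examples
#' sa_nb(list(q1 = 0, q2 = 0, q3 = 0.01))  # 4 / 0.02 = 200
sa_nb <- function(q, alpha = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= -1, alpha <= 1)
  q1 <- q$q1; q2 <- q$q2; q3 <- q$q3
  if (min(q1, q2, q3) < 0 || q1 + q2 + q3 > 1 + 1e-12) {
    stop("invalid sibship frequencies")
  }
  denom <- (1 + 3 * alpha) / 4 * (q1 + q2 + 2 * q3)
  if (alpha != 0) {
    inv_n1 <- q1 + q3  # N1 substituted by 1/(Q1+Q3); zero prob drops term
    inv_n2 <- q2 + q3
    denom <- denom - alpha / 2 * (inv_n1 + inv_n2)
  }
  value <- if (denom <= 0) Inf else 1 / denom
  structure(value, method = "SA", alpha = alpha,
            q = c(q1 = q1, q2 = q2, q3 = q3), class = "nb_estimate")
}

#' Family-size vector implied by a sibship partition
#'
#' Each latent sire and dam receives as `ki` the number of offspring
#' assigned to it; `sum(ki) = 2 * S` always.
#'
#' @param partition a [sibship_partition()].
#' @return a [ki_vector()].
#' @export
ki_from_partition <- function(partition) {
  tab <- table(c(paste0("S\r", partition$sire), paste0("D\r", partition$dam)))
  out <- setNames(as.integer(tab), names(tab))
  attr(out, "S") <- length(partition$offspring_id)
  class(out) <- "ki_vector"
  out
}

#' PwoP estimate of Nb from a sibship partition
#'
#' Reconstructs the per-parent offspring counts from the partition's latent
#' parent assignments and applies the PwoP estimator [pwop_nb()]; this is
#' the same code path used to compute the true Nb from a complete pedigree,
#' so applying it to the true partition reproduces the true Nb exactly.
#'
#' @param partition a [sibship_partition()].
#' @return Nb estimate (positive real or `Inf`) of class `nb_estimate`.
#' @export
pwop_nb_from_partition <- function(partition) {
  structure(pwop_nb(ki_from_partition(partition)), method = "PwoP",
            class = "nb_estimate")
}

#' @export
print.nb_estimate <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("Nb estimate (%s): %s\n", attr(x, "method"),
              if (is.finite(v)) format(round(v)) else "Inf"))
  invisible(x)
}

#' Read a sibship partition from a BestCluster-style file
#'
#' Parses the whitespace-delimited cluster listing emitted by COLONY-style
#' sibship software (and by [write_best_cluster()]): columns
#' `ClusterIndex`, `ClusterProbability`, `OffspringID`, `FatherID`,
#' `MotherID`, with an optional header line. Latent father/mother IDs
#' become the partition's sire and dam labels.
#'
#' @param path file to read.
#' @param mating_system mating system to stamp on the partition (the file
#'   does not record it); default `"polygamy"`, the least constrained.
#' @return a [sibship_partition()].
#' @export
read_best_cluster <- function(path, mating_system = "polygamy") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty BestCluster file: ", path)
  tok <- strsplit(trimws(lines), "[[:space:]]+")
  short <- vapply(tok, length, integer(1)) < 5L
  if (any(short)) {
    stop("line ", which(short)[1],
         " has fewer than 5 columns (ClusterIndex ClusterProbability OffspringID FatherID MotherID)")
  }
  if (grepl("cluster", tok[[1]][1], ignore.case = TRUE) ||
      is.na(suppressWarnings(as.numeric(tok[[1]][1])))) {
    tok <- tok[-1]
    if (!length(tok)) stop("BestCluster file has a header but no data rows")
  }
  off <- vapply(tok, `[`, character(1), 3L)
  if (anyDuplicated(off)) {
    stop("duplicate OffspringID in BestCluster file: ",
         off[duplicated(off)][1])
  }
  sibship_partition(off,
                    sire = vapply(tok, `[`, character(1), 4L),
                    dam = vapply(tok, `[`, character(1), 5L),
                    mating_system = mating_system)
}

#' Write a sibship partition in BestCluster-compatible format
#'
#' Writes the maximum-likelihood configuration with a cluster probability
#' of 1.0 per row, so downstream Nb estimation consumes native and
#' external sibship outputs identically.
#'
#' @param partition a [sibship_partition()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_best_cluster <- function(partition, path) {
  cluster <- match(paste(partition$sire, partition$dam, sep = "\r"),
                   unique(paste(partition$sire, partition$dam, sep = "\r")))
  lines <- c("ClusterIndex ClusterProbability OffspringID FatherID MotherID",
             sprintf("%d 1.0 %s %s %s", cluster, partition$offspring_id,
                     partition$sire, partition$dam))
  writeLines(lines, path)
  invisible(path)
}
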